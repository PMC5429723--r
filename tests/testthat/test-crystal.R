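cell <- magnetite_cell()

test_that("replication builds correct supercells", {
  bulk <- replicate_cell(cell, 3, 3, 3)
  expect_equal(nrow(bulk), 56 * 27)
  expect_equal(attr(bulk, "box"), c(3, 3, 3) * 8.3958)

  one <- replicate_cell(cell, 1, 1, 1)
  expect_equal(nrow(one), 56)
  A <- cell_matrix(cell)
  ref <- as.matrix(cell$sites[, c("fx", "fy", "fz")]) %*% t(A)
  expect_equal(unname(coords(one)), unname(ref), tolerance = 1e-12)

  expect_error(replicate_cell(cell, 0, 1, 1), "factors")
  expect_error(replicate_cell(cell, 1.5, 1, 1), "factors")
})

test_that("single-family Wulff shapes are the analytic solids", {
  cube <- wulff_shape(miller_facets(1, 0, 0), cell, target_diameter = 30)
  expect_equal(cube$n_faces, 6)
  expect_equal(cube$volume, 27000, tolerance = 1e-9)
  expect_equal(cube$area, 6 * 900, tolerance = 1e-9)

  octa <- wulff_shape(miller_facets(1, 1, 1), cell, target_diameter = 30)
  expect_equal(octa$n_faces, 8)
  # regular octahedron with inradius 15: V = (4/3) d^3 / sqrt(3) with d = 15*sqrt(3)
  a_oct <- 15 * sqrt(6)   # edge for inradius 15
  expect_equal(octa$volume, sqrt(2) / 3 * a_oct^3, tolerance = 1e-6)
})

test_that("half-space distances follow the Wulff condition d ~ gamma", {
  ws <- wulff_shape(miller_facets(c(1, 1), c(0, 1), c(0, 1),
                                  gamma = c(1.0, 1.15)), cell, 30)
  expect_equal(unname(ws$d / ws$gamma), rep(ws$scale, length(ws$d)))
  # diameter along the dominant facet normal
  expect_equal(2 * min(ws$d), 30)
  td <- tidy(ws)
  expect_true(all(td$boundary_face))      # truncated cube keeps all 14 faces
  expect_equal(nrow(td), 14)
})

test_that("Wulff vertices match the plane-triple oracle", {
  for (gamma111 in c(1.05, 1.15, 1.5)) {
    ws <- wulff_shape(miller_facets(c(1, 1), c(0, 1), c(0, 1),
                                    gamma = c(1.0, gamma111)), cell, 30)
    ov <- oracle_halfspace_vertices(ws$normals, ws$d)
    got <- ws$vertices
    got <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
    expect_equal(nrow(got), nrow(ov))
    expect_lt(max(abs(got - ov)), 1e-6)
  }
})

test_that("an open facet set raises a geometry error", {
  expect_error(
    wulff_shape(miller_facets(0, 0, 1, expand_family = FALSE), cell, 30),
    "unbounded|close the shape")
})

test_that("carving equals the naive per-atom filter and keeps boundary atoms", {
  bulk <- replicate_cell(cell, 5, 5, 5)
  shape <- wulff_shape(miller_facets(1, 0, 0), cell, 30)
  center <- attr(bulk, "box") / 2
  core <- carve(bulk, shape, center)

  # brute-force |x|,|y|,|z| <= 15 about the center
  rel <- sweep(coords(bulk), 2, center)
  ref_ids <- sort(bulk$atom_id[apply(abs(rel) <= 15 + 1e-6, 1, all)])
  expect_identical(sort(core$atom_id), ref_ids)
  expect_identical(sort(core$atom_id), oracle_carve_ids(bulk, shape, center))

  # postcondition: every carved atom satisfies all half-space inequalities
  viol <- coords(core) %*% t(shape$normals) - rep(shape$d, each = nrow(core))
  expect_lt(max(viol), 1e-6)
})

test_that("carve refuses a shape larger than the bulk", {
  bulk <- replicate_cell(cell, 2, 2, 2)
  shape <- wulff_shape(miller_facets(1, 0, 0), cell, 60)
  expect_error(carve(bulk, shape), "larger replication")
})

test_that("atom count grows monotonically with diameter", {
  facets <- miller_facets(c(1, 1), c(0, 1), c(0, 1), gamma = c(1.0, 1.15))
  counts <- vapply(c(12, 18, 24, 30), function(dm) {
    nrow(carve_core(cell, facets, dm, verbose = FALSE))
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("a {100}-only particle spans the diameter within one plane spacing", {
  core <- carve_core(cell, miller_facets(1, 0, 0), 30, verbose = FALSE)
  spacing <- cell$a / 8   # adjacent atomic planes along <100> in the spinel
  for (axis in 1:3) {
    span <- diff(range(coords(core)[, axis]))
    expect_lt(30 - span, spacing + 1e-9)
    expect_lte(span, 30 + 1e-9)
  }
})

test_that("facet families expand under the cubic point group", {
  f100 <- nanoforge:::expand_family(c(1, 0, 0), nanoforge:::point_group(cell))
  f111 <- nanoforge:::expand_family(c(1, 1, 1), nanoforge:::point_group(cell))
  expect_equal(nrow(f100), 6)
  expect_equal(nrow(f111), 8)
})
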