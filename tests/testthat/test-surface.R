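cell <- magnetite_cell()
facets <- miller_facets(c(1, 1), c(0, 1), c(0, 1), gamma = c(1.0, 1.15))
core <- carve_core(cell, facets, 30, verbose = FALSE)

test_that("bulk Fe coordination recovers the spinel site split", {
  bulk <- replicate_cell(cell, 3, 3, 3)
  # interior copy of the full cell: atoms of the central cell
  cls <- classify_fe_sites(bulk)
  # compare against the brute-force neighbour scan
  ref <- oracle_fe_coordination(bulk, 2.35)
  expect_equal(cls$coordination, ref$coordination)
  # interior cell (surrounded on all sides) shows the 16:8 oct:tet split
  ctr <- attr(bulk, "box") / 2
  inner <- bulk$atom_id[abs(bulk$x - ctr[1]) < cell$a / 2 &
                        abs(bulk$y - ctr[2]) < cell$a / 2 &
                        abs(bulk$z - ctr[3]) < cell$a / 2]
  icls <- cls[cls$atom_id %in% inner & !is.na(cls$class), ]
  tab <- table(icls$class)
  expect_equal(as.integer(tab[["octahedral"]]), 16)
  expect_equal(as.integer(tab[["tetrahedral"]]), 8)
})

test_that("classification is invariant under rigid motion", {
  bulk <- replicate_cell(cell, 2, 2, 2)
  cls1 <- classify_fe_sites(bulk)
  moved <- translate_structure(
    rotate_structure(bulk, nanoforge:::rotation_about(c(1, 2, 3), 37)),
    c(5, -3, 11))
  cls2 <- classify_fe_sites(moved)
  expect_equal(cls1$coordination, cls2$coordination)
  expect_equal(cls1$class, cls2$class)
})

test_that("degenerate coordination inputs behave per contract", {
  lone <- nf_structure(tibble::tibble(element = c("Fe", "O"),
                                      x = c(0, 50), y = 0, z = 0))
  cls <- classify_fe_sites(lone)
  expect_equal(cls$coordination, 0L)
  expect_equal(cls$class, "undercoordinated-surface")
  no_o <- nf_structure(tibble::tibble(element = "Fe", x = 0, y = 0, z = 0))
  expect_error(classify_fe_sites(no_o), "no O atoms")
})

test_that("surface detection equals the per-face distance filter", {
  shape <- attr(core, "shape")
  surf <- detect_surface_atoms(core, shape, skin = 1.5)
  # brute force: distance below each boundary face plane
  face_ids <- as.integer(sub("^f", "", names(shape$faces)))
  nrm <- shape$normals[face_ids, , drop = FALSE]
  dd <- shape$d[face_ids]
  ref <- integer(0)
  for (r in seq_len(nrow(core))) {
    p <- c(core$x[r], core$y[r], core$z[r])
    gaps <- dd - as.numeric(nrm %*% p)
    if (min(gaps) <= 1.5 + 1e-9) ref <- c(ref, core$atom_id[r])
  }
  expect_setequal(surf$atom_id, ref)
  # normals are unit length
  expect_equal(sqrt(surf$nx^2 + surf$ny^2 + surf$nz^2),
               rep(1, nrow(surf)), tolerance = 1e-9)

  # skin larger than the particle: everything is surface
  all_surf <- detect_surface_atoms(core, shape, skin = 100)
  expect_equal(nrow(all_surf), nrow(core))

  # skin 0: only atoms exactly on a face plane
  on_plane <- detect_surface_atoms(core, shape, skin = 0)
  expect_true(all(on_plane$face_distance <= 1e-9))
})

test_that("graft site selection is uniform, capped and seeded", {
  sites <- select_graft_sites(core, n_chains = 64, seed = 1)
  expect_equal(nrow(sites), 64)
  expect_equal(anyDuplicated(sites$atom_id), 0)
  cls <- classify_fe_sites(core)
  picked <- cls[match(sites$atom_id, cls$atom_id), ]
  expect_true(all(picked$bulk_class == "octahedral"))

  expect_equal(nrow(select_graft_sites(core, n_chains = 0, seed = 1)), 0)

  n_cand <- sum(!is.na(cls$bulk_class) & cls$bulk_class == "octahedral" &
                  cls$atom_id %in% detect_surface_atoms(core, skin = 3)$atom_id)
  expect_error(select_graft_sites(core, n_chains = n_cand + 1, seed = 1),
               "capacity")

  # density mode: n = round(sigma * area)
  shape <- attr(core, "shape")
  dsites <- select_graft_sites(core, density = 1.0, seed = 1)
  expect_equal(nrow(dsites), round(shape$area / 100))
})

test_that("farthest-point packing is monotone in the request size", {
  minspace <- vapply(c(8, 16, 32, 64), function(n) {
    s <- select_graft_sites(core, n_chains = n, seed = 3)
    min(dist(cbind(s$x, s$y, s$z)))
  }, 1.0)
  expect_true(all(diff(minspace) <= 1e-9))
})

test_that("polyhedron surface area matches analytic single-family values", {
  cube <- wulff_shape(miller_facets(1, 0, 0), cell, 30)
  expect_equal(cube$area, 5400, tolerance = 1e-6)
  octa <- wulff_shape(miller_facets(1, 1, 1), cell, 30)
  a_oct <- 15 * sqrt(6)
  expect_equal(octa$area, 2 * sqrt(3) * a_oct^2, tolerance = 1e-6)
})
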