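test_that("magnetite fixture expands to the full spinel cell", {
  cell <- magnetite_cell()
  comp <- table(cell$sites$element)
  expect_equal(nrow(cell$sites), 56)
  expect_equal(as.integer(comp[["Fe"]]), 24)
  expect_equal(as.integer(comp[["O"]]), 32)
  # cubic lattice
  expect_equal(cell$a, cell$b)
  expect_equal(cell$b, cell$c)
  expect_equal(c(cell$alpha, cell$beta, cell$gamma), c(90, 90, 90))
  expect_equal(length(cell$symops), 192)
})

test_that("symmetry expansion matches an independent operator application", {
  cell <- magnetite_cell()
  # independent route: apply every operator to every asymmetric site, wrap
  # into [0,1), round, and deduplicate exactly
  pts <- NULL
  for (k in seq_len(nrow(cell$asym))) {
    r <- unlist(cell$asym[k, c("fx", "fy", "fz")])
    for (op in cell$symops) {
      p <- round(((op$M %*% r + op$t) %% 1), 6) %% 1
      pts <- rbind(pts, c(p))
    }
  }
  pts <- unique(pts)
  expect_equal(nrow(pts), 56)
  got <- round(as.matrix(cell$sites[, c("fx", "fy", "fz")]), 6) %% 1
  expect_setequal(apply(pts, 1, paste, collapse = ","),
                  apply(got, 1, paste, collapse = ","))
})

test_that("minimal and malformed CIFs behave per contract", {
  p1 <- minimal_p1_cif(withr::local_tempfile(fileext = ".cif"))
  cell <- read_cif(p1)
  expect_equal(nrow(cell$sites), 1)

  nolen <- minimal_p1_cif(withr::local_tempfile(fileext = ".cif"),
                          with_lengths = FALSE)
  expect_error(read_cif(nolen), "_cell_length")

  nosym <- minimal_p1_cif(withr::local_tempfile(fileext = ".cif"),
                          with_symops = FALSE)
  expect_error(read_cif(nosym), "symop")
  expect_equal(nrow(read_cif(nosym, p1_fallback = TRUE)$sites), 1)
})

test_that("symmetry operator parsing handles fractions and signs", {
  op <- nanoforge:::parse_symop("3/4-x,1/4+z,-y")
  expect_equal(op$t, c(0.75, 0.25, 0))
  expect_equal(op$M, matrix(c(-1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE))
  expect_error(nanoforge:::parse_symop("a,b,c"), "unparseable")
})

test_that("duplicate positions merge at the stated tolerance", {
  # two sites 1e-4 A apart must merge; 0.1 A apart must not
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_t", "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_space_group_symop_operation_xyz", "  'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "O1 O 0.100000 0.1 0.1",
    "O2 O 0.100001 0.1 0.1",
    "O3 O 0.110000 0.1 0.1"), path)
  cell <- read_cif(path)
  expect_equal(nrow(cell$sites), 2)
})
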