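test_that("bilayers hold exactly the requested lipid count per leaflet", {
  bl <- build_bilayer(489)
  lipids <- dplyr::distinct(tibble::as_tibble(bl), .data$molid, .data$leaflet)
  counts <- table(lipids$leaflet)
  expect_equal(as.integer(counts[["upper"]]), 489)
  expect_equal(as.integer(counts[["lower"]]), 489)
  expect_equal(attr(bl, "leaflet_area_nm2"), 489 * 0.63, tolerance = 1e-6)
})

test_that("small grids place lipids at the grid centres", {
  bl <- build_bilayer(4, area_per_lipid = 0.64)   # pitch exactly 8 A
  up_p <- tibble::as_tibble(bl) |>
    dplyr::filter(.data$leaflet == "upper", .data$name == "P")
  expect_equal(nrow(up_p), 4)
  expect_setequal(round(up_p$x, 6), c(4, 12))
  expect_setequal(round(up_p$y, 6), c(4, 12))
  expect_error(build_bilayer(0), "positive")
})

test_that("bilayer leaflets are mirror images with no overlaps", {
  bl <- build_bilayer(9)
  expect_gte(min_interatomic_distance(bl), 0.9)
  tb <- tibble::as_tibble(bl)
  up <- tb[tb$leaflet == "upper", ]; lo <- tb[tb$leaflet == "lower", ]
  expect_equal(nrow(up), nrow(lo))
  expect_equal(sort(abs(up$z)), sort(abs(lo$z)), tolerance = 1e-9)
})

test_that("solvation fills at bulk density and respects exclusions", {
  empty <- nf_structure(tibble::tibble(
    element = character(), x = numeric(), y = numeric(), z = numeric()))
  w <- solvate(empty, c(30, 30, 30))
  n_w <- nrow(w) / 3
  expect_lt(abs(n_w - 33.4 * 27) / (33.4 * 27), 0.05)

  # rigid template: all O-H distances identical
  ow <- w[w$name == "OW", ]; h1 <- w[w$name == "HW1", ]; h2 <- w[w$name == "HW2", ]
  d1 <- sqrt((ow$x - h1$x)^2 + (ow$y - h1$y)^2 + (ow$z - h1$z)^2)
  d2 <- sqrt((ow$x - h2$x)^2 + (ow$y - h2$y)^2 + (ow$z - h2$z)^2)
  expect_equal(unique(round(c(d1, d2), 9)), 0.9572)

  # determinism
  w2 <- solvate(empty, c(30, 30, 30))
  expect_identical(coords(w), coords(w2))

  # a solute filling the whole box leaves no room
  grid <- expand.grid(x = seq(1, 29, 2), y = seq(1, 29, 2), z = seq(1, 29, 2))
  solute <- nf_structure(tibble::tibble(element = "C", x = grid$x,
                                        y = grid$y, z = grid$z))
  packed <- solvate(solute, c(30, 30, 30))
  expect_equal(nrow(packed), nrow(solute))

  # no solute-water clash below the exclusion radius
  few <- nf_structure(tibble::tibble(element = "C", x = 15, y = 15, z = 15))
  sw <- solvate(few, c(30, 30, 30))
  wat_o <- sw[sw$name == "OW", ]
  dmin <- min(sqrt((wat_o$x - 15)^2 + (wat_o$y - 15)^2 + (wat_o$z - 15)^2))
  expect_gte(dmin, 2.4)

  expect_error(solvate(few, c(10, 10, 10)), "smaller than solute")
})

test_that("assembly places the particle at the requested gap and partitions atoms", {
  bl <- build_bilayer(25)
  g <- expand.grid(x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = seq(-2, 2, 2))
  np <- nf_structure(tibble::tibble(element = "Fe", resname = "CRY",
                                    x = g$x, y = g$y, z = g$z))
  sys <- assemble_system(np, bl, gap = 5, solvate_system = TRUE)
  expect_equal(sys$gap_realized, 5, tolerance = 0.1)
  expect_equal(sum(as.integer(sys$components)), nrow(sys$structure))
  expect_setequal(unique(sys$structure$component), c("np", "lipid", "water"))
  # no water oxygen within the exclusion radius of any solute atom
  wat_o <- sys$structure[sys$structure$component == "water" &
                           sys$structure$name == "OW", ]
  sol <- sys$structure[sys$structure$component != "water", ]
  d2 <- outer(rowSums(coords(wat_o)^2), rowSums(coords(sol)^2), "+") -
    2 * tcrossprod(coords(wat_o), coords(sol))
  expect_gte(sqrt(min(d2)), 2.4 - 1e-9)

  touching <- assemble_system(np, bl, gap = 0, solvate_system = FALSE)
  expect_equal(touching$gap_realized, 0, tolerance = 1e-9)

  wide <- nf_structure(tibble::tibble(element = "Fe", resname = "CRY",
                                      x = c(-100, 100), y = 0, z = 0))
  expect_error(assemble_system(wide, bl, gap = 5), "exceeds the bilayer")
})
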