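test_that("collinear and bent geometries follow the distance-angle criteria", {
  frame <- nf_structure(tibble::tibble(
    atom_id = 1:3, element = c("O", "H", "O"),
    resid = 1L, resname = "GAL",
    x = 0, y = 0, z = c(0, 0.96, 2.8)))   # collinear O-H...O, D-A 2.8 A
  bonds <- cbind(1L, 2L)
  recs <- detect_hbonds(frame, bonds, donors = 1L, acceptors = 3L)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$angle, 180, tolerance = 1e-6)
  expect_equal(recs$distance, 2.8, tolerance = 1e-9)

  # bend the acceptor to 90 degrees at the H: angle below the 150 cutoff
  bent <- frame
  bent$x[3] <- 2.0; bent$z[3] <- 0.96
  expect_equal(nrow(detect_hbonds(bent, bonds, 1L, 3L)), 0)

  # donor with no attached hydrogen is a configuration error
  expect_error(detect_hbonds(frame, matrix(0L, 0, 2), 1L, 3L),
               "configuration error")
  expect_error(detect_hbonds(frame, bonds, integer(0), 3L), "empty")
})

test_that("detector equals the all-pairs oracle on random frames", {
  crit <- default_hbond_criteria()
  for (seed in 1:6) {
    sc <- random_hbond_frame(n_heavy = 50, seed = seed)
    got <- detect_hbonds(sc$frame, sc$bonds, sc$donors, sc$acceptors, crit)
    ref <- oracle_hbonds(sc$frame, sc$bonds, sc$donors, sc$acceptors, crit)
    key <- function(df) if (is.null(df) || nrow(df) == 0) character(0) else
      sort(paste(df$donor, df$hydrogen, df$acceptor, df$class))
    expect_identical(key(got), key(ref))
  }
})

test_that("disabling CH...O never increases and enabling never decreases counts", {
  sc <- random_hbond_frame(n_heavy = 60, seed = 11)
  both <- detect_hbonds(sc$frame, sc$bonds, sc$donors, sc$acceptors,
                        default_hbond_criteria(include_ch_o = TRUE))
  oh <- detect_hbonds(sc$frame, sc$bonds, sc$donors, sc$acceptors,
                      default_hbond_criteria(include_ch_o = FALSE))
  expect_gte(nrow(both), nrow(oh))
  expect_identical(sort(paste(oh$donor, oh$acceptor)),
                   sort(paste(both$donor[both$class == "OH...O"],
                              both$acceptor[both$class == "OH...O"])))
})

test_that("summary recovers planted means", {
  # persistent: 2 galactose-phosphate bonds in every frame
  tr <- synth_hbond_trajectory(100, tibble::tibble(
    donor_resname = "GAL", group = "phosphate", count = 2, fraction = 1),
    seed = 5)
  sm <- hbond_summary(tr$frames, tr$bonds, tr$donors, tr$acceptors, tr$groups)
  cell <- sm[sm$donor_resname == "GAL" & sm$acceptor_group == "phosphate", ]
  expect_equal(cell$mean_bonds, 2.0, tolerance = 1e-12)

  # intermittent: present in about half the frames; compare to the exact
  # realized fraction and to 0.5 within 3 block SEs
  tr2 <- synth_hbond_trajectory(400, tibble::tibble(
    donor_resname = "ARA", group = "choline", count = 1, fraction = 0.5),
    seed = 9)
  sm2 <- hbond_summary(tr2$frames, tr2$bonds, tr2$donors, tr2$acceptors, tr2$groups)
  cell2 <- sm2[sm2$donor_resname == "ARA" & sm2$acceptor_group == "choline", ]
  expect_equal(cell2$mean_bonds, tr2$truth$mean_bonds, tolerance = 1e-12)
  expect_lt(abs(cell2$mean_bonds - 0.5), 3 * cell2$se + 1e-12)

  # no contacts: all cells zero
  tr3 <- synth_hbond_trajectory(10, tibble::tibble(
    donor_resname = "GAL", group = "phosphate", count = 1, fraction = 0),
    seed = 2)
  sm3 <- hbond_summary(tr3$frames, tr3$bonds, tr3$donors, tr3$acceptors, tr3$groups)
  expect_true(all(sm3$mean_bonds == 0))

  expect_error(hbond_summary(list(), tr$bonds, tr$donors, tr$acceptors,
                             tr$groups), "empty trajectory")
})

test_that("particle-membrane distance series is signed and monotone-faithful", {
  mk_frame <- function(np_z) nf_structure(tibble::tibble(
    atom_id = 1:4, element = c("Fe", "Fe", "P", "P"),
    name = c("FE", "FE", "P", "P"),
    x = c(0, 1, 0, 1), y = 0, z = c(np_z, np_z + 2, 0, 0)))
  frames <- lapply(c(10, 7, 5, 2, -1), mk_frame)
  ds <- np_membrane_distance(frames, np_ids = 1:2, p_ids = 3:4)
  expect_equal(ds$distance, c(10, 7, 5, 2, -1))
  expect_true(all(diff(ds$distance) < 0))
  expect_lte(ds$distance[5], 0)   # penetration flips the sign
  expect_error(np_membrane_distance(frames, integer(0), 3:4), "empty")
})

test_that("SNR follows the 0.655 formula and its scaling invariance", {
  im <- synth_roi_image(tumor_mean = 100, background_mean = 100, noise_sd = 0)
  expect_equal(snr(im$image, im$tumor_mask, im$background_masks)$snr, 0.655)

  im2 <- synth_roi_image(tumor_mean = 131, background_mean = 65.5, noise_sd = 0)
  expect_equal(snr(im2$image, im2$tumor_mask, im2$background_masks)$snr, 1.310)

  # homogeneous of degree zero in global intensity
  r1 <- snr(im2$image, im2$tumor_mask, im2$background_masks)$snr
  r2 <- snr(im2$image * 7.3, im2$tumor_mask, im2$background_masks)$snr
  expect_equal(r1, r2, tolerance = 1e-12)

  empty_mask <- matrix(FALSE, nrow(im$image), ncol(im$image))
  expect_error(snr(im$image, empty_mask, im$background_masks), "empty tumor")
  expect_error(snr(im$image, im$tumor_mask, empty_mask), "background")
})

test_that("CNR and tumor volume are the printed formulas", {
  expect_equal(cnr(10, 3)$cnr, 7)
  expect_equal(cnr(5, 5)$cnr, 0)
  res <- cnr(3, 10)
  expect_equal(res$cnr, -7)
  expect_equal(res$magnitude, 7)

  expect_equal(tumor_volume(2, 1), 1)
  expect_equal(tumor_volume(0, 5), 0)
  expect_equal(tumor_volume(5, 0), 0)
  expect_equal(tumor_volume(10, 4), 80)
  expect_error(tumor_volume(-1, 2), "non-negative")
})

test_that("DPPC acceptor groups pick the named phosphate and choline atoms", {
  bl <- build_bilayer(4)
  gr <- lipid_acceptor_groups(bl)
  tb <- tibble::as_tibble(bl)
  expect_setequal(unique(tb$name[tb$atom_id %in% gr$phosphate]),
                  c("P", "O11", "O12", "O13", "O14"))
  expect_true(all(c("N", "C13", "C14", "C15") %in%
                    tb$name[tb$atom_id %in% gr$choline]))
  expect_length(intersect(gr$phosphate, gr$choline), 0)
})
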