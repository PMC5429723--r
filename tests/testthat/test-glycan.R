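templates <- monomer_templates()

test_that("monomer templates satisfy their invariants", {
  for (rn in c("ARA", "GAL", "RHA", "GLA")) {
    tpl <- templates[[rn]]
    expect_true(tpl$upstream %in% tpl$atoms$name)
    expect_true(tpl$downstream_main %in% tpl$atoms$name)
    expect_equal(sum(tpl$atoms$charge), tpl$formal_charge, tolerance = 1e-4)
    # bond graph is connected (checked at load; assert again on the result)
    lab <- nanoforge:::graph_components(nrow(tpl$atoms), tpl$bonds)
    expect_equal(length(unique(lab)), 1)
  }
  expect_equal(templates$GLA$formal_charge, -1)
})

test_that("chain composition is exactly 3:3:1:1 per repeat", {
  s1 <- compose_chain(1)
  cnt <- table(s1$resname)
  expect_equal(as.integer(cnt[c("ARA", "GAL", "RHA", "GLA")]), c(3, 3, 1, 1))

  s3 <- compose_chain(3)
  expect_equal(nrow(s3), 24)
  cnt3 <- table(s3$resname)
  expect_equal(as.integer(cnt3[c("ARA", "GAL", "RHA", "GLA")]), c(9, 9, 3, 3))
  # forced ratio for any repeat count
  for (n in c(1, 2, 5)) {
    cc <- table(compose_chain(n)$resname)
    expect_equal((cc[["ARA"]] + cc[["GAL"]]) / (cc[["RHA"]] + cc[["GLA"]]), 3)
  }
  expect_error(compose_chain(0), "n_repeats")
})

test_that("built chains hit the target length and stay clash-free", {
  chain <- build_chain_geometry(target_length = 6.5, templates = templates)
  len <- attr(chain, "length_nm")
  expect_gte(len, 6.37)
  expect_lte(len, 6.63)
  expect_gte(min_interatomic_distance(chain), 0.9)
  # residue connectivity is a tree: exactly (#residues - 1) glycosidic links
  expect_equal(nrow(attr(chain, "glyco_bonds")),
               nrow(attr(chain, "sequence")) - 1)
  # deterministic construction
  chain2 <- build_chain_geometry(target_length = 6.5, templates = templates)
  expect_identical(coords(chain), coords(chain2))
})

test_that("extended-chain length is additive in the repeat count", {
  s2 <- compose_chain(2); s4 <- compose_chain(4)
  c2 <- nanoforge:::place_chain(s2, templates, tilt = 10)
  c4 <- nanoforge:::place_chain(s4, templates, tilt = 10)
  l2 <- nanoforge:::measured_length(c2)
  l4 <- nanoforge:::measured_length(c4)
  expect_lt(abs(l4 / l2 - 2), 0.05 * 2)
})

test_that("a single-residue chain spans its template extent", {
  seq1 <- tibble::tibble(residue_index = 1L, resname = "GAL",
                         role = "backbone", parent = NA_integer_,
                         backbone_position = 1L)
  ch <- nanoforge:::place_chain(seq1, templates, tilt = 0)
  got <- nanoforge:::measured_length(ch)
  tpl <- templates$GAL$atoms
  o1 <- unlist(tpl[tpl$name == "O1", c("x", "y", "z")])
  ref <- max(sqrt(colSums((t(as.matrix(tpl[, c("x", "y", "z")])) - o1)^2)))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("impossible chain lengths raise geometry errors", {
  expect_error(build_chain_geometry(target_length = 0.2,
                                    templates = templates), "geometry error")
})

test_that("attaching zero chains leaves the core untouched", {
  cell <- magnetite_cell()
  core <- carve_core(cell, miller_facets(1, 0, 0), 20, verbose = FALSE)
  sites <- select_graft_sites(core, n_chains = 0, seed = 1)
  chain <- build_chain_geometry(target_length = 2.3, templates = templates)
  out <- attach_chains(core, sites, chain)
  expect_equal(nrow(out), nrow(core))
  expect_identical(coords(out), coords(core))
})

test_that("grafted chains bond to Fe and renumber cleanly", {
  cell <- magnetite_cell()
  core <- carve_core(cell, miller_facets(1, 0, 0), 20, verbose = FALSE)
  sites <- select_graft_sites(core, n_chains = 4, seed = 2)
  chain <- build_chain_geometry(target_length = 2.3, templates = templates)
  np <- attach_chains(core, sites, chain)
  lb <- attr(np, "link_bonds")
  expect_equal(nrow(lb), 4)
  expect_true(all(lb[, 1] %in% sites$atom_id))
  # each link joins an Fe to the chain's root oxygen at ~1.95 A
  for (r in seq_len(nrow(lb))) {
    fe <- np[np$atom_id == lb[r, 1], ]; o <- np[np$atom_id == lb[r, 2], ]
    expect_equal(fe$element, "Fe"); expect_equal(o$element, "O")
    d <- sqrt((fe$x - o$x)^2 + (fe$y - o$y)^2 + (fe$z - o$z)^2)
    expect_equal(d, 1.95, tolerance = 1e-6)
  }
  expect_equal(anyDuplicated(np$atom_id), 0)
  expect_gte(min_interatomic_distance(np), 0.9)
  # residue bookkeeping: core + 4 chains x residues per chain
  expect_equal(max(np$resid), 1 + 4 * nrow(attr(chain, "sequence")))
})

test_that("an engineered clash raises a placement error", {
  cell <- magnetite_cell()
  core <- carve_core(cell, miller_facets(1, 0, 0), 20, verbose = FALSE)
  chain <- build_chain_geometry(target_length = 2.3, templates = templates)
  # two fake sites 0.5 A apart with identical normals cannot both host
  fe_ids <- core$atom_id[core$element == "Fe"][1:2]
  s <- tibble::tibble(atom_id = fe_ids,
                      x = c(0, 0.5), y = 0, z = c(10, 10),
                      nx = 0, ny = 0, nz = 1)
  one <- attach_chain(core[core$atom_id %in% fe_ids, ], s[1, ], chain)
  expect_error(attach_chain(one, s[2, ], chain), "placement error")
})

test_that("chain charges stay integral through linking", {
  chain <- build_chain_geometry(target_length = 6.5, templates = templates)
  nrep <- attr(chain, "n_repeats")
  expect_equal(sum(chain$charge), -(nrep + 1), tolerance = 1e-6)
  expect_equal(attr(chain, "formal_charge"), -(nrep + 1))
})
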