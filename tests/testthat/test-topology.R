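test_that("tiny molecules enumerate by hand-countable results", {
  bent <- nf_structure(tibble::tibble(element = "O", x = c(0, 1, 2),
                                      y = c(0, 1, 0), z = 0))
  t1 <- enumerate_topology(bent, cbind(c(1, 2), c(2, 3)))
  expect_equal(nrow(t1$bonds), 2)
  expect_equal(nrow(t1$angles), 1)
  expect_equal(unlist(t1$angles[1, ]), c(i = 1, j = 2, k = 3))
  expect_equal(nrow(t1$dihedrals), 0)

  lin4 <- nf_structure(tibble::tibble(element = "C", x = 1:4, y = 0, z = 0))
  t2 <- enumerate_topology(lin4, cbind(1:3, 2:4))
  expect_equal(glance(t2)[, 1:3],
               tibble::tibble(n_bonds = 3L, n_angles = 2L, n_dihedrals = 1L))
  expect_equal(unlist(t2$dihedrals[1, ]), c(i = 1, j = 2, k = 3, l = 4))
})

test_that("random graphs match the exhaustive path-enumeration oracle", {
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(5:30, 1)
    edges <- random_bond_graph(n, extra = sample(0:4, 1))
    s <- nf_structure(tibble::tibble(element = "C", x = seq_len(n), y = 0, z = 0))
    topo <- enumerate_topology(s, edges)
    ref_ang <- oracle_paths(seq_len(n), edges, 2)
    ref_dih <- oracle_paths(seq_len(n), edges, 3)
    expect_identical(unname(as.matrix(topo$angles)), unname(ref_ang))
    expect_identical(unname(as.matrix(topo$dihedrals)), unname(ref_dih))
    # angle count identity: sum over vertices of C(deg, 2)
    deg <- table(factor(c(edges[, 1], edges[, 2]), levels = seq_len(n)))
    expect_equal(nrow(topo$angles), sum(choose(as.integer(deg), 2)))
  }
})

test_that("shuffled bond lists yield the identical canonical topology", {
  set.seed(7)
  edges <- random_bond_graph(20, extra = 5)
  s <- nf_structure(tibble::tibble(element = "C", x = 1:20, y = 0, z = 0))
  t1 <- enumerate_topology(s, edges)
  shuffled <- edges[sample(nrow(edges)), c(2, 1)]
  t2 <- enumerate_topology(s, shuffled)
  expect_identical(t1$bonds, t2$bonds)
  expect_identical(t1$angles, t2$angles)
  expect_identical(t1$dihedrals, t2$dihedrals)
})

test_that("malformed bonds raise topology errors", {
  s <- nf_structure(tibble::tibble(element = "C", x = 1:3, y = 0, z = 0))
  expect_error(enumerate_topology(s, cbind(1, 1)), "self-bond")
  expect_error(enumerate_topology(s, cbind(1, 9)), "absent")
})

test_that("charge assignment uses templates, scheme, and reports offenders", {
  tpl <- monomer_templates()$GAL$atoms
  s <- nf_structure(tibble::tibble(
    atom_id = seq_len(nrow(tpl)), element = tpl$element, name = tpl$name,
    resname = "GAL", x = tpl$x, y = tpl$y, z = tpl$z, charge = tpl$charge))
  topo <- assign_charges(s, enumerate_topology(s, monomer_templates()$GAL$bonds))
  expect_equal(topo$net_charge, 0, tolerance = 1e-4)

  core <- replicate_cell(magnetite_cell(), 1, 1, 1)
  topo2 <- assign_charges(core, enumerate_topology(core, guess_bonds(core)))
  expect_equal(topo2$net_charge, 0, tolerance = 1e-9)  # 24*1.2 - 32*0.9

  bad <- nf_structure(tibble::tibble(element = "Xx", resname = "ZZZ",
                                     x = 0, y = 0, z = 0))
  expect_error(assign_charges(bad, enumerate_topology(bad, matrix(0L, 0, 2))),
               "Xx_ZZZ")
})

test_that("net charge is invariant under atom reordering", {
  chain <- build_chain_geometry(target_length = 2.3)
  topo <- assign_charges(chain, enumerate_topology(chain, attr(chain, "glyco_bonds")))
  perm <- sample(nrow(chain))
  topo2 <- assign_charges(chain[perm, ],
                          enumerate_topology(chain[perm, ], attr(chain, "glyco_bonds")))
  expect_equal(topo$net_charge, topo2$net_charge, tolerance = 1e-9)
})

test_that("system files round-trip counts, charges and coordinates", {
  chain <- build_chain_geometry(target_length = 2.3)
  bonds <- guess_bonds(chain)
  topo <- assign_charges(chain, enumerate_topology(chain, bonds))
  gro <- withr::local_tempfile(fileext = ".gro")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  top <- withr::local_tempfile(fileext = ".top")
  write_system(chain, topo, gro = gro, pdb = pdb, top = top)

  back <- read_topology(top)
  expect_equal(nrow(back$bonds), nrow(topo$bonds))
  expect_equal(nrow(back$angles), nrow(topo$angles))
  expect_equal(nrow(back$dihedrals), nrow(topo$dihedrals))
  expect_equal(back$net_charge, topo$net_charge, tolerance = 1e-3)

  g <- read_gro(gro)
  expect_equal(nrow(g), nrow(chain))
  expect_lt(max(abs(coords(g) - coords(chain))), 0.01 + 1e-9)  # 0.001 nm

  p <- read_pdb(pdb)
  expect_equal(nrow(p), nrow(chain))
  expect_lt(max(abs(coords(p) - coords(chain))), 0.001 + 1e-9)
  expect_equal(p$element, chain$element)
})

test_that("empty structures write valid empty-section files", {
  empty <- nf_structure(tibble::tibble(
    atom_id = integer(), element = character(), name = character(),
    resid = integer(), resname = character(), molid = integer(),
    x = numeric(), y = numeric(), z = numeric()))
  topo <- enumerate_topology(empty, matrix(0L, 0, 2))
  topo$net_charge <- 0
  top <- withr::local_tempfile(fileext = ".top")
  gro <- withr::local_tempfile(fileext = ".gro")
  write_system(empty, topo, gro = gro, top = top)
  back <- read_topology(top)
  expect_equal(nrow(back$bonds), 0)
  expect_equal(nrow(read_gro(gro)), 0)
})
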