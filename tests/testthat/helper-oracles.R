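# Independent brute-force oracles. These deliberately re-derive results by
# the most naive method available and share no code with the package paths
# they check.

# vertices of the polytope {x : n_i . x <= d_i} by dense enumeration over all
# plane triples, feasibility-filtered
oracle_halfspace_vertices <- function(normals, d, tol = 1e-7) {
  m <- nrow(normals)
  verts <- NULL
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    A <- normals[c(i, j, k), , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    v <- solve(A, d[c(i, j, k)])
    if (all(normals %*% v <= d + tol * max(d))) verts <- rbind(verts, v)
  }
  verts <- verts[!duplicated(round(verts, 6)), , drop = FALSE]
  verts[order(verts[, 1], verts[, 2], verts[, 3]), , drop = FALSE]
}

# naive per-atom inequality filter for carving
oracle_carve_ids <- function(bulk, shape, center) {
  keep <- logical(nrow(bulk))
  for (r in seq_len(nrow(bulk))) {
    p <- c(bulk$x[r], bulk$y[r], bulk$z[r]) - center
    keep[r] <- all(shape$normals %*% p <= shape$d + 1e-6)
  }
  sort(bulk$atom_id[keep])
}

# brute-force O neighbour count per Fe atom
oracle_fe_coordination <- function(structure, cutoff) {
  fe <- which(structure$element == "Fe")
  ox <- which(structure$element == "O")
  out <- integer(length(fe))
  for (a in seq_along(fe)) {
    i <- fe[a]
    n <- 0L
    for (j in ox) {
      dd <- sqrt((structure$x[i] - structure$x[j])^2 +
                 (structure$y[i] - structure$y[j])^2 +
                 (structure$z[i] - structure$z[j])^2)
      if (dd <= cutoff + 1e-9) n <- n + 1L
    }
    out[a] <- n
  }
  data.frame(atom_id = structure$atom_id[fe], coordination = out)
}

# exhaustive path enumeration on a bond graph: all simple paths of length
# `len` edges, canonicalised (smaller endpoint first) and deduplicated
oracle_paths <- function(ids, bonds, len) {
  adj <- lapply(stats::setNames(seq_along(ids), ids), function(i) integer(0))
  for (r in seq_len(nrow(bonds))) {
    a <- as.character(bonds[r, 1]); b <- as.character(bonds[r, 2])
    adj[[a]] <- union(adj[[a]], bonds[r, 2])
    adj[[b]] <- union(adj[[b]], bonds[r, 1])
  }
  paths <- list()
  walk <- function(path) {
    if (length(path) == len + 1) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nxt in adj[[as.character(path[length(path)])]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  for (v in ids) walk(v)
  if (!length(paths)) return(matrix(integer(0), 0, len + 1))
  mat <- do.call(rbind, paths)
  rev_ <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  # lexicographic canonicalisation on the integer tuples
  for (r in which(tuple_gt(mat, rev_))) mat[r, ] <- rev_[r, ]
  mat <- mat[!duplicated(mat), , drop = FALSE]
  mat[do.call(order, as.data.frame(mat)), , drop = FALSE]
}

# rowwise lexicographic a > b for integer matrices
tuple_gt <- function(a, b) {
  out <- rep(FALSE, nrow(a))
  undecided <- rep(TRUE, nrow(a))
  for (c_ in seq_len(ncol(a))) {
    gt <- undecided & a[, c_] > b[, c_]
    lt <- undecided & a[, c_] < b[, c_]
    out[gt] <- TRUE
    undecided <- undecided & !gt & !lt
  }
  out
}

# random connected bond graph on n atoms (spanning tree + extra edges)
random_bond_graph <- function(n, extra = 3) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  for (k in seq_len(extra)) {
    cand <- sort(sample.int(n, 2))
    edges <- rbind(edges, cand)
  }
  edges <- unique(t(apply(edges, 1, sort)))
  edges[edges[, 1] != edges[, 2], , drop = FALSE]
}

# O(N^2) all-pairs hydrogen-bond scan
oracle_hbonds <- function(frame, bonds, donors, acceptors, criteria) {
  idx <- stats::setNames(seq_len(nrow(frame)), frame$atom_id)
  b2 <- rbind(as.matrix(bonds), as.matrix(bonds)[, 2:1, drop = FALSE])
  recs <- NULL
  for (d_id in donors) {
    del <- frame$element[idx[as.character(d_id)]]
    cls <- if (del == "C") "CH...O" else "OH...O"
    crit <- criteria[criteria$class == cls, ]
    if (nrow(crit) == 0) next
    hs <- b2[b2[, 1] == d_id, 2]
    hs <- hs[frame$element[idx[as.character(hs)]] == "H"]
    for (a_id in acceptors) {
      if (a_id == d_id) next
      dp <- unlist(frame[idx[as.character(d_id)], c("x", "y", "z")])
      ap <- unlist(frame[idx[as.character(a_id)], c("x", "y", "z")])
      dda <- sqrt(sum((dp - ap)^2))
      if (dda > crit$dist_max || dda < 1e-6) next
      for (h_id in hs) {
        hp <- unlist(frame[idx[as.character(h_id)], c("x", "y", "z")])
        v1 <- dp - hp; v2 <- ap - hp
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= crit$angle_min) {
          recs <- rbind(recs, data.frame(donor = d_id, hydrogen = h_id,
                                         acceptor = a_id, class = cls))
        }
      }
    }
  }
  recs
}

# random frame of O/C/H atoms with H bonded to heavy atoms
random_hbond_frame <- function(n_heavy = 60, seed = 1) {
  set.seed(seed)
  heavy <- tibble::tibble(
    atom_id = seq_len(n_heavy),
    element = sample(c("O", "C"), n_heavy, replace = TRUE),
    x = runif(n_heavy, 0, 25), y = runif(n_heavy, 0, 25),
    z = runif(n_heavy, 0, 25))
  # one H on a random subset of the heavy atoms
  has_h <- sort(sample.int(n_heavy, round(n_heavy * 0.7)))
  hs <- tibble::tibble(
    atom_id = n_heavy + seq_along(has_h),
    element = "H",
    x = heavy$x[has_h] + rnorm(length(has_h), 0, 0.4),
    y = heavy$y[has_h] + rnorm(length(has_h), 0, 0.4),
    z = heavy$z[has_h] + rnorm(length(has_h), 0, 0.4))
  frame <- nf_structure(dplyr::bind_rows(heavy, hs))
  bonds <- cbind(has_h, hs$atom_id)
  donors <- heavy$atom_id[has_h]
  acceptors <- heavy$atom_id[heavy$element == "O"]
  list(frame = frame, bonds = bonds, donors = donors, acceptors = acceptors)
}

# small helper: minimal CIF text
minimal_p1_cif <- function(path, atom_line = "X1 X 0.0 0.0 0.0",
                           with_symops = TRUE, with_lengths = TRUE) {
  lines <- c("data_minimal")
  if (with_lengths) {
    lines <- c(lines,
               "_cell_length_a 5.0", "_cell_length_b 5.0", "_cell_length_c 5.0")
  }
  lines <- c(lines,
             "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90")
  if (with_symops) {
    lines <- c(lines, "loop_", "_space_group_symop_operation_xyz", "  'x,y,z'")
  }
  lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             atom_line)
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
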