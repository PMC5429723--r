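#' Enumerate bonds, angles and dihedrals from a bond list
#'
#' Angles are all simple paths of length two (the central atom in the middle)
#' and proper dihedrals all simple paths of length three, in canonical
#' orientation (the lexicographically smaller endpoint first), deduplicated.
#' This is the combinatorial step of building MD topology files for systems
#' the standard force-field tools do not cover, such as an oxide core with
#' grafted ligands.
#'
#' @param structure atom tibble.
#' @param bonds two-column matrix / data frame of atom-id pairs.
#' @return object of class `topology_set`: list with `bonds` (tibble `i`,`j`),
#'   `angles` (`i`,`j`,`k`; `j` central), `dihedrals` (`i`,`j`,`k`,`l`),
#'   `charges` (per-atom tibble, `NA` until [assign_charges()]), `net_charge`.
#' @examples
#' s <- nf_structure(tibble::tibble(element = "C", x = 1:4, y = 0, z = 0))
#' enumerate_topology(s, cbind(1:3, 2:4))  # 3 bonds, 2 angles, 1 dihedral
#' @export
enumerate_topology <- function(structure, bonds) {
  bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
  storage.mode(bonds) <- "integer"
  ids <- structure$atom_id
  if (nrow(bonds) > 0) {
    if (any(!(bonds %in% ids))) {
      stop("topology error: bond references atom id(s) absent from the ",
           "structure: ", paste(utils::head(setdiff(as.vector(bonds), ids), 5),
                                collapse = ", "), call. = FALSE)
    }
    if (any(bonds[, 1] == bonds[, 2])) {
      stop("topology error: self-bond", call. = FALSE)
    }
  }
  # canonical bonds, deduplicated
  b <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  b <- unique(b)
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]

  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  adj <- lapply(adj, function(v) sort(unique(v)))
  nb <- function(v) adj[[as.character(v)]]

  # angles: choose 2 neighbours of every central atom
  ang <- list()
  for (jc in names(adj)) {
    nbs <- adj[[jc]]
    if (length(nbs) >= 2) {
      pairs <- utils::combn(nbs, 2)
      ang[[jc]] <- cbind(pairs[1, ], as.integer(jc), pairs[2, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    matrix(integer(0), 0, 3)
  if (nrow(angles) > 0) {
    flip <- angles[, 1] > angles[, 3]
    angles[flip, ] <- angles[flip, c(3, 2, 1)]
    angles <- unique(angles)
    angles <- angles[order(angles[, 1], angles[, 2], angles[, 3]), , drop = FALSE]
  }

  # dihedrals: extend every central bond j-k by a!=k and l!=j, a!=l
  dih <- list()
  for (r in seq_len(nrow(b))) {
    jj <- b[r, 1]; kk <- b[r, 2]
    as_ <- setdiff(nb(jj), kk)
    ls_ <- setdiff(nb(kk), jj)
    if (length(as_) && length(ls_)) {
      g <- expand.grid(i = as_, l = ls_)
      g <- g[g$i != g$l, , drop = FALSE]  # exclude 3-rings traversed twice
      if (nrow(g)) dih[[length(dih) + 1]] <- cbind(g$i, jj, kk, g$l)
    }
  }
  dihedrals <- if (length(dih)) do.call(rbind, dih) else
    matrix(integer(0), 0, 4)
  if (nrow(dihedrals) > 0) {
    flip <- dihedrals[, 1] > dihedrals[, 4] |
      (dihedrals[, 1] == dihedrals[, 4] & dihedrals[, 2] > dihedrals[, 3])
    dihedrals[flip, ] <- dihedrals[flip, c(4, 3, 2, 1)]
    dihedrals <- unique(dihedrals)
    dihedrals <- dihedrals[order(dihedrals[, 1], dihedrals[, 2],
                                 dihedrals[, 3], dihedrals[, 4]), , drop = FALSE]
  }

  dimnames(b) <- dimnames(angles) <- dimnames(dihedrals) <- NULL
  structure(list(
    bonds = tibble::tibble(i = b[, 1], j = b[, 2]),
    angles = tibble::tibble(i = angles[, 1], j = angles[, 2], k = angles[, 3]),
    dihedrals = tibble::tibble(i = dihedrals[, 1], j = dihedrals[, 2],
                               k = dihedrals[, 3], l = dihedrals[, 4]),
    charges = tibble::tibble(atom_id = ids, charge = NA_real_,
                             type = paste0(structure$element, "_",
                                           structure$resname)),
    net_charge = NA_real_), class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  cat("# Topology:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals\n")
  if (!is.na(x$net_charge)) cat(sprintf("# Net charge %+.4f e\n", x$net_charge))
  invisible(x)
}

#' @rdname enumerate_topology
#' @param x a `topology_set`.
#' @param ... unused.
#' @return `glance()`: one-row tibble of counts and net charge.
#' @export
glance.topology_set <- function(x, ...) {
  tibble::tibble(n_bonds = nrow(x$bonds), n_angles = nrow(x$angles),
                 n_dihedrals = nrow(x$dihedrals), net_charge = x$net_charge)
}

#' Default partial-charge scheme
#'
#' Ligand atoms carry per-atom charges from the monomer templates (the
#' structure's `charge` column). The oxide core takes scheme charges: the
#' defaults Fe +1.2 e / O -0.9 e keep a stoichiometric Fe3O4 cell exactly
#' neutral; they are placeholders (the force-field values are not published)
#' and are meant to be overridden.
#'
#' @param fe,o core iron and oxygen charges (e).
#' @param extra named numeric vector of additional `element_resname` types.
#' @return named list used by [assign_charges()].
#' @export
charge_scheme <- function(fe = 1.2, o = -0.9, extra = NULL) {
  sch <- list(Fe_CRY = fe, O_CRY = o)
  if (!is.null(extra)) sch <- utils::modifyList(sch, as.list(extra))
  sch
}

#' Assign per-atom partial charges
#'
#' Atoms with a `charge` column value (grafted ligands, lipids, waters) keep
#' it; remaining atoms are looked up in the scheme by `element_resname` type.
#' Unmapped atoms are an explicit error listing the offenders.
#'
#' @param structure atom tibble.
#' @param topology `topology_set` from [enumerate_topology()].
#' @param scheme from [charge_scheme()].
#' @return the topology with `charges$charge` filled and `net_charge` set.
#' @export
assign_charges <- function(structure, topology, scheme = charge_scheme()) {
  q <- if ("charge" %in% names(structure)) structure$charge else
    rep(NA_real_, nrow(structure))
  type <- paste0(structure$element, "_", structure$resname)
  miss <- is.na(q)
  q[miss] <- unlist(scheme)[type[miss]]
  if (anyNA(q)) {
    bad <- unique(type[is.na(q)])
    stop("charge scheme error: no charge for atom type(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  topology$charges <- tibble::tibble(atom_id = structure$atom_id,
                                     charge = q, type = type)
  topology$net_charge <- sum(q)
  topology
}

#' Infer bonds from interatomic distances
#'
#' Element-pair cutoffs: H binds its nearest heavy atom within 1.2 A; heavy
#' pairs bind within covalent-ish cutoffs (default 1.75 A, Fe-O 2.35 A, the
#' same cutoff that defines the coordination shells of the oxide).
#'
#' @param structure atom tibble.
#' @param heavy_cutoff generic heavy-heavy cutoff (A).
#' @param fe_o_cutoff Fe-O cutoff (A).
#' @param h_cutoff maximum H-heavy bond length (A).
#' @return integer matrix of atom-id pairs.
#' @export
guess_bonds <- function(structure, heavy_cutoff = 1.75, fe_o_cutoff = 2.35,
                        h_cutoff = 1.2) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  el <- structure$element
  maxcut <- max(heavy_cutoff, fe_o_cutoff, h_cutoff)
  pairs <- neighbor_pairs(xyz, maxcut)
  if (nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  e1 <- el[pairs[, 1]]; e2 <- el[pairs[, 2]]
  ish <- (e1 == "H") + (e2 == "H")
  feo <- (e1 == "Fe" & e2 == "O") | (e1 == "O" & e2 == "Fe")
  cut <- ifelse(ish == 2, -1,                  # H-H never bonds
                ifelse(ish == 1, h_cutoff, ifelse(feo, fe_o_cutoff, heavy_cutoff)))
  keep <- d <= cut
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  e1 <- el[pairs[, 1]]; e2 <- el[pairs[, 2]]
  # each H keeps only its nearest partner
  hsel <- e1 == "H" | e2 == "H"
  if (any(hsel)) {
    hp <- pairs[hsel, , drop = FALSE]; hd <- d[hsel]
    hid <- ifelse(el[hp[, 1]] == "H", hp[, 1], hp[, 2])
    ord <- order(hid, hd)
    keep_h <- !duplicated(hid[ord])
    pairs <- rbind(pairs[!hsel, , drop = FALSE], hp[ord, , drop = FALSE][keep_h, , drop = FALSE])
  }
  ids <- structure$atom_id
  cbind(ids[pairs[, 1]], ids[pairs[, 2]])
}

# all index pairs within cutoff, via grid hashing (memory-bounded)
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  key <- floor(xyz / cutoff)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  cellmap <- split(seq_len(n), kstr)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- list()
  for (cellname in names(cellmap)) {
    i <- cellmap[[cellname]]
    k0 <- key[i[1], ]
    neigh <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      kk <- paste(k0[1] + offsets[r, 1], k0[2] + offsets[r, 2], k0[3] + offsets[r, 3])
      j <- cellmap[[kk]]
      if (!is.null(j)) neigh <- c(neigh, j)
    }
    a <- xyz[i, , drop = FALSE]; b <- xyz[neigh, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      p <- cbind(i[hit[, 1]], neigh[hit[, 2]])
      p <- p[p[, 1] < p[, 2], , drop = FALSE]
      if (nrow(p)) out[[length(out) + 1]] <- p
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, out))
}

#' Collect the full bond list of an assembled particle
#'
#' Fe-O network of the core (within cutoff), intra-residue template bonds of
#' the ligands, glycosidic links, and the Fe-O graft links recorded by
#' [attach_chains()].
#'
#' @param np functionalized particle from [attach_chains()].
#' @param frozen_core if `TRUE`, the magnetite core contributes no internal
#'   bonds (restrained-core convention); graft links are kept either way.
#' @return two-column matrix of atom-id pairs.
#' @export
system_bonds <- function(np, frozen_core = FALSE) {
  np_t <- tibble::as_tibble(np)
  parts <- list()
  cry <- np_t[np_t$resname == "CRY", , drop = FALSE]
  lig <- np_t[np_t$resname != "CRY", , drop = FALSE]
  if (!frozen_core && nrow(cry) > 1) {
    parts$core <- guess_bonds(nf_structure(cry))
  }
  if (nrow(lig) > 1) parts$lig <- guess_bonds(nf_structure(lig))
  parts$glyco <- attr(np, "glyco_bonds")
  parts$links <- attr(np, "link_bonds")
  do.call(rbind, parts)
}

#' Write coordinates and topology as MD-engine text files
#'
#' Writes the structure as GRO (nm) and PDB (A), and the topology in a plain
#' sectioned text dialect: `[ atoms ]` (id, type, resid, resname, name,
#' charge), `[ bonds ]`, `[ angles ]`, `[ dihedrals ]` — the conventional
#' shape of a GROMACS-style topology stripped of force-field parameters
#' (which this package deliberately does not ship).
#'
#' @param structure atom tibble.
#' @param topology `topology_set` with charges assigned.
#' @param gro,pdb,top output paths (any may be `NULL` to skip).
#' @return named list of the files written, invisibly.
#' @export
write_system <- function(structure, topology, gro = NULL, pdb = NULL,
                         top = NULL) {
  if (nrow(topology$charges) != nrow(structure) ||
      !all(topology$charges$atom_id == structure$atom_id)) {
    stop("atom count/id mismatch between structure and topology", call. = FALSE)
  }
  out <- list()
  if (!is.null(gro)) out$gro <- write_gro(structure, gro)
  if (!is.null(pdb)) out$pdb <- write_pdb(structure, pdb)
  if (!is.null(top)) {
    con <- file(top, "w"); on.exit(close(con))
    ch <- topology$charges
    writeLines("; topology written by nanoforge", con)
    writeLines("[ atoms ]", con)
    if (nrow(ch)) {
      writeLines(sprintf("%8d %-12s %6d %-5s %-5s %10.4f",
                         structure$atom_id, ch$type, structure$resid,
                         structure$resname, structure$name, ch$charge), con)
    }
    writeLines("[ bonds ]", con)
    if (nrow(topology$bonds))
      writeLines(sprintf("%8d %8d", topology$bonds$i, topology$bonds$j), con)
    writeLines("[ angles ]", con)
    if (nrow(topology$angles))
      writeLines(sprintf("%8d %8d %8d", topology$angles$i, topology$angles$j,
                         topology$angles$k), con)
    writeLines("[ dihedrals ]", con)
    if (nrow(topology$dihedrals))
      writeLines(sprintf("%8d %8d %8d %8d", topology$dihedrals$i,
                         topology$dihedrals$j, topology$dihedrals$k,
                         topology$dihedrals$l), con)
    out$top <- top
  }
  invisible(out)
}

#' Read back a topology text file written by [write_system()]
#' @param path topology file.
#' @return `topology_set` (charges included; `type` from the atoms section).
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^;", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  names_ <- sub("^\\[ *([a-z]+) *\\]$", "\\1", lines[grepl("^\\[", lines)])
  blocks <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(blocks) <- names_[as.integer(names(blocks))]
  parse_ints <- function(b, k) {
    if (is.null(b) || !length(b)) return(matrix(integer(0), 0, k))
    t(vapply(strsplit(trimws(b), "\\s+"),
             function(p) as.integer(p[1:k]), integer(k)))
  }
  atoms <- blocks[["atoms"]]
  charges <- if (!is.null(atoms) && length(atoms)) {
    p <- strsplit(trimws(atoms), "\\s+")
    tibble::tibble(atom_id = vapply(p, function(x) as.integer(x[1]), 1L),
                   charge = vapply(p, function(x) as.numeric(x[6]), 1.0),
                   type = vapply(p, function(x) x[2], ""))
  } else tibble::tibble(atom_id = integer(), charge = numeric(), type = character())
  b <- parse_ints(blocks[["bonds"]], 2)
  a <- parse_ints(blocks[["angles"]], 3)
  d <- parse_ints(blocks[["dihedrals"]], 4)
  structure(list(
    bonds = tibble::tibble(i = b[, 1], j = b[, 2]),
    angles = tibble::tibble(i = a[, 1], j = a[, 2], k = a[, 3]),
    dihedrals = tibble::tibble(i = d[, 1], j = d[, 2], k = d[, 3], l = d[, 4]),
    charges = charges, net_charge = sum(charges$charge)),
    class = "topology_set")
}
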