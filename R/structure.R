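#' Atomistic structures as tidy tibbles
#'
#' Throughout nanoforge an atomistic structure is an ordinary tibble with one
#' row per atom and the columns `atom_id` (integer, unique), `element`
#' (chemical symbol), `name` (atom name), `resid` (integer residue id),
#' `resname` (residue name), `molid` (integer molecule id) and Cartesian
#' coordinates `x`, `y`, `z` in Angstrom. Optional extra columns (`charge`,
#' `component`, `label`, ...) ride along through every verb. An orthorhombic
#' periodic box, when present, is stored in the `"box"` attribute as a
#' length-3 numeric vector of edge lengths (Angstrom).
#'
#' @param df data frame of atoms; missing bookkeeping columns are filled.
#' @param box optional length-3 numeric box edges (Angstrom).
#' @return a tibble of atoms (class `nf_structure` prepended for printing).
#' @examples
#' nf_structure(data.frame(element = "Fe", x = 0, y = 0, z = 0))
#' @export
nf_structure <- function(df, box = NULL) {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  if (!"atom_id" %in% names(df)) df$atom_id <- seq_len(n)
  if (!"element" %in% names(df)) stop("structure needs an `element` column", call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$element
  if (!"resid" %in% names(df)) df$resid <- 1L
  if (!"resname" %in% names(df)) df$resname <- "UNK"
  if (!"molid" %in% names(df)) df$molid <- 1L
  for (cc in c("x", "y", "z")) {
    if (!cc %in% names(df)) stop("structure needs coordinate column `", cc, "`", call. = FALSE)
  }
  if (n > 0) {
    if (anyDuplicated(df$atom_id)) stop("atom ids must be unique", call. = FALSE)
    if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
      stop("all coordinates must be finite", call. = FALSE)
    }
  }
  df$atom_id <- as.integer(df$atom_id)
  df$resid <- as.integer(df$resid)
  df$molid <- as.integer(df$molid)
  core <- c("atom_id", "element", "name", "resid", "resname", "molid", "x", "y", "z")
  df <- df[, c(core, setdiff(names(df), core))]
  if (!is.null(box)) {
    stopifnot(is.numeric(box), length(box) == 3, all(box > 0))
    attr(df, "box") <- as.numeric(box)
  }
  class(df) <- unique(c("nf_structure", class(df)))
  df
}

#' @export
print.nf_structure <- function(x, ...) {
  comp <- composition(x)
  cat("# Atomistic structure:", nrow(x), "atoms (",
      paste0(comp$element, ":", comp$n, collapse = " "), ")\n")
  box <- attr(x, "box")
  if (!is.null(box)) cat("# Box (A):", paste(signif(box, 6), collapse = " x "), "\n")
  NextMethod()
}

#' Element composition of a structure
#'
#' @param structure atom tibble.
#' @return tibble with columns `element` and `n`, sorted by element.
#' @export
composition <- function(structure) {
  dplyr::count(tibble::as_tibble(structure), .data$element, name = "n") |>
    dplyr::arrange(.data$element)
}

#' Coordinate matrix of a structure
#' @param structure atom tibble.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Minimum interatomic distance
#'
#' Used to assert the no-overlap invariant of assembled structures. Works in
#' chunks so large systems do not allocate an n^2 matrix.
#'
#' @param structure atom tibble.
#' @param stop_below stop early once a pair below this distance is found
#'   (useful as a clash test); default 0 scans every pair.
#' @return smallest pairwise distance (Angstrom); `Inf` for < 2 atoms.
#' @export
min_interatomic_distance <- function(structure, stop_below = 0) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  # grid hash: only neighbouring cells can hold the closest pair
  cell <- 3.0
  key <- floor(xyz / cell)
  ord <- order(key[, 1], key[, 2], key[, 3])
  xyz <- xyz[ord, , drop = FALSE]
  key <- key[ord, , drop = FALSE]
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  idx <- split(seq_len(n), kstr)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (cells in names(idx)) {
    i <- idx[[cells]]
    k0 <- key[i[1], ]
    neigh <- i
    for (r in seq_len(nrow(offsets))) {
      if (all(offsets[r, ] == 0)) next
      kk <- paste(k0[1] + offsets[r, 1], k0[2] + offsets[r, 2], k0[3] + offsets[r, 3])
      j <- idx[[kk]]
      if (!is.null(j)) neigh <- c(neigh, j)
    }
    if (length(i) >= 1 && length(neigh) >= 2) {
      a <- xyz[i, , drop = FALSE]
      b <- xyz[neigh, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      # mask self-pairs
      self <- outer(i, neigh, "==")
      d2[self] <- Inf
      m <- sqrt(max(0, min(d2)))
      if (m < best) best <- m
      if (best < stop_below) return(best)
    }
  }
  best
}

#' Merge structures, renumbering atom and molecule ids
#'
#' @param ... atom tibbles (or a single list of them).
#' @param box box attribute for the merged structure (default: first non-NULL).
#' @return merged atom tibble with unique `atom_id` and shifted `molid`.
#' @export
merge_structures <- function(..., box = NULL) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (is.null(box)) {
    for (p in parts) if (!is.null(attr(p, "box"))) { box <- attr(p, "box"); break }
  }
  off_atom <- 0L; off_mol <- 0L
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    p <- tibble::as_tibble(parts[[k]])
    p$atom_id <- p$atom_id - min(p$atom_id) + 1L + off_atom
    p$molid <- as.integer(factor(p$molid)) + off_mol
    off_atom <- off_atom + nrow(p)
    off_mol <- max(p$molid)
    out[[k]] <- p
  }
  nf_structure(dplyr::bind_rows(out), box = box)
}

#' Translate a structure
#' @param structure atom tibble.
#' @param shift length-3 numeric (Angstrom).
#' @return shifted structure.
#' @export
translate_structure <- function(structure, shift) {
  stopifnot(length(shift) == 3)
  structure$x <- structure$x + shift[1]
  structure$y <- structure$y + shift[2]
  structure$z <- structure$z + shift[3]
  structure
}

#' Rotate a structure by a 3x3 rotation matrix about a pivot
#' @param structure atom tibble.
#' @param R 3x3 rotation matrix.
#' @param pivot length-3 pivot point (default origin).
#' @return rotated structure.
#' @export
rotate_structure <- function(structure, R, pivot = c(0, 0, 0)) {
  xyz <- sweep(coords(structure), 2, pivot)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, pivot, "+")
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}

#' Rotation matrix taking unit vector `a` onto unit vector `b`
#' @keywords internal
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Rotation matrix about an axis by an angle
#' @keywords internal
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  c_ <- cos(th); s <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  c_ * diag(3) + s * ux + (1 - c_) * tcrossprod(u)
}

#' Select atom ids by attribute
#'
#' Convenience filter used for hydrogen-bond donor/acceptor and distance-series
#' selections.
#'
#' @param structure atom tibble.
#' @param element,name,resname,component optional character vectors to match.
#' @return integer vector of `atom_id`s.
#' @export
select_atoms <- function(structure, element = NULL, name = NULL,
                         resname = NULL, component = NULL) {
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(element)) keep <- keep & structure$element %in% element
  if (!is.null(name)) keep <- keep & structure$name %in% name
  if (!is.null(resname)) keep <- keep & structure$resname %in% resname
  if (!is.null(component) && "component" %in% names(structure)) {
    keep <- keep & structure$component %in% component
  }
  structure$atom_id[keep]
}
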