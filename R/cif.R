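#' Read a crystallographic unit cell from a CIF file
#'
#' Parses cell parameters, the symmetry-operator loop and the atom-site loop,
#' applies every symmetry operation to the asymmetric unit and merges
#' duplicate positions, returning the full conventional cell. This is the
#' entry point for building bulk crystals; for the packaged magnetite spinel
#' fixture the expanded cell holds 24 Fe and 32 O (Fe3O4 stoichiometry).
#'
#' @param path CIF file. Needs `_cell_length_*`, `_cell_angle_*`, an
#'   `_atom_site_*` loop and (unless `p1_fallback = TRUE`) a
#'   `_space_group_symop_operation_xyz` / `_symmetry_equiv_pos_as_xyz` loop.
#' @param p1_fallback if `TRUE`, a file without a symmetry loop is accepted
#'   and treated as P1. Defaults to `FALSE`: a missing loop is an error naming
#'   the missing tag, never a silent fallback.
#' @param dedup_tol merge tolerance for symmetry-equivalent positions, in
#'   Angstrom (default 1e-3, far below any interatomic distance).
#' @return an object of class `unit_cell`: list with `a,b,c` (Angstrom),
#'   `alpha,beta,gamma` (degrees), `sites` (tibble of the full cell:
#'   `label`, `element`, `fx`, `fy`, `fz`), `asym` (the asymmetric unit as
#'   read), and `symops` (list of `list(M, t)` affine maps on fractional
#'   coordinates).
#' @examples
#' cif <- system.file("extdata", "magnetite_synthetic.cif", package = "nanoforge")
#' cell <- read_cif(cif)
#' nrow(cell$sites)  # 56
#' @export
read_cif <- function(path, p1_fallback = FALSE, dedup_tol = 1e-3) {
  if (!file.exists(path)) stop("CIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  get_tag <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    val <- trimws(sub(paste0("^", tag, "\\s*"), "", hit[1]))
    gsub("^'|'$", "", val)
  }
  num_tag <- function(tag) {
    v <- get_tag(tag)
    if (is.na(v)) return(NA_real_)
    as.numeric(gsub("\\(.*\\)", "", v))  # strip esd parentheses
  }

  a <- num_tag("_cell_length_a"); b <- num_tag("_cell_length_b"); c_ <- num_tag("_cell_length_c")
  if (any(is.na(c(a, b, c_)))) {
    stop("CIF format error: missing _cell_length_a/_b/_c tags in ", path, call. = FALSE)
  }
  alpha <- num_tag("_cell_angle_alpha"); beta <- num_tag("_cell_angle_beta")
  gamma <- num_tag("_cell_angle_gamma")
  if (any(is.na(c(alpha, beta, gamma)))) {
    stop("CIF format error: missing _cell_angle_* tags in ", path, call. = FALSE)
  }
  if (!all(c(a, b, c_) > 0)) stop("CIF format error: non-positive cell length", call. = FALSE)
  if (!all(c(alpha, beta, gamma) > 0 & c(alpha, beta, gamma) < 180)) {
    stop("CIF format error: cell angles must lie in (0, 180)", call. = FALSE)
  }

  # ---- loops ---------------------------------------------------------------
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "loop_") {
      j <- i + 1
      tags <- character()
      while (j <= length(lines) && startsWith(lines[j], "_")) {
        tags <- c(tags, strsplit(lines[j], "\\s+")[[1]][1])
        j <- j + 1
      }
      rows <- character()
      while (j <= length(lines) && !startsWith(lines[j], "_") && lines[j] != "loop_" &&
             !startsWith(lines[j], "data_")) {
        rows <- c(rows, lines[j])
        j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      i <- j
    } else {
      i <- i + 1
    }
  }

  find_loop <- function(pattern) {
    for (lp in loops) if (any(grepl(pattern, lp$tags))) return(lp)
    NULL
  }

  # ---- symmetry ------------------------------------------------------------
  symloop <- find_loop("_space_group_symop_operation_xyz|_symmetry_equiv_pos_as_xyz")
  if (is.null(symloop)) {
    sg <- get_tag("_space_group_name_H-M_alt")
    if (!p1_fallback) {
      if (!is.na(sg) && !grepl("^P *1$", sg)) {
        stop("CIF symmetry error: no _space_group_symop_operation_xyz / ",
             "_symmetry_equiv_pos_as_xyz loop in ", path,
             " (space group '", sg, "'); pass p1_fallback = TRUE to force P1",
             call. = FALSE)
      }
      if (is.na(sg)) {
        stop("CIF symmetry error: missing _space_group_symop_operation_xyz loop ",
             "and no space-group tag; pass p1_fallback = TRUE to force P1",
             call. = FALSE)
      }
    }
    symops <- list(list(M = diag(3), t = c(0, 0, 0)))
  } else {
    opstr <- gsub("^'|'$", "", gsub('^"|"$', "", symloop$rows))
    # drop a leading op index if present ("1 x,y,z")
    opstr <- sub("^[0-9]+\\s+", "", opstr)
    symops <- lapply(opstr, parse_symop)
  }

  # ---- atom sites ----------------------------------------------------------
  siteloop <- find_loop("_atom_site_fract_x")
  if (is.null(siteloop) || length(siteloop$rows) == 0) {
    stop("CIF format error: no _atom_site loop in ", path, call. = FALSE)
  }
  tags <- siteloop$tags
  parts <- strsplit(siteloop$rows, "\\s+")
  col <- function(tag) {
    k <- match(tag, tags)
    if (is.na(k)) return(rep(NA_character_, length(parts)))
    vapply(parts, function(p) p[k], character(1))
  }
  label <- col("_atom_site_label")
  symbol <- col("_atom_site_type_symbol")
  if (all(is.na(symbol))) symbol <- gsub("[^A-Za-z].*$", "", label)
  fx <- as.numeric(gsub("\\(.*\\)", "", col("_atom_site_fract_x")))
  fy <- as.numeric(gsub("\\(.*\\)", "", col("_atom_site_fract_y")))
  fz <- as.numeric(gsub("\\(.*\\)", "", col("_atom_site_fract_z")))
  element <- paste0(toupper(substr(symbol, 1, 1)), tolower(substr(symbol, 2, 2)))
  element <- gsub("[^A-Za-z]", "", element)
  asym <- tibble::tibble(label = label, element = element, fx = fx %% 1, fy = fy %% 1, fz = fz %% 1)

  sites <- expand_symmetry(asym, symops, cell_lengths = c(a, b, c_), tol = dedup_tol)

  structure(
    list(a = a, b = b, c = c_, alpha = alpha, beta = beta, gamma = gamma,
         sites = sites, asym = asym, symops = symops, source = path),
    class = "unit_cell")
}

#' Parse a symmetry operation string like `"1/4+y,3/4-x,z"`
#'
#' @param s operator in xyz notation.
#' @return `list(M, t)`: 3x3 integer matrix and length-3 translation, both
#'   acting on fractional coordinates as `M %*% r + t`.
#' @keywords internal
parse_symop <- function(s) {
  comps <- strsplit(gsub("\\s", "", s), ",")[[1]]
  if (length(comps) != 3) stop("unparseable symmetry operation: '", s, "'", call. = FALSE)
  M <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    comp <- comps[i]
    for (j in 1:3) {
      v <- c("x", "y", "z")[j]
      if (grepl(paste0("-", v), comp, fixed = TRUE)) M[i, j] <- -1
      else if (grepl(v, comp, fixed = TRUE)) M[i, j] <- 1
    }
    rest <- gsub("[+-]?[xyz]", "", comp)
    if (nzchar(rest)) {
      if (grepl("/", rest)) {
        num <- strsplit(gsub("^\\+", "", rest), "/")[[1]]
        t[i] <- as.numeric(num[1]) / as.numeric(num[2])
      } else {
        t[i] <- suppressWarnings(as.numeric(rest))
      }
      if (is.na(t[i])) stop("unparseable symmetry operation: '", s, "'", call. = FALSE)
    }
  }
  if (all(M == 0)) stop("unparseable symmetry operation: '", s, "'", call. = FALSE)
  list(M = M, t = t)
}

#' Apply symmetry operations to an asymmetric unit and deduplicate
#' @keywords internal
expand_symmetry <- function(asym, symops, cell_lengths, tol = 1e-3) {
  out <- vector("list", nrow(asym))
  for (k in seq_len(nrow(asym))) {
    r <- c(asym$fx[k], asym$fy[k], asym$fz[k])
    pts <- t(vapply(symops, function(op) (op$M %*% r + op$t) %% 1, numeric(3)))
    out[[k]] <- tibble::tibble(label = asym$label[k], element = asym$element[k],
                               fx = pts[, 1], fy = pts[, 2], fz = pts[, 3])
  }
  sites <- dplyr::bind_rows(out)
  # deduplicate across the whole cell (orbits can coincide between sites)
  keep <- dedup_fractional(as.matrix(sites[, c("fx", "fy", "fz")]),
                           cell_lengths, tol)
  sites[keep, ]
}

# minimum-image deduplication of fractional points; returns indices to keep
dedup_fractional <- function(pts, cell_lengths, tol) {
  n <- nrow(pts)
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0) { keep[i] <- TRUE; kept <- pts[i, , drop = FALSE]; next }
    d <- abs(sweep(kept, 2, pts[i, ]))
    d <- pmin(d, 1 - d)  # minimum image in fractional space
    dang <- sweep(d, 2, cell_lengths, "*")
    if (min(sqrt(rowSums(dang^2))) > tol) {
      keep[i] <- TRUE
      kept <- rbind(kept, pts[i, ])
    }
  }
  keep
}

#' @export
print.unit_cell <- function(x, ...) {
  cat("# Unit cell:", sprintf("a=%.4f b=%.4f c=%.4f A, alpha=%g beta=%g gamma=%g deg\n",
                              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  comp <- dplyr::count(x$sites, .data$element)
  cat("# Full cell:", nrow(x$sites), "sites (",
      paste0(comp$element, ":", comp$n, collapse = " "), "),",
      length(x$symops), "symmetry operations\n")
  invisible(x)
}

#' Cell matrix (columns are lattice vectors, Angstrom)
#' @param cell a `unit_cell`.
#' @return 3x3 matrix `A` with `r_cart = A %*% r_frac`.
#' @export
cell_matrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  sg <- sin(cell$gamma * d2r)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(max(0, cell$c^2 - cx^2 - cy^2))
  cbind(av, bv, c(cx, cy, cz))
}

#' Replicate the full cell into a Cartesian supercell
#'
#' @param cell a `unit_cell`.
#' @param nx,ny,nz replication counts (>= 1) along the three lattice vectors.
#' @return atom tibble of `nx*ny*nz` copies of the full cell; for orthogonal
#'   cells the box attribute is `c(nx*a, ny*b, nz*c)`.
#' @examples
#' bulk <- replicate_cell(magnetite_cell(), 3, 3, 3)  # 1512 atoms
#' @export
replicate_cell <- function(cell, nx, ny, nz) {
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) != round(c(nx, ny, nz)))) {
    stop("replication factors must be integers >= 1", call. = FALSE)
  }
  A <- cell_matrix(cell)
  shifts <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  s <- cell$sites
  n1 <- nrow(s)
  frac <- cbind(rep(s$fx, nrow(shifts)) + rep(shifts$i, each = n1),
                rep(s$fy, nrow(shifts)) + rep(shifts$j, each = n1),
                rep(s$fz, nrow(shifts)) + rep(shifts$k, each = n1))
  cart <- frac %*% t(A)
  box <- NULL
  if (all(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) < 1e-6)) {
    box <- c(nx * cell$a, ny * cell$b, nz * cell$c)
  }
  nf_structure(tibble::tibble(
    atom_id = seq_len(nrow(cart)),
    element = rep(s$element, nrow(shifts)),
    name = rep(s$element, nrow(shifts)),
    label = rep(s$label, nrow(shifts)),
    resid = 1L, resname = "CRY", molid = 1L,
    x = cart[, 1], y = cart[, 2], z = cart[, 3]), box = box)
}
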