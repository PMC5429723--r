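#' Classify iron coordination sites by oxygen neighbour count
#'
#' In the inverse-spinel lattice an octahedral Fe has six O neighbours and a
#' tetrahedral Fe has four. Atoms carved at the particle surface lose
#' neighbours; they are classed `undercoordinated-surface`, and their
#' reference bulk class is recovered from the crystallographic site label
#' when the structure carries one (column `label`, e.g. `"Fe2_oct"`).
#'
#' @param structure atom tibble containing Fe and O atoms.
#' @param neighbor_cutoff Fe-O neighbour cutoff in Angstrom. Default 2.35 A,
#'   between the Fe-O bond (1.9-2.1 A) and the next coordination shell.
#' @return tibble with one row per Fe atom: `atom_id`, `coordination`,
#'   `class` (octahedral / tetrahedral / undercoordinated-surface / other)
#'   and `bulk_class` (class of the site's interior analog).
#' @examples
#' classify_fe_sites(replicate_cell(magnetite_cell(), 2, 2, 2))
#' @export
classify_fe_sites <- function(structure, neighbor_cutoff = 2.35) {
  fe <- structure[structure$element == "Fe", , drop = FALSE]
  ox <- structure[structure$element == "O", , drop = FALSE]
  if (nrow(fe) == 0) stop("structure contains no Fe atoms", call. = FALSE)
  if (nrow(ox) == 0) stop("structure contains no O atoms", call. = FALSE)
  coord <- neighbor_counts(coords(fe), coords(ox), neighbor_cutoff)
  cls <- dplyr::case_when(
    coord == 6 ~ "octahedral",
    coord == 4 ~ "tetrahedral",
    coord < 4 | coord == 5 ~ "undercoordinated-surface",
    TRUE ~ "other")
  bulk <- rep(NA_character_, nrow(fe))
  if ("label" %in% names(fe)) {
    bulk <- dplyr::case_when(
      grepl("oct", fe$label, ignore.case = TRUE) ~ "octahedral",
      grepl("tet", fe$label, ignore.case = TRUE) ~ "tetrahedral",
      TRUE ~ NA_character_)
  }
  # fall back to the observed class for fully coordinated atoms
  bulk[is.na(bulk) & cls %in% c("octahedral", "tetrahedral")] <-
    cls[is.na(bulk) & cls %in% c("octahedral", "tetrahedral")]
  tibble::tibble(atom_id = fe$atom_id, coordination = coord,
                 class = cls, bulk_class = bulk)
}

# counts of B-points within cutoff of each A-point, blocked to bound memory
neighbor_counts <- function(a, b, cutoff) {
  na <- nrow(a)
  counts <- integer(na)
  block <- max(1L, floor(2e6 / max(1, nrow(b))))
  c2 <- cutoff^2
  bb <- rowSums(b^2)
  i <- 1L
  while (i <= na) {
    j <- min(na, i + block - 1L)
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * tcrossprod(aa, b)
    counts[i:j] <- rowSums(d2 <= c2 + 1e-9)
    i <- j + 1L
  }
  counts
}

#' Identify surface atoms of a carved particle and their outward normals
#'
#' An atom is a surface atom when it lies within `skin` of at least one
#' boundary face of the generating Wulff shape. Its outward normal is the
#' normal of that face; when several faces are equally close (edge/corner
#' atoms) the normals are averaged and renormalised.
#'
#' @param structure carved atom tibble, centred on the carve origin.
#' @param shape the generating `wulff_shape` (defaults to the `"shape"`
#'   attribute left by [carve()]).
#' @param skin distance from a boundary face below which an atom counts as
#'   surface (Angstrom).
#' @return tibble: `atom_id`, `face_distance` (to the nearest boundary face),
#'   `nx`, `ny`, `nz` (unit outward normal).
#' @export
detect_surface_atoms <- function(structure, shape = attr(structure, "shape"),
                                 skin = 1.5) {
  if (is.null(shape)) stop("no Wulff shape supplied or attached", call. = FALSE)
  xyz <- coords(structure)
  face_planes <- as.integer(sub("^f", "", names(shape$faces)))
  nrm <- shape$normals[face_planes, , drop = FALSE]
  dd <- shape$d[face_planes]
  # distance below each boundary face plane (>= 0 inside)
  gaps <- sweep(-(xyz %*% t(nrm)), 2, dd, "+")
  mind <- apply(gaps, 1, min)
  keep <- which(mind <= skin + 1e-9)
  if (length(keep) == 0) {
    return(tibble::tibble(atom_id = integer(), face_distance = numeric(),
                          nx = numeric(), ny = numeric(), nz = numeric()))
  }
  normals <- t(vapply(keep, function(i) {
    tie <- which(gaps[i, ] <= mind[i] + 1e-6)
    v <- colSums(nrm[tie, , drop = FALSE])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  tibble::tibble(atom_id = structure$atom_id[keep], face_distance = mind[keep],
                 nx = normals[, 1], ny = normals[, 2], nz = normals[, 3])
}

#' Select grafting sites among surface octahedral iron atoms
#'
#' Sites are chosen by deterministic farthest-point sampling: the seed picks
#' the starting site (by index ordering among candidates), then each further
#' site maximises its minimum distance to the sites already chosen, ties
#' broken by lowest atom id. This maximises spatial uniformity of the coating.
#' Candidates are surface Fe whose bulk site class is octahedral (surface
#' atoms necessarily lose neighbours, so the interior analog decides
#' eligibility).
#'
#' @param structure carved atom tibble.
#' @param n_chains requested number of chains (count mode).
#' @param density chains per nm^2 (density mode; used when `n_chains` is
#'   `NULL`); the site count is `round(density * area_nm2)` with the area
#'   taken from the Wulff polyhedron surface.
#' @param shape generating `wulff_shape` (default: `"shape"` attribute).
#' @param skin grafting skin depth (Angstrom). Default 3.0: octahedral Fe
#'   planes repeat every a/4 (~2.1 A) along <100>, so a thinner skin can
#'   miss them entirely on unluckily cut faces; 3 A always includes at
#'   least one.
#' @param neighbor_cutoff Fe-O cutoff for site classification.
#' @param seed integer seed designating the starting site.
#' @return object of class `graft_spec`: tibble of selected sites
#'   (`atom_id`, `x`, `y`, `z`, `nx`, `ny`, `nz`) with attributes
#'   `n_requested`, `area_nm2`, `density_realized` (chains/nm^2) and
#'   `min_spacing` (Angstrom).
#' @examples
#' core <- carve_core(magnetite_cell(),
#'                    miller_facets(c(1, 1), c(0, 1), c(0, 1), c(1, 1.15)), 30)
#' sites <- select_graft_sites(core, n_chains = 64, seed = 1)
#' @export
select_graft_sites <- function(structure, n_chains = NULL, density = NULL,
                               shape = attr(structure, "shape"), skin = 3.0,
                               neighbor_cutoff = 2.35, seed = 1) {
  if (is.null(shape)) stop("no Wulff shape supplied or attached", call. = FALSE)
  area_nm2 <- shape$area / 100
  if (is.null(n_chains)) {
    if (is.null(density)) stop("give n_chains or density", call. = FALSE)
    n_chains <- round(density * area_nm2)
  }
  n_chains <- as.integer(n_chains)
  if (n_chains < 0) stop("n_chains must be >= 0", call. = FALSE)

  surf <- detect_surface_atoms(structure, shape, skin)
  cls <- classify_fe_sites(structure, neighbor_cutoff)
  cand <- dplyr::inner_join(surf, cls, by = "atom_id") |>
    dplyr::filter(.data$bulk_class == "octahedral") |>
    dplyr::inner_join(tibble::as_tibble(structure)[, c("atom_id", "x", "y", "z")],
                      by = "atom_id") |>
    dplyr::arrange(.data$atom_id)
  if (n_chains > nrow(cand)) {
    stop("capacity error: requested ", n_chains, " graft sites but only ",
         nrow(cand), " surface octahedral Fe candidates are available",
         call. = FALSE)
  }
  sel <- farthest_point_sample(coords(cand), n_chains, seed)
  sites <- cand[sel, c("atom_id", "x", "y", "z", "nx", "ny", "nz")]
  spacing <- if (n_chains >= 2) min(stats::dist(cbind(sites$x, sites$y, sites$z))) else Inf
  structure(sites,
            class = c("graft_spec", class(sites)),
            n_requested = n_chains, area_nm2 = area_nm2,
            density_realized = if (area_nm2 > 0) n_chains / area_nm2 else NA_real_,
            min_spacing = spacing, seed = seed)
}

# deterministic farthest-point sampling; seed picks the first index
farthest_point_sample <- function(xyz, n, seed) {
  if (n == 0) return(integer(0))
  m <- nrow(xyz)
  first <- (as.integer(seed) %% m) + 1L
  sel <- first
  mind <- sqrt(rowSums(sweep(xyz, 2, xyz[first, ])^2))
  while (length(sel) < n) {
    nxt <- which(mind == max(mind))[1]  # ties: lowest index (= lowest atom id)
    sel <- c(sel, nxt)
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

#' @export
print.graft_spec <- function(x, ...) {
  cat("# Graft sites:", nrow(x), "surface octahedral Fe;",
      sprintf("area %.1f nm^2, density %.2f chains/nm^2, min spacing %.2f A\n",
              attr(x, "area_nm2"), attr(x, "density_realized"),
              attr(x, "min_spacing")))
  NextMethod()
}

#' @rdname select_graft_sites
#' @param x a `graft_spec`.
#' @param ... unused.
#' @return `glance()`: one-row tibble with `n_sites`, `area_nm2`,
#'   `density_realized`, `min_spacing`.
#' @export
glance.graft_spec <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x), area_nm2 = attr(x, "area_nm2"),
                 density_realized = attr(x, "density_realized"),
                 min_spacing = attr(x, "min_spacing"))
}
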