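#' Declare Miller facets with relative surface energies
#'
#' The equilibrium (Wulff) shape of a crystal is the inner envelope of planes
#' whose distance from the origin is proportional to the surface energy of the
#' corresponding facet. Facets are declared per family: `{100}` with its six
#' symmetry-equivalent planes dominates the magnetite morphology, truncated at
#' the corners by `{111}`.
#'
#' @param h,k,l integer Miller indices (not all zero).
#' @param gamma relative surface energies (> 0), recycled.
#' @param expand_family expand each index to its full symmetry-equivalent
#'   family using the cell's point group (default `TRUE`).
#' @return tibble with columns `h`, `k`, `l`, `gamma`, `expand_family`.
#' @examples
#' miller_facets(c(1, 1), c(0, 1), c(0, 1), gamma = c(1.0, 1.15))
#' @export
miller_facets <- function(h, k, l, gamma = 1, expand_family = TRUE) {
  n <- max(length(h), length(k), length(l), length(gamma))
  f <- tibble::tibble(h = as.integer(rep_len(h, n)), k = as.integer(rep_len(k, n)),
                      l = as.integer(rep_len(l, n)), gamma = rep_len(gamma, n),
                      expand_family = rep_len(expand_family, n))
  if (any(f$gamma <= 0)) stop("facet surface energies must be > 0", call. = FALSE)
  if (any(f$h == 0 & f$k == 0 & f$l == 0)) {
    stop("Miller index (0,0,0) is not a facet", call. = FALSE)
  }
  f
}

#' Parse a facet string like `"100:1.0,111:1.15"`
#' @param spec character scalar, comma-separated `hkl:gamma` entries.
#' @return facet tibble as from [miller_facets()].
#' @export
parse_facets <- function(spec) {
  entries <- strsplit(spec, ",")[[1]]
  hkl <- t(vapply(entries, function(e) {
    p <- strsplit(trimws(e), ":")[[1]]
    idx <- strsplit(p[1], "")[[1]]
    c(as.numeric(idx[1]), as.numeric(idx[2]), as.numeric(idx[3]),
      if (length(p) > 1) as.numeric(p[2]) else 1)
  }, numeric(4)))
  miller_facets(hkl[, 1], hkl[, 2], hkl[, 3], gamma = hkl[, 4])
}

# point-group rotations of a cell = unique linear parts of its symmetry ops
point_group <- function(cell) {
  mats <- lapply(cell$symops, `[[`, "M")
  keys <- vapply(mats, function(m) paste(m, collapse = ","), character(1))
  mats[!duplicated(keys)]
}

# expand (h,k,l) to the set of symmetry-equivalent integer triples
expand_family <- function(hkl, pg) {
  out <- t(vapply(pg, function(R) as.numeric(t(R) %*% hkl), numeric(3)))
  out <- round(out)
  out[!duplicated(out), , drop = FALSE]
}

#' Construct the Wulff equilibrium shape for a facet set
#'
#' Each facet family contributes half-spaces whose plane distance from the
#' origin is proportional to its surface energy (the Wulff condition
#' `d_hkl / gamma_hkl = const`). The shape is scaled so that the face-to-face
#' extent along the lowest-energy facet normal equals `target_diameter`.
#' Facets dominated by the inner envelope stay in the input but contribute no
#' boundary face.
#'
#' @param facets facet tibble from [miller_facets()].
#' @param cell `unit_cell`; its point group expands facet families and its
#'   reciprocal lattice orients plane normals.
#' @param target_diameter face-to-face extent along the dominant (lowest
#'   gamma) facet normal, Angstrom.
#' @return object of class `wulff_shape`: list with `normals` (n x 3 unit
#'   rows), `d` (plane distances, Angstrom), `hkl`, `gamma`, `vertices`,
#'   `faces` (list of vertex indices per boundary face), `n_faces`, `area`
#'   (A^2), `volume` (A^3).
#' @examples
#' cell <- magnetite_cell()
#' ws <- wulff_shape(miller_facets(1, 0, 0), cell, target_diameter = 30)
#' ws$n_faces  # 6: a cube
#' @export
wulff_shape <- function(facets, cell, target_diameter) {
  stopifnot(nrow(facets) >= 1, target_diameter > 0)
  A <- cell_matrix(cell)
  Bstar <- t(solve(A))  # reciprocal lattice (no 2*pi), columns a*,b*,c*
  pg <- point_group(cell)

  planes <- list()
  for (i in seq_len(nrow(facets))) {
    hkl0 <- c(facets$h[i], facets$k[i], facets$l[i])
    fam <- if (isTRUE(facets$expand_family[i])) expand_family(hkl0, pg)
           else matrix(hkl0, 1)
    for (r in seq_len(nrow(fam))) {
      nvec <- Bstar %*% fam[r, ]
      nvec <- as.numeric(nvec) / sqrt(sum(nvec^2))
      planes[[length(planes) + 1]] <- list(
        n = nvec, gamma = facets$gamma[i],
        hkl = sprintf("(%d%d%d)", fam[r, 1], fam[r, 2], fam[r, 3]))
    }
  }
  normals <- t(vapply(planes, `[[`, numeric(3), "n"))
  gam <- vapply(planes, `[[`, numeric(1), "gamma")
  hkl <- vapply(planes, `[[`, character(1), "hkl")
  # drop duplicated planes (same normal; keep the lower energy = inner one)
  ord <- order(gam)
  normals <- normals[ord, , drop = FALSE]; gam <- gam[ord]; hkl <- hkl[ord]
  dup <- duplicated(round(normals, 9))
  normals <- normals[!dup, , drop = FALSE]; gam <- gam[!dup]; hkl <- hkl[!dup]

  scale <- target_diameter / (2 * min(gam))
  d <- scale * gam

  if (!halfspaces_bounded(normals)) {
    stop("Wulff geometry error: facet set does not close the shape ",
         "(unbounded half-space intersection); add more facets or enable ",
         "family expansion", call. = FALSE)
  }
  geom <- halfspace_geometry(normals, d)
  structure(list(normals = normals, d = d, gamma = gam, hkl = hkl,
                 scale = scale, vertices = geom$vertices, faces = geom$faces,
                 n_faces = length(geom$faces), area = geom$area,
                 volume = geom$volume, target_diameter = target_diameter),
            class = "wulff_shape")
}

# bounded iff the normals positively span R^3: no direction u with n_i.u <= 0
# for all i. Checked over a dense direction sample plus the normals' span.
halfspaces_bounded <- function(normals) {
  if (nrow(normals) < 4) return(FALSE)
  if (abs(det(crossprod(normals))) < 1e-12) return(FALSE)  # normals coplanar
  dirs <- rbind(normals, -normals, fib_sphere(400))
  proj <- dirs %*% t(normals)
  all(apply(proj, 1, max) > 1e-9)
}

# quasi-uniform unit directions (Fibonacci sphere)
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# vertex enumeration over all plane triples, feasibility-filtered; faces are
# planes that carry a polygon (>= 3 vertices) of the resulting polytope
halfspace_geometry <- function(normals, d, tol = 1e-7) {
  m <- nrow(normals)
  verts <- matrix(numeric(0), 0, 3)
  if (m >= 3) {
    combos <- utils::combn(m, 3)
    for (cc in seq_len(ncol(combos))) {
      tri <- combos[, cc]
      Mm <- normals[tri, , drop = FALSE]
      if (abs(det(Mm)) < 1e-10) next
      v <- solve(Mm, d[tri])
      if (all(normals %*% v <= d + tol * max(d))) verts <- rbind(verts, v)
    }
  }
  if (nrow(verts) == 0) stop("degenerate Wulff shape: no vertices", call. = FALSE)
  # dedup vertices
  keep <- !duplicated(round(verts, 6))
  verts <- verts[keep, , drop = FALSE]

  faces <- list(); area <- 0; volume <- 0
  face_ids <- integer(0)
  for (i in seq_len(m)) {
    on_face <- which(abs(verts %*% normals[i, ] - d[i]) < tol * max(d) + 1e-9)
    if (length(on_face) < 3) next
    pts <- verts[on_face, , drop = FALSE]
    ctr <- colMeans(pts)
    # order around centroid in the face plane
    e1 <- pts[1, ] - ctr; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(normals[i, 2] * e1[3] - normals[i, 3] * e1[2],
            normals[i, 3] * e1[1] - normals[i, 1] * e1[3],
            normals[i, 1] * e1[2] - normals[i, 2] * e1[1])
    ang <- atan2((pts - rep(ctr, each = nrow(pts))) %*% e2,
                 (pts - rep(ctr, each = nrow(pts))) %*% e1)
    ordv <- on_face[order(ang)]
    pts <- verts[ordv, , drop = FALSE]
    # polygon area by the shoelace formula in 3-D
    a <- 0
    np <- nrow(pts)
    for (k in seq_len(np)) {
      p1 <- pts[k, ]; p2 <- pts[if (k == np) 1 else k + 1, ]
      cr <- c(p1[2] * p2[3] - p1[3] * p2[2], p1[3] * p2[1] - p1[1] * p2[3],
              p1[1] * p2[2] - p1[2] * p2[1])
      a <- a + sum(cr * normals[i, ])
    }
    a <- abs(a) / 2
    if (a < tol * max(d)^2) next
    faces[[length(faces) + 1]] <- ordv
    face_ids <- c(face_ids, i)
    area <- area + a
    volume <- volume + a * d[i] / 3  # cone from origin
  }
  list(vertices = verts, faces = stats::setNames(faces, paste0("f", face_ids)),
       face_planes = face_ids, area = area, volume = volume)
}

#' @export
print.wulff_shape <- function(x, ...) {
  cat("# Wulff shape:", nrow(x$normals), "half-spaces,", x$n_faces,
      "boundary faces,", nrow(x$vertices), "vertices\n")
  cat(sprintf("# volume %.1f A^3, surface area %.1f A^2, diameter %.3f A along %s\n",
              x$volume, x$area, x$target_diameter, x$hkl[which.min(x$gamma)]))
  invisible(x)
}

#' @rdname wulff_shape
#' @param x a `wulff_shape`.
#' @param ... unused.
#' @return `tidy()`: one row per half-space with `hkl`, `gamma`, plane
#'   distance `d` and whether it carries a boundary face.
#' @export
tidy.wulff_shape <- function(x, ...) {
  face_planes <- as.integer(sub("^f", "", names(x$faces)))
  tibble::tibble(hkl = x$hkl, gamma = x$gamma, d = x$d,
                 nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3],
                 boundary_face = seq_along(x$d) %in% face_planes)
}

#' Scale a Wulff shape to a new diameter
#' @param shape `wulff_shape`.
#' @param target_diameter new face-to-face extent (Angstrom).
#' @return rescaled `wulff_shape`.
#' @export
scale_shape <- function(shape, target_diameter) {
  f <- target_diameter / shape$target_diameter
  shape$d <- shape$d * f
  shape$scale <- shape$scale * f
  shape$vertices <- shape$vertices * f
  shape$area <- shape$area * f^2
  shape$volume <- shape$volume * f^3
  shape$target_diameter <- target_diameter
  shape
}

#' Carve a faceted nanoparticle from a bulk supercell
#'
#' Keeps exactly the atoms satisfying every half-space constraint
#' `n . (r - center) <= d` (boundary atoms on a plane are included). Atom ids
#' are preserved from the bulk; output coordinates are re-centred on the carve
#' center so the particle origin is the Wulff origin.
#'
#' @param bulk atom tibble (a supercell from [replicate_cell()]).
#' @param shape `wulff_shape`.
#' @param center carve center in the bulk's coordinates (default: box center
#'   if a box is present, otherwise the coordinate centroid).
#' @return atom tibble of the carved particle, centred on the origin.
#' @examples
#' cell <- magnetite_cell()
#' shape <- wulff_shape(miller_facets(c(1, 1), c(0, 1), c(0, 1),
#'                                    gamma = c(1.0, 1.15)), cell, 30)
#' core <- carve(replicate_cell(cell, 5, 5, 5), shape)
#' @export
carve <- function(bulk, shape, center = NULL) {
  xyz <- coords(bulk)
  if (is.null(center)) {
    box <- attr(bulk, "box")
    center <- if (!is.null(box)) box / 2 else colMeans(xyz)
  }
  vlo <- apply(shape$vertices, 2, min); vhi <- apply(shape$vertices, 2, max)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  if (any(center + vlo < lo - 1e-6) || any(center + vhi > hi + 1e-6)) {
    stop("carve error: shape (extent ",
         paste(sprintf("%.1f", vhi - vlo), collapse = " x "),
         " A) extends beyond the bulk supercell; use a larger replication",
         call. = FALSE)
  }
  rel <- sweep(xyz, 2, center)
  inside <- rowSums(rel %*% t(shape$normals) > rep(shape$d + 1e-6, each = nrow(rel))) == 0
  out <- bulk[inside, , drop = FALSE]
  out$x <- out$x - center[1]; out$y <- out$y - center[2]; out$z <- out$z - center[3]
  attr(out, "box") <- NULL
  attr(out, "shape") <- shape
  out
}

#' Build a carved core straight from a cell and facet set
#'
#' Convenience wrapper: chooses a replication large enough to contain the
#' Wulff shape (at least the requested `min_replication`, auto-expanded and
#' logged when that is too small), carves, and returns the particle.
#'
#' @param cell `unit_cell`.
#' @param facets facet tibble from [miller_facets()].
#' @param target_diameter Angstrom.
#' @param min_replication requested replication per axis (default 3, the
#'   conventional starting point; expanded automatically when the shape does
#'   not fit).
#' @param verbose log the realized replication.
#' @return carved atom tibble (with the generating `wulff_shape` in the
#'   `"shape"` attribute).
#' @export
carve_core <- function(cell, facets, target_diameter, min_replication = 3,
                       verbose = TRUE) {
  shape <- wulff_shape(facets, cell, target_diameter)
  rmax <- sqrt(max(rowSums(shape$vertices^2)))
  need <- ceiling(2 * (rmax + 1e-6) / min(cell$a, cell$b, cell$c)) + 1L
  nrep <- max(min_replication, need)
  if (verbose && nrep > min_replication) {
    message("carve_core: replication expanded from ", min_replication, " to ",
            nrep, " per axis to contain the ", sprintf("%.1f", 2 * rmax),
            " A shape")
  }
  bulk <- replicate_cell(cell, nrep, nrep, nrep)
  carve(bulk, shape)
}
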