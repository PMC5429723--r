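#' Idealized all-atom DPPC lipid template
#'
#' A synthetic, deterministically generated DPPC
#' (1,2-dipalmitoyl-sn-glycero-3-phosphocholine) template with the atom
#' groups the hydrogen-bond analysis needs by name: the phosphate (`P`,
#' `O11`-`O14`) and the choline (`N`, `C12`-`C15` and their hydrogens), a
#' glycerol backbone, and two 16-carbon palmitoyl tails in all-trans zigzag.
#' Head sits at high z, tails point to z = 0; geometry is idealized (bond
#' lengths and zigzag spacing from standard values), not an equilibrated
#' conformation.
#'
#' @return atom tibble of one lipid (resname `DPC`), head up.
#' @export
dppc_template <- function() {
  at <- list()
  add <- function(name, el, x, y, z) {
    at[[length(at) + 1]] <<- tibble::tibble(name = name, element = el,
                                            x = x, y = y, z = z)
  }
  # palmitoyl tail: carbonyl C at top (z0), 15 CH2/CH3 below, all-trans zigzag
  tail <- function(prefix, x0, z0) {
    add(paste0(prefix, "1"), "C", x0, 0, z0)            # carbonyl C
    add(paste0(prefix, "1O"), "O", x0 + 1.1, 0.6, z0 + 0.3)  # C=O
    for (k in 2:16) {
      zz <- z0 - (k - 1) * 1.27
      xx <- x0 + 0.44 * ((k %% 2) * 2 - 1)
      add(paste0(prefix, k), "C", xx, 0, zz)
      add(paste0("H", prefix, k, "A"), "H", xx, 1.0, zz + 0.35)
      add(paste0("H", prefix, k, "B"), "H", xx, -1.0, zz + 0.35)
    }
    add(paste0("H", prefix, "16C"), "H", x0 + 0.44 * ((16 %% 2) * 2 - 1),
        0, z0 - 15 * 1.27 - 1.09)
  }
  zg <- 19.6  # glycerol level
  tail("C2", 0.0, zg - 1.5)
  tail("C3", 4.2, zg - 1.5)
  # esters
  add("O21", "O", 0.0, -0.7, zg - 0.3); add("O31", "O", 4.2, -0.7, zg - 0.3)
  # glycerol C1-C2-C3 (C1 carries the phosphate)
  add("C1", "C", 2.1, 0, zg + 1.2); add("HC1A", "H", 2.1, 0.95, zg + 1.75)
  add("C2G", "C", 0.9, -0.4, zg + 0.6); add("HC2G", "H", 0.9, -1.3, zg + 1.1)
  add("C3G", "C", 3.3, -0.4, zg + 0.6); add("HC3G", "H", 3.3, -1.3, zg + 1.1)
  # phosphate: ester O to glycerol, ester O to choline arm, two bare O
  zp <- zg + 4.2
  add("O11", "O", 2.1, 0, zp - 1.59)
  add("P", "P", 2.1, 0, zp)
  add("O13", "O", 0.9, 0.8, zp + 0.5); add("O14", "O", 3.3, 0.8, zp + 0.5)
  add("O12", "O", 2.1, -1.0, zp + 1.0)
  # choline arm: O12-C11-C12-N(CH3)3
  zc <- zp + 2.4
  add("C11", "C", 2.1, -1.0, zc)
  add("HC11A", "H", 1.2, -1.5, zc - 0.2); add("HC11B", "H", 3.0, -1.5, zc - 0.2)
  add("C12", "C", 2.1, 0.1, zc + 1.0)
  add("HC12A", "H", 1.2, 0.7, zc + 0.9); add("HC12B", "H", 3.0, 0.7, zc + 0.9)
  add("N", "N", 2.1, -0.3, zc + 2.4)
  meth <- list(c(0.75, -0.7), c(3.45, -0.7), c(2.1, 1.2))
  for (m in seq_along(meth)) {
    mx <- meth[[m]][1]; my <- meth[[m]][2]
    add(paste0("C1", 2 + m), "C", mx, my, zc + 3.0)
    for (h in 1:3) {
      add(paste0("HN", m, h), "H", mx + 0.8 * cos(2 * pi * h / 3),
          my + 0.8 * sin(2 * pi * h / 3), zc + 3.6)
    }
  }
  df <- dplyr::bind_rows(at)
  nf_structure(tibble::tibble(
    atom_id = seq_len(nrow(df)), element = df$element, name = df$name,
    resid = 1L, resname = "DPC", molid = 1L,
    x = df$x - 2.1, y = df$y, z = df$z))  # centred laterally on the P column
}

#' Build a DPPC bilayer on a tetragonal grid
#'
#' Two leaflets of exactly `n_per_leaflet` lipids each, placed on a
#' near-square tetragonal grid with pitch `sqrt(area_per_lipid)`; the upper
#' leaflet points its tails down and the lower leaflet is its mirror image,
#' tails meeting at the bilayer midplane (z = 0).
#'
#' @param n_per_leaflet lipids in each leaflet (>= 1); 489 reproduces the
#'   published membrane patch.
#' @param area_per_lipid nm^2 per lipid (default 0.63, fluid-phase DPPC).
#' @param template lipid template, default [dppc_template()].
#' @param tail_gap spacing between leaflet tail ends at the midplane (A).
#' @return atom tibble with a lateral box attribute; column `leaflet`
#'   (`upper` / `lower`), one `molid`/`resid` per lipid.
#' @examples
#' bl <- build_bilayer(4)   # 2 x 2 grid per leaflet, 8 lipids
#' @export
build_bilayer <- function(n_per_leaflet, area_per_lipid = 0.63,
                          template = dppc_template(), tail_gap = 2.0) {
  n_per_leaflet <- as.integer(n_per_leaflet)
  if (is.na(n_per_leaflet) || n_per_leaflet < 1) {
    stop("n_per_leaflet must be a positive integer", call. = FALSE)
  }
  pitch <- sqrt(area_per_lipid) * 10         # A
  ncol_ <- ceiling(sqrt(n_per_leaflet))
  nrow_ <- ceiling(n_per_leaflet / ncol_)
  k <- seq_len(n_per_leaflet) - 1L
  gx <- (k %% ncol_) * pitch + pitch / 2
  gy <- (k %/% ncol_) * pitch + pitch / 2
  box <- c(ncol_ * pitch, nrow_ * pitch, NA)

  tpl <- tibble::as_tibble(template)
  zmin <- min(tpl$z)
  tpl$z <- tpl$z - zmin + tail_gap / 2       # tails end at +tail_gap/2
  nat <- nrow(tpl)

  leaflet_atoms <- function(upper) {
    t2 <- tpl
    if (!upper) t2$z <- -t2$z
    df <- t2[rep(seq_len(nat), n_per_leaflet), ]
    df$x <- df$x + rep(gx, each = nat)
    df$y <- df$y + rep(gy, each = nat)
    df$resid <- rep(seq_len(n_per_leaflet), each = nat)
    df$molid <- df$resid
    df$leaflet <- if (upper) "upper" else "lower"
    df
  }
  up <- leaflet_atoms(TRUE)
  lo <- leaflet_atoms(FALSE)
  lo$resid <- lo$resid + n_per_leaflet
  lo$molid <- lo$molid + n_per_leaflet
  all_ <- dplyr::bind_rows(up, lo)
  all_$atom_id <- seq_len(nrow(all_))
  zspan <- range(all_$z)
  box[3] <- diff(zspan) + 2
  out <- nf_structure(all_, box = box)
  attr(out, "n_per_leaflet") <- n_per_leaflet
  attr(out, "area_per_lipid") <- area_per_lipid
  attr(out, "leaflet_area_nm2") <- n_per_leaflet * area_per_lipid
  out
}

#' Solvate a box with a rigid three-site water lattice
#'
#' Waters are placed on a near-cubic lattice at bulk density (33.4
#' molecules/nm^3) and molecules overlapping the solute (any solute atom
#' within `exclusion` of the water oxygen) are removed. Geometry is the
#' rigid 3-site model: O-H 0.9572 A, H-O-H 104.52 degrees, identical for
#' every molecule. Placement is deterministic.
#'
#' @param structure solute atom tibble (may be empty).
#' @param box length-3 box edges (A); must enclose the solute.
#' @param density molecules per nm^3 (default 33.4, ambient water).
#' @param exclusion solute-oxygen exclusion radius (A).
#' @return solute plus waters (resname `SOL`, names `OW`,`HW1`,`HW2`), box
#'   attribute set.
#' @export
solvate <- function(structure, box, density = 33.4, exclusion = 2.4) {
  stopifnot(length(box) == 3, all(box > 0))
  xyz <- coords(structure)
  if (nrow(xyz) > 0) {
    lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
    if (any(lo < -1e-6) || any(hi > box + 1e-6)) {
      stop("box smaller than solute", call. = FALSE)
    }
  }
  vol_nm3 <- prod(box) / 1000
  n_target <- round(density * vol_nm3)
  if (n_target < 1) return(structure)
  # grid dims: near-cubic, product as close to the target as possible
  s <- (prod(box) / n_target)^(1 / 3)
  nx <- max(1L, round(box[1] / s)); ny <- max(1L, round(box[2] / s))
  nz <- max(1L, round(n_target / (nx * ny)))
  ox <- (seq_len(nx) - 0.5) * box[1] / nx
  oy <- (seq_len(ny) - 0.5) * box[2] / ny
  oz <- (seq_len(nz) - 0.5) * box[3] / nz
  g <- expand.grid(x = ox, y = oy, z = oz)
  # remove waters overlapping the solute
  if (nrow(xyz) > 0) {
    keep <- !grid_near(as.matrix(g), xyz, exclusion)
    g <- g[keep, , drop = FALSE]
  }
  nw <- nrow(g)
  if (nw == 0) return(structure)
  # rigid 3-site geometry
  r_oh <- 0.9572; half <- 104.52 / 2 * pi / 180
  h1 <- c(r_oh * sin(half), 0, r_oh * cos(half))
  h2 <- c(-r_oh * sin(half), 0, r_oh * cos(half))
  wat <- tibble::tibble(
    element = rep(c("O", "H", "H"), nw),
    name = rep(c("OW", "HW1", "HW2"), nw),
    resid = rep(seq_len(nw), each = 3),
    resname = "SOL",
    molid = rep(seq_len(nw), each = 3),
    x = rep(g$x, each = 3) + rep(c(0, h1[1], h2[1]), nw),
    y = rep(g$y, each = 3) + rep(c(0, h1[2], h2[2]), nw),
    z = rep(g$z, each = 3) + rep(c(0, h1[3], h2[3]), nw),
    charge = rep(c(-0.834, 0.417, 0.417), nw))
  base <- tibble::as_tibble(structure)
  if (nrow(base) > 0) {
    wat$resid <- wat$resid + max(base$resid)
    wat$molid <- wat$molid + max(base$molid)
    wat$atom_id <- seq_len(nrow(wat)) + max(base$atom_id)
  } else {
    wat$atom_id <- seq_len(nrow(wat))
  }
  out <- nf_structure(dplyr::bind_rows(base, wat), box = box)
  for (a in c("shape", "glyco_bonds", "link_bonds", "graft_sites")) {
    attr(out, a) <- attr(structure, a)
  }
  out
}

# TRUE for grid points with any reference atom within cutoff (blocked)
grid_near <- function(g, ref, cutoff) {
  near <- logical(nrow(g))
  block <- max(1L, floor(2e6 / max(1, nrow(g))))
  c2 <- cutoff^2
  gg2 <- rowSums(g^2)
  i <- 1L
  while (i <= nrow(ref)) {
    j <- min(nrow(ref), i + block - 1L)
    rr <- ref[i:j, , drop = FALSE]
    d2 <- outer(gg2, rowSums(rr^2), "+") - 2 * tcrossprod(g, rr)
    near <- near | (rowSums(d2 <= c2) > 0)
    i <- j + 1L
  }
  near
}

#' Assemble the nanoparticle-bilayer simulation system
#'
#' Places the particle above the upper leaflet so that the smallest distance
#' from any particle atom to the upper phosphate plane (the mean z of the
#' upper-leaflet P atoms) equals `gap`, centres it laterally, optionally
#' solvates, and builds the component index.
#'
#' @param np functionalized particle (centred on its own origin).
#' @param bilayer from [build_bilayer()].
#' @param gap particle-to-phosphate-plane distance (A); 5 reproduces the
#'   published starting configuration.
#' @param solvate_system add the water phase (default `TRUE`; building the
#'   619k-atom water box is the slow step, so desk-scale work may skip it).
#' @param padding solvent padding above the particle / below the bilayer (A).
#' @param density,exclusion passed to [solvate()].
#' @return object of class `sim_system`: list with `structure` (component
#'   column set to np/lipid/water), `box`, `components` (count per
#'   component), `gap_realized` (A).
#' @export
assemble_system <- function(np, bilayer, gap = 5, solvate_system = TRUE,
                            padding = 10, density = 33.4, exclusion = 2.4) {
  box <- attr(bilayer, "box")
  bl <- tibble::as_tibble(bilayer)
  p_upper <- bl$z[bl$name == "P" & bl$leaflet == "upper"]
  if (length(p_upper) == 0) stop("bilayer has no upper-leaflet P atoms", call. = FALSE)
  p_plane <- mean(p_upper)

  npx <- tibble::as_tibble(np)
  np_width <- c(diff(range(npx$x)), diff(range(npx$y)))
  if (any(np_width > box[1:2])) {
    stop("nanoparticle lateral extent (", paste(round(np_width, 1), collapse = " x "),
         " A) exceeds the bilayer patch (", paste(round(box[1:2], 1), collapse = " x "),
         " A); build a larger bilayer", call. = FALSE)
  }
  shift <- c(box[1] / 2 - mean(range(npx$x)),
             box[2] / 2 - mean(range(npx$y)),
             p_plane + gap - min(npx$z))
  npx <- translate_structure(npx, shift)
  npx$component <- "np"
  bl$component <- "lipid"
  # shift everything so z starts at 0, with padding below and above
  zlo <- min(bl$z) - padding
  zhi <- max(npx$z) + padding
  npx$z <- npx$z - zlo; bl$z <- bl$z - zlo
  box[3] <- zhi - zlo
  merged <- merge_structures(bl, npx, box = box)
  merged$component <- c(bl$component, npx$component)
  if (solvate_system) {
    n0 <- nrow(merged)
    merged <- solvate(merged, box, density = density, exclusion = exclusion)
    merged$component <- c(c(bl$component, npx$component),
                          rep("water", nrow(merged) - n0))
  }
  p_plane_new <- mean(merged$z[merged$name == "P" &
                                 !is.na(merged$component) &
                                 merged$component == "lipid" &
                                 merged$z > (p_plane - zlo) - 1])
  npz <- merged$z[merged$component == "np"]
  structure(list(
    structure = merged, box = box,
    components = table(merged$component),
    gap_realized = min(npz) - (p_plane - zlo),
    p_plane = p_plane - zlo), class = "sim_system")
}

#' @export
print.sim_system <- function(x, ...) {
  cat("# Simulation system:", nrow(x$structure), "atoms —",
      paste(names(x$components), as.integer(x$components), collapse = ", "), "\n")
  cat(sprintf("# box %.1f x %.1f x %.1f A; particle-phosphate gap %.2f A\n",
              x$box[1], x$box[2], x$box[3], x$gap_realized))
  invisible(x)
}

#' @rdname assemble_system
#' @param x a `sim_system`.
#' @param ... unused.
#' @return `glance()`: one-row tibble with total and per-component atom
#'   counts, box edges and the realized gap.
#' @export
glance.sim_system <- function(x, ...) {
  tb <- as.list(x$components)
  tibble::tibble(n_atoms = nrow(x$structure),
                 n_np = tb$np %||% 0L, n_lipid = tb$lipid %||% 0L,
                 n_water = tb$water %||% 0L,
                 box_x = x$box[1], box_y = x$box[2], box_z = x$box[3],
                 gap_realized = x$gap_realized)
}
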