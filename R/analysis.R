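#' Hydrogen-bond geometric criteria
#'
#' Two criteria classes are supported: conventional `OH...O` bonds and the
#' weaker, less directional `CH...O` bonds that carbohydrates form with
#' choline groups. Defaults: OH...O donor-acceptor <= 3.5 A and
#' donor-H-acceptor angle >= 150 degrees; CH...O <= 3.8 A and >= 130
#' degrees. The looser CH...O thresholds reflect the weaker directionality
#' of carbon donors; both are configurable.
#'
#' @param class `"OH...O"` or `"CH...O"`.
#' @param dist_max donor-acceptor distance cutoff (A).
#' @param angle_min donor-H-acceptor angle cutoff (degrees).
#' @return one-row tibble; pass a row-bound set to [detect_hbonds()].
#' @export
hbond_criteria <- function(class = c("OH...O", "CH...O"), dist_max = NULL,
                           angle_min = NULL) {
  class <- match.arg(class)
  if (is.null(dist_max)) dist_max <- if (class == "OH...O") 3.5 else 3.8
  if (is.null(angle_min)) angle_min <- if (class == "OH...O") 150 else 130
  stopifnot(dist_max > 0, angle_min > 0, angle_min <= 180)
  tibble::tibble(class = class, dist_max = dist_max, angle_min = angle_min)
}

#' Default criteria set (OH...O plus CH...O)
#' @param include_ch_o include the weak-carbon-donor class (default `TRUE`).
#' @return criteria tibble.
#' @export
default_hbond_criteria <- function(include_ch_o = TRUE) {
  out <- hbond_criteria("OH...O")
  if (include_ch_o) out <- dplyr::bind_rows(out, hbond_criteria("CH...O"))
  out
}

#' Detect hydrogen bonds in one frame
#'
#' Emits every donor-hydrogen-acceptor triple (D, H, A) with D in the donor
#' selection carrying a covalently bonded H, A in the acceptor selection,
#' D-A distance within the class cutoff and D-H...A angle at least the class
#' minimum. O/N donors are matched against the `OH...O` criteria row, C
#' donors against `CH...O` (and are only considered when that row is
#' present).
#'
#' @param frame atom tibble (one frame).
#' @param bonds two-column atom-id pairs (used to find each donor's H).
#' @param donors,acceptors integer vectors of atom ids (heavy atoms).
#' @param criteria tibble from [default_hbond_criteria()].
#' @return tibble of records: `donor`, `hydrogen`, `acceptor`, `class`,
#'   `distance`, `angle`, `donor_resid`, `donor_resname`.
#' @export
detect_hbonds <- function(frame, bonds, donors, acceptors,
                          criteria = default_hbond_criteria()) {
  if (length(donors) == 0 || length(acceptors) == 0) {
    stop("empty donor or acceptor selection", call. = FALSE)
  }
  idx <- stats::setNames(seq_len(nrow(frame)), frame$atom_id)
  el <- frame$element
  # hydrogens attached to each donor
  b <- rbind(as.matrix(bonds), as.matrix(bonds)[, 2:1, drop = FALSE])
  hb <- b[el[idx[as.character(b[, 2])]] == "H", , drop = FALSE]
  h_of <- split(hb[, 2], hb[, 1])
  don_el <- el[idx[as.character(donors)]]
  cls_of_donor <- ifelse(don_el == "C", "CH...O", "OH...O")
  use <- cls_of_donor %in% criteria$class
  donors <- donors[use]; cls_of_donor <- cls_of_donor[use]
  if (length(donors) == 0) return(empty_hbond_records())
  no_h <- !(as.character(donors) %in% names(h_of))
  if (any(no_h)) {
    stop("configuration error: donor atom(s) without a bonded hydrogen: ",
         paste(utils::head(donors[no_h], 5), collapse = ", "), call. = FALSE)
  }
  xyz <- coords(frame)
  dmax <- max(criteria$dist_max)
  dxyz <- xyz[idx[as.character(donors)], , drop = FALSE]
  axyz <- xyz[idx[as.character(acceptors)], , drop = FALSE]
  d2 <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") - 2 * tcrossprod(dxyz, axyz)
  hits <- which(d2 <= dmax^2 & d2 > 1e-12, arr.ind = TRUE)
  recs <- list()
  for (r in seq_len(nrow(hits))) {
    di <- hits[r, 1]; ai <- hits[r, 2]
    d_id <- donors[di]; a_id <- acceptors[ai]
    if (d_id == a_id) next
    cls <- cls_of_donor[di]
    crit <- criteria[criteria$class == cls, ]
    dist <- sqrt(d2[di, ai])
    if (dist > crit$dist_max) next
    for (h_id in h_of[[as.character(d_id)]]) {
      hv <- xyz[idx[as.character(h_id)], ]
      v1 <- xyz[idx[as.character(d_id)], ] - hv
      v2 <- xyz[idx[as.character(a_id)], ] - hv
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= crit$angle_min) {
        ii <- idx[as.character(d_id)]
        recs[[length(recs) + 1]] <- tibble::tibble(
          donor = d_id, hydrogen = h_id, acceptor = a_id, class = cls,
          distance = dist, angle = ang,
          donor_resid = frame$resid[ii], donor_resname = frame$resname[ii])
      }
    }
  }
  if (!length(recs)) return(empty_hbond_records())
  dplyr::bind_rows(recs)
}

empty_hbond_records <- function() {
  tibble::tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                 class = character(), distance = numeric(), angle = numeric(),
                 donor_resid = integer(), donor_resname = character())
}

#' Summarise hydrogen bonds over a trajectory
#'
#' Counts bonds per (donor residue type, acceptor group) in every frame,
#' normalises by the number of donor residues of that type (the published
#' convention: "bonds per residue, on average"), and reports the time mean
#' with a block-averaged standard error.
#'
#' @param frames list of atom tibbles (one per frame, same atoms).
#' @param bonds,donors,acceptors,criteria as in [detect_hbonds()].
#' @param groups named list of acceptor atom-id vectors (e.g. `phosphate`,
#'   `choline`); acceptors outside every group count as `other`.
#' @param n_blocks blocks for the standard error (default 5).
#' @return object of class `hbond_summary`: tibble with `donor_resname`,
#'   `acceptor_group`, `mean_bonds` (per donor residue per frame), `se`
#'   (block SE), `n_frames`.
#' @export
hbond_summary <- function(frames, bonds, donors, acceptors, groups,
                          criteria = default_hbond_criteria(), n_blocks = 5) {
  if (length(frames) == 0) stop("empty trajectory", call. = FALSE)
  f1 <- frames[[1]]
  idx <- stats::setNames(seq_len(nrow(f1)), f1$atom_id)
  don_res <- unique(f1[idx[as.character(donors)], c("resid", "resname")])
  n_res_of <- table(don_res$resname)
  group_of <- rep("other", length(acceptors))
  names(group_of) <- as.character(acceptors)
  for (g in names(groups)) {
    group_of[as.character(intersect(acceptors, groups[[g]]))] <- g
  }
  cells <- expand.grid(donor_resname = names(n_res_of),
                       acceptor_group = unique(c(names(groups), "other")),
                       stringsAsFactors = FALSE)
  per_frame <- matrix(0, nrow(cells), length(frames))
  for (t in seq_along(frames)) {
    recs <- detect_hbonds(frames[[t]], bonds, donors, acceptors, criteria)
    if (nrow(recs)) {
      recs$acceptor_group <- group_of[as.character(recs$acceptor)]
      cnt <- dplyr::count(recs, .data$donor_resname, .data$acceptor_group)
      key <- paste(cnt$donor_resname, cnt$acceptor_group)
      m <- match(key, paste(cells$donor_resname, cells$acceptor_group))
      per_frame[m[!is.na(m)], t] <- cnt$n[!is.na(m)]
    }
  }
  norm <- as.numeric(n_res_of[cells$donor_resname])
  per_frame <- per_frame / norm
  mean_ <- rowMeans(per_frame)
  se <- apply(per_frame, 1, block_se, n_blocks = n_blocks)
  out <- tibble::as_tibble(cells)
  out$mean_bonds <- mean_
  out$se <- se
  out$n_frames <- length(frames)
  class(out) <- c("hbond_summary", class(out))
  out
}

# block-averaged standard error of a time series
block_se <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks * 2) return(stats::sd(x) / sqrt(max(1, n)))
  size <- floor(n / n_blocks)
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(x[((b - 1) * size + 1):(b * size)]), 1.0)
  stats::sd(bm) / sqrt(n_blocks)
}

#' Per-frame minimum distance between the particle and the phosphate plane
#'
#' The phosphate plane is the mean z of the selected phosphorus atoms in each
#' frame; the reported value is the signed minimum over particle atoms of
#' (z - plane), so a particle that has penetrated below the plane gives a
#' negative distance.
#'
#' @param frames list of atom tibbles.
#' @param np_ids,p_ids atom-id selections for the particle and the
#'   phosphates.
#' @return tibble `frame`, `distance` (A).
#' @export
np_membrane_distance <- function(frames, np_ids, p_ids) {
  if (length(np_ids) == 0 || length(p_ids) == 0) {
    stop("empty selection", call. = FALSE)
  }
  out <- purrr::imap(frames, function(fr, t) {
    plane <- mean(fr$z[fr$atom_id %in% p_ids])
    tibble::tibble(frame = t, distance = min(fr$z[fr$atom_id %in% np_ids]) - plane)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("nf_distance_series", class(res))
  res
}

#' Region-of-interest signal-to-noise ratio of a grayscale image
#'
#' `SNR = 0.655 * ROI_tumor / averageROI_background`, where `ROI_tumor` is
#' the mean intensity inside the tumor mask and `averageROI_background` the
#' mean of the per-ROI mean intensities of the background masks. The 0.655
#' factor is the standard Rayleigh-noise correction for single-coil
#' magnitude MR images.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param tumor_mask logical matrix, same dim as `image`.
#' @param background_masks logical matrix or list of logical matrices.
#' @return object of class `roi_analysis` (one-row tibble): `roi_tumor`,
#'   `average_background`, `snr`.
#' @examples
#' img <- matrix(100, 32, 32)
#' tm <- matrix(FALSE, 32, 32); tm[4:8, 4:8] <- TRUE
#' bg <- matrix(FALSE, 32, 32); bg[20:28, 20:28] <- TRUE
#' snr(img, tm, bg)$snr  # 0.655: equal means
#' @export
snr <- function(image, tumor_mask, background_masks) {
  if (!is.list(background_masks)) background_masks <- list(background_masks)
  stopifnot(is.matrix(image), all(dim(tumor_mask) == dim(image)))
  if (!any(tumor_mask)) stop("empty tumor ROI", call. = FALSE)
  if (length(background_masks) == 0 ||
      any(!vapply(background_masks, any, TRUE))) {
    stop("empty background ROI", call. = FALSE)
  }
  roi_tumor <- mean(image[tumor_mask])
  bg_means <- vapply(background_masks, function(m) mean(image[m]), 1.0)
  avg_bg <- mean(bg_means)
  if (avg_bg <= 0) stop("non-positive background mean", call. = FALSE)
  out <- tibble::tibble(roi_tumor = roi_tumor, average_background = avg_bg,
                        snr = 0.655 * roi_tumor / avg_bg)
  class(out) <- c("roi_analysis", class(out))
  out
}

#' Contrast-to-noise ratio from pre- and post-contrast SNR
#'
#' Computed as `SNR_pre - SNR_post`, exactly as the imaging protocol prints
#' it (the sign convention is preserved; the magnitude is also returned).
#'
#' @param snr_pre,snr_post numeric SNR values (or `roi_analysis` rows).
#' @return tibble `cnr`, `magnitude`.
#' @export
cnr <- function(snr_pre, snr_post) {
  p <- if (is.data.frame(snr_pre)) snr_pre$snr else snr_pre
  q <- if (is.data.frame(snr_post)) snr_post$snr else snr_post
  stopifnot(is.finite(p), is.finite(q))
  tibble::tibble(cnr = p - q, magnitude = abs(p - q))
}

#' Tumor volume from caliper length and width
#'
#' `V = (length / 2) * width^2` — the standard ellipsoid approximation for
#' subcutaneous xenografts measured with calipers.
#'
#' @param length,width caliper measurements (mm).
#' @return volume (mm^3), vectorised.
#' @examples
#' tumor_volume(2, 1)   # 1
#' tumor_volume(10, 4)  # 80
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) {
    stop("length and width must be non-negative", call. = FALSE)
  }
  (length / 2) * width^2
}

#' Acceptor groups of a DPPC bilayer by atom name
#'
#' Phosphate group: P plus its bonded oxygens (`O11`-`O14`). Choline group:
#' N plus its bonded carbons and their hydrogens.
#'
#' @param structure atom tibble containing the lipids.
#' @return named list of atom-id vectors (`phosphate`, `choline`).
#' @export
lipid_acceptor_groups <- function(structure) {
  list(
    phosphate = select_atoms(structure, name = c("P", "O11", "O12", "O13", "O14"),
                             resname = "DPC"),
    choline = structure$atom_id[structure$resname == "DPC" &
                                  (structure$name %in% c("N", "C12", "C13", "C14", "C15") |
                                     grepl("^HN", structure$name) |
                                     grepl("^HC12", structure$name))])
}
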