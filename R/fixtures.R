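#' The packaged magnetite unit cell
#'
#' Reads the synthetic magnetite CIF shipped with the package: an
#' inverse-spinel Fe3O4 conventional cell (Fd-3m, origin choice 2,
#' a = 8.3958 A) with Fe on the tetrahedral 8a and octahedral 16d Wyckoff
#' sites and O on 32e (u = 0.2549). The full cell holds 24 Fe + 32 O. The
#' fixture emulates the crystallography-open-database magnetite entry so no
#' download is needed; substitute a genuine CIF via [read_cif()] at will.
#'
#' @param path optional substitute CIF file.
#' @return a `unit_cell` (see [read_cif()]).
#' @examples
#' cell <- magnetite_cell()
#' table(cell$sites$element)  # Fe 24, O 32
#' @export
magnetite_cell <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "magnetite_synthetic.cif",
                        package = "nanoforge")
  }
  read_cif(path)
}

#' Synthetic hydrogen-bond trajectory with planted ground truth
#'
#' Builds a minimal donor/acceptor scene — one donor residue per requested
#' residue type, `count` donor-H pairs each, one acceptor per pair assigned
#' to the requested acceptor group — and emits `n_frames` frames in which
#' each planted bond satisfies the default OH...O criteria in a Bernoulli
#' fraction of frames (acceptors of "absent" bonds are displaced out of
#' range). The exact per-cell ground-truth means realized in the emitted
#' frames are returned, so recovery can be asserted without statistical
#' slack.
#'
#' @param n_frames number of frames (>= 1).
#' @param planted tibble with columns `donor_resname`, `group`
#'   (`phosphate` / `choline` / `other`), `count` (bonds per residue) and
#'   `fraction` (per-frame presence probability in `[0, 1]`).
#' @param noise coordinate jitter s.d. (A), small enough not to break the
#'   planted geometry (kept below 0.05 A internally).
#' @param seed integer seed; same seed, same trajectory, bit for bit.
#' @return list: `frames` (list of atom tibbles), `bonds`, `donors`,
#'   `acceptors`, `groups`, `truth` (tibble with the realized per-cell
#'   means), `presence` (logical matrix bonds x frames).
#' @export
synth_hbond_trajectory <- function(n_frames,
                                   planted = tibble::tibble(
                                     donor_resname = c("GAL", "ARA"),
                                     group = "phosphate",
                                     count = 2, fraction = 1),
                                   noise = 0, seed = 1) {
  stopifnot(n_frames >= 1)
  if (any(planted$fraction < 0 | planted$fraction > 1)) {
    stop("planted fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(planted$count < 1)) stop("planted count must be >= 1", call. = FALSE)
  noise <- min(noise, 0.05)
  rows <- list(); bonds <- list()
  donors <- integer(); acceptors <- integer()
  groups <- list(phosphate = integer(), choline = integer())
  bond_meta <- list()
  aid <- 0L
  type_resid <- stats::setNames(seq_along(unique(planted$donor_resname)),
                                unique(planted$donor_resname))
  for (p in seq_len(nrow(planted))) {
    # one donor residue per residue type: per-residue means equal the
    # planted counts regardless of how many rows share a type
    resid <- unname(type_resid[planted$donor_resname[p]])
    for (k in seq_len(planted$count[p])) {
      base <- c(20 * p, 8 * k, 0)  # well-separated scene per bond
      d_id <- aid + 1L; h_id <- aid + 2L; a_id <- aid + 3L
      rows[[length(rows) + 1]] <- tibble::tibble(
        atom_id = c(d_id, h_id, a_id),
        element = c("O", "H", "O"),
        name = c("OD", "HD", "OA"),
        resid = c(resid, resid, 1000L + p),
        resname = c(planted$donor_resname[p], planted$donor_resname[p], "ACC"),
        molid = 1L,
        x = base[1] + c(0, 0, 0), y = base[2] + c(0, 0, 0),
        z = base[3] + c(0, 0.96, 2.8))   # collinear O-H...O, D-A 2.8 A
      bonds[[length(bonds) + 1]] <- c(d_id, h_id)
      donors <- c(donors, d_id)
      acceptors <- c(acceptors, a_id)
      if (planted$group[p] %in% names(groups)) {
        groups[[planted$group[p]]] <- c(groups[[planted$group[p]]], a_id)
      }
      bond_meta[[length(bond_meta) + 1]] <- tibble::tibble(
        acceptor = a_id, donor_resname = planted$donor_resname[p],
        group = planted$group[p], fraction = planted$fraction[p])
      aid <- aid + 3L
    }
  }
  base_frame <- nf_structure(dplyr::bind_rows(rows))
  meta <- dplyr::bind_rows(bond_meta)
  set.seed(seed %% .Machine$integer.max)
  presence <- matrix(stats::runif(nrow(meta) * n_frames) < meta$fraction,
                     nrow(meta), n_frames)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    fr <- base_frame
    off <- which(!presence[, t])
    if (length(off)) {
      rows_off <- match(meta$acceptor[off], fr$atom_id)
      fr$z[rows_off] <- fr$z[rows_off] + 6  # far outside any cutoff
    }
    if (noise > 0) {
      fr$x <- fr$x + stats::rnorm(nrow(fr), 0, noise)
      fr$y <- fr$y + stats::rnorm(nrow(fr), 0, noise)
      fr$z <- fr$z + stats::rnorm(nrow(fr), 0, noise)
    }
    frames[[t]] <- fr
  }
  truth <- meta
  truth$realized <- rowMeans(presence)
  truth_cells <- truth |>
    dplyr::group_by(.data$donor_resname, .data$group) |>
    dplyr::summarise(mean_bonds = sum(.data$realized), .groups = "drop")
  list(frames = frames, bonds = do.call(rbind, bonds), donors = donors,
       acceptors = acceptors, groups = groups, truth = truth_cells,
       presence = presence)
}

#' Synthetic grayscale image with tumor and background ROIs
#'
#' A flat image carrying one disk-shaped tumor ROI at the requested mean
#' intensity and three disjoint background disks at the background mean,
#' plus optional Gaussian noise. Returns the masks and the noise-free
#' ground-truth SNR (`0.655 * tumor_mean / background_mean`).
#'
#' @param shape image dimensions (rows, cols), default `c(128, 128)`.
#' @param tumor_mean,background_mean ROI intensities (> 0).
#' @param noise_sd Gaussian noise s.d. (0 for a deterministic image).
#' @param seed integer seed.
#' @return list: `image` (matrix), `tumor_mask`, `background_masks` (list of
#'   3), `snr_truth`.
#' @export
synth_roi_image <- function(shape = c(128, 128), tumor_mean = 100,
                            background_mean = 100, noise_sd = 0, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 16))
  if (tumor_mean <= 0 || background_mean <= 0) {
    stop("ROI means must be > 0", call. = FALSE)
  }
  disk <- function(cx, cy, r) {
    outer(seq_len(shape[1]), seq_len(shape[2]),
          function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
  }
  r <- round(min(shape) * 0.1)
  tumor <- disk(shape[1] * 0.3, shape[2] * 0.3, r)
  bgs <- list(disk(shape[1] * 0.75, shape[2] * 0.25, r),
              disk(shape[1] * 0.25, shape[2] * 0.75, r),
              disk(shape[1] * 0.75, shape[2] * 0.75, r))
  overlap <- tumor & Reduce(`|`, bgs)
  if (any(overlap) || any(bgs[[1]] & bgs[[2]]) || any(bgs[[1]] & bgs[[3]]) ||
      any(bgs[[2]] & bgs[[3]])) {
    stop("overlapping ROI masks", call. = FALSE)
  }
  img <- matrix(background_mean, shape[1], shape[2])
  img[tumor] <- tumor_mean
  if (noise_sd > 0) {
    set.seed(seed %% .Machine$integer.max)
    img <- img + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                        shape[1], shape[2])
  }
  list(image = img, tumor_mask = tumor, background_masks = bgs,
       snr_truth = 0.655 * tumor_mean / background_mean)
}
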