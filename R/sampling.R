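#' Circumferential sampling grid
#'
#' Controls how regional time-activity curves are sampled from a gated
#' study: the number of angular samples per short-axis slice, the slice
#' range, and the radial search annulus around the myocardial peak.
#'
#' @param n_angles angular samples per slice (default 36, minimum 8).
#' @param slice_range optional inclusive `(apical, basal)` slice bounds;
#'   by default every slice whose total counts reach 10% of the busiest
#'   slice is used.
#' @param radial_window_mm half-width in mm of the annulus around the
#'   per-profile count peak searched for the myocardial sample (default 20).
#' @param angle_offset_deg rotation of the first sample away from the
#'   anterior wall (default 5, placing samples between AHA sector edges).
#' @param radial_step_px radial sampling step in pixels (default 0.5).
#' @return object of class `sampling_grid`.
#' @export
sampling_grid <- function(n_angles = 36, slice_range = NULL,
                          radial_window_mm = 20, angle_offset_deg = 5,
                          radial_step_px = 0.5) {
  if (n_angles < 8) stop("validation error: n_angles must be >= 8")
  structure(list(n_angles = as.integer(n_angles), slice_range = slice_range,
                 radial_window_mm = radial_window_mm,
                 angle_offset_deg = angle_offset_deg,
                 radial_step_px = radial_step_px),
            class = "sampling_grid")
}

#' Per-slice myocardial centers
#'
#' Count-weighted centroid of each short-axis slice, smoothed with a
#' 3-slice running mean along the long axis. All-zero slices are marked
#' invalid and excluded from sampling.
#'
#' @param study a [gated_study()].
#' @param frame frame index to use, or `NULL` (default) for the
#'   frame-summed image.
#' @return data frame with `slice`, `row`, `col`, `valid`.
#' @export
find_center <- function(study, frame = NULL) {
  stopifnot(inherits(study, "gated_study"))
  img <- if (is.null(frame)) colSums(study$counts)
         else study$counts[frame, , , ]
  S <- dim(img)[1]
  rows <- cols <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    m <- img[s, , ]
    tot <- sum(m)
    if (tot > 0) {
      rows[s] <- sum(row(m) * m) / tot
      cols[s] <- sum(col(m) * m) / tot
    }
  }
  sm <- function(x) {
    y <- x
    for (s in seq_along(x)) {
      w <- max(1, s - 1):min(length(x), s + 1)
      if (!is.na(x[s])) y[s] <- mean(x[w], na.rm = TRUE)
    }
    y
  }
  data.frame(slice = seq_len(S), row = sm(rows), col = sm(cols),
             valid = !is.na(rows))
}

# Radial profiles for every (frame, used slice, angle, radius) by bilinear
# interpolation along rays from the per-slice center. The workhorse shared
# by sample_profiles() and estimate_volumes().
ray_profiles <- function(study, grid = sampling_grid(), centers = NULL) {
  counts <- study$counts
  d <- dim(counts)
  nf <- d[1]; S <- d[2]; M <- d[3]
  if (is.null(centers)) centers <- find_center(study)
  slice_tot <- apply(counts, 2, sum)
  used <- if (!is.null(grid$slice_range)) {
    seq(grid$slice_range[1], grid$slice_range[2])
  } else {
    which(slice_tot >= 0.10 * max(slice_tot) & centers$valid)
  }
  if (!length(used)) stop("validation error: empty slice range")
  if (any(used < 1 | used > S))
    stop("validation error: slice range outside study")
  A <- grid$n_angles
  ang <- (grid$angle_offset_deg + (seq_len(A) - 1) * 360 / A) %% 360
  r_px <- seq(grid$radial_step_px, M / 2 - 2, by = grid$radial_step_px)
  R <- length(r_px)
  th <- ang * pi / 180
  dr <- outer(-cos(th), r_px)           # [A, R] row offsets
  dc <- outer(sin(th), r_px)
  prof <- array(0, c(nf, length(used), A, R))
  for (si in seq_along(used)) {
    s <- used[si]
    rowf <- centers$row[s] + dr
    colf <- centers$col[s] + dc
    i0 <- pmin(pmax(floor(rowf), 1), M - 1)
    j0 <- pmin(pmax(floor(colf), 1), M - 1)
    fr <- pmin(pmax(rowf - i0, 0), 1)
    fc <- pmin(pmax(colf - j0, 0), 1)
    V <- matrix(counts[, s, , ], nf, M * M)
    id <- function(i, j) as.vector(i + (j - 1) * M)
    wt <- function(w) rep(as.vector(w), each = nf)  # per-column weights
    p <- V[, id(i0, j0)] * wt((1 - fr) * (1 - fc)) +
         V[, id(i0 + 1, j0)] * wt(fr * (1 - fc)) +
         V[, id(i0, j0 + 1)] * wt((1 - fr) * fc) +
         V[, id(i0 + 1, j0 + 1)] * wt(fr * fc)
    prof[, si, , ] <- array(p, c(nf, A, R))
  }
  list(prof = prof, r_px = r_px, r_mm = r_px * study$pixel_mm,
       slices = used, angles = ang, centers = centers,
       pixel_mm = study$pixel_mm, slice_mm = study$slice_mm)
}

#' Sample regional time-activity curves
#'
#' For every used slice and sample angle, the time-activity curve is the
#' maximum count along the radial ray within an annulus of
#' `radial_window_mm` around the (frame-summed) profile peak — the standard
#' maximal-count circumferential-profile convention behind polar maps.
#' The basal 20% of used slices are flagged `basal` for base-cut handling.
#'
#' @param study a [gated_study()].
#' @param grid a [sampling_grid()].
#' @return object of class `sample_tacs`: a TAC matrix
#'   `[n_samples, n_frames]` plus per-sample `slice`, `angle_deg` and
#'   `basal` descriptors. Samples are ordered slice-major, apex first.
#' @export
sample_profiles <- function(study, grid = sampling_grid()) {
  rays <- ray_profiles(study, grid)
  prof <- rays$prof
  dn <- dim(prof)                     # [F, S, A, R]
  sum_sa <- colSums(prof)                            # [S, A, R]
  peak <- max.col(matrix(sum_sa, dn[2] * dn[3], dn[4]),
                  ties.method = "first")             # radius index, (s, a)
  ring <- array(abs(outer(rays$r_mm[peak], rays$r_mm, "-")) <=
                  grid$radial_window_mm, dn[2:4])    # [S, A, R]
  ringf <- aperm(array(ring, c(dn[2], dn[3], dn[4], dn[1])), c(4, 1, 2, 3))
  masked <- ifelse(ringf, prof, -Inf)
  tacvec <- Reduce(pmax, asplit(matrix(masked, ncol = dn[4]), 2))
  tac_fsa <- array(tacvec, dn[1:3])                  # [F, S, A]
  # row order: angle fastest within slice, slices apex-first
  tac <- matrix(aperm(tac_fsa, c(3, 2, 1)), dn[2] * dn[3], dn[1])
  n_used <- length(rays$slices)
  slice_id <- rep(rays$slices, each = grid$n_angles)
  n_basal <- ceiling(0.2 * n_used)
  basal_slices <- rays$slices[(n_used - n_basal + 1):n_used]
  structure(list(
    tac = tac, slice = slice_id,
    angle_deg = rep(rays$angles, n_used),
    basal = slice_id %in% basal_slices,
    n_frames = dn[1], n_angles = grid$n_angles,
    slices = rays$slices, slices_all = rays$slices,
    pixel_mm = study$pixel_mm, slice_mm = study$slice_mm,
    centers = rays$centers),
    class = "sample_tacs")
}

#' @export
print.sample_tacs <- function(x, ...) {
  cat(sprintf("Sampled TACs: %d samples (%d slices x %d angles, %d frames)\n",
              nrow(x$tac), length(x$slices), x$n_angles, x$n_frames))
  invisible(x)
}

sample_amplitude <- function(samples) {
  apply(samples$tac, 1, max) - apply(samples$tac, 1, min)
}

drop_samples <- function(samples, keep) {
  samples$tac <- samples$tac[keep, , drop = FALSE]
  samples$slice <- samples$slice[keep]
  samples$angle_deg <- samples$angle_deg[keep]
  samples$basal <- samples$basal[keep]
  samples$slices <- sort(unique(samples$slice))
  samples
}

#' Remove basal slices contaminated by the membranous base
#'
#' Automatic mode removes basal-flagged slices whose mean sample amplitude
#' falls below `frac` (default 0.5) of the mid-ventricular mean amplitude —
#' the equivalent of the manual basal adjustment and basal circular removal
#' offered by clinical packages — and never removes more than 40% of
#' slices. Manual mode removes exactly the stated slices.
#'
#' @param samples a [sample_profiles()] result.
#' @param mode `"auto"` or `"manual"`.
#' @param manual_slices slice indices to remove in manual mode.
#' @param frac amplitude fraction threshold for auto mode.
#' @return filtered `sample_tacs`.
#' @export
base_cut <- function(samples, mode = c("auto", "manual"),
                     manual_slices = NULL, frac = 0.5) {
  stopifnot(inherits(samples, "sample_tacs"))
  mode <- match.arg(mode)
  if (!nrow(samples$tac)) stop("validation error: no samples")
  if (mode == "manual") {
    if (is.null(manual_slices)) return(samples)
    if (!all(manual_slices %in% samples$slices))
      stop("validation error: manual slices outside the sampled range")
    return(drop_samples(samples, !(samples$slice %in% manual_slices)))
  }
  amp <- sample_amplitude(samples)
  sl <- samples$slices
  slice_amp <- vapply(sl, function(s) mean(amp[samples$slice == s]),
                      numeric(1))
  n <- length(sl)
  mid <- sl[seq(floor(n / 3) + 1, ceiling(2 * n / 3))]
  mid_mean <- mean(slice_amp[sl %in% mid])
  basal_sl <- unique(samples$slice[samples$basal])
  low <- basal_sl[slice_amp[match(basal_sl, sl)] < frac * mid_mean]
  max_rm <- floor(0.4 * n)
  if (length(low) > max_rm) {
    ord <- order(slice_amp[match(low, sl)])
    low <- low[ord][seq_len(max_rm)]
  }
  if (!length(low)) return(samples)
  drop_samples(samples, !(samples$slice %in% low))
}

#' Smooth a phase map on the (slice, angle) grid
#'
#' Circular-aware weighted smoothing of per-sample phases: phases are
#' averaged as unit vectors with a Gaussian kernel in the angular direction
#' (wrap-safe in both the sample angle and the phase itself) and along the
#' slice axis. A zero kernel is the identity. The analogue of the phase-map
#' smoothing function in clinical software.
#'
#' @param phases matrix `[n_slices, n_angles]` of phases in degrees; `NA`
#'   cells are ignored and returned unchanged.
#' @param kernel_deg angular FWHM of the kernel in degrees.
#' @param kernel_slices Gaussian sigma along the slice axis, in slices
#'   (0 = no axial smoothing).
#' @return smoothed phase matrix.
#' @export
smooth_phases <- function(phases, kernel_deg, kernel_slices = 0) {
  stopifnot(is.matrix(phases))
  if (kernel_deg < 0 || kernel_slices < 0)
    stop("validation error: negative kernel")
  if (kernel_deg == 0 && kernel_slices == 0) return(phases)
  S <- nrow(phases); A <- ncol(phases)
  ang <- (seq_len(A) - 1) * 360 / A
  d_ang <- abs(outer(ang, ang, "-"))
  d_ang <- pmin(d_ang, 360 - d_ang)
  sig_a <- kernel_deg / 2.3548
  Wa <- if (sig_a > 0) exp(-0.5 * (d_ang / sig_a)^2) else diag(A)
  Ws <- if (kernel_slices > 0)
    exp(-0.5 * (outer(seq_len(S), seq_len(S), "-") / kernel_slices)^2)
  else diag(S)
  ok <- !is.na(phases) + 0
  u <- ifelse(is.na(phases), 0, cos(phases * pi / 180))
  v <- ifelse(is.na(phases), 0, sin(phases * pi / 180))
  num_u <- Ws %*% u %*% t(Wa)
  num_v <- Ws %*% v %*% t(Wa)
  wsum <- Ws %*% ok %*% t(Wa)
  out <- (atan2(num_v, num_u) * 180 / pi) %% 360
  out[wsum == 0 | is.na(phases)] <- NA
  out[is.na(phases)] <- phases[is.na(phases)]
  out
}

#' Aggregate samples into AHA 17-segment time-activity curves
#'
#' Used slices are banded apex-to-base by [slice_bands()] (apical cap, then
#' apical/mid/basal thirds); sample angles map to AHA sectors via
#' [aha_sector()]. Each segment's TAC is the mean of its member sample
#' TACs. Segments without members (e.g. after removing apex slices) are
#' flagged absent.
#'
#' @param samples a [sample_profiles()] (possibly [base_cut()]) result.
#' @param grid unused; accepted for interface symmetry.
#' @return object of class `segment_tacs`: `tac` (`17 x n_frames`),
#'   `present`, `n_members`.
#' @export
aggregate_17seg <- function(samples, grid = NULL) {
  stopifnot(inherits(samples, "sample_tacs"))
  all_sl <- samples$slices_all
  bands <- slice_bands(length(all_sl))
  band_of <- bands[match(samples$slice, all_sl)]
  seg <- aha_sector(samples$angle_deg, band_of)
  tac <- matrix(NA_real_, 17, samples$n_frames)
  n_members <- integer(17)
  for (g in 1:17) {
    idx <- which(seg == g)
    n_members[g] <- length(idx)
    if (length(idx))
      tac[g, ] <- colMeans(samples$tac[idx, , drop = FALSE])
  }
  structure(list(tac = tac, present = n_members > 0, n_members = n_members,
                 n_frames = samples$n_frames,
                 segment = seq_len(17), names = aha_segment_names()),
            class = "segment_tacs")
}

#' @export
print.segment_tacs <- function(x, ...) {
  cat(sprintf("17-segment TACs (%d frames); absent: %s\n", x$n_frames,
              if (all(x$present)) "none"
              else paste(which(!x$present), collapse = ", ")))
  invisible(x)
}
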