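#' Specify a digital gated-SPECT phantom
#'
#' Defines a left ventricle as a half-ellipsoid myocardial shell (hemispheric
#' apex, open base, long axis along the slice axis) with uniform tracer
#' concentration. Per-segment wall thickness varies over the cardiac cycle as
#' \deqn{w(t) = w_{ED} + \Delta w \, (1 - \cos(\theta_t - \delta_{seg}))/2,}
#' so thickness (end-systole) peaks at cycle angle 180 degrees plus the
#' segmental delay. The endocardial radius scales each frame so that cavity
#' volume interpolates from EDV to ESV and attains the requested ejection
#' fraction; the long axis stays fixed (pure radial contraction), so no
#' through-plane motion confounds slice-wise sampling. Apparent counts arise from rasterizing the shell, blurring with
#' a Gaussian PSF (the partial-volume mechanism that converts thickening
#' into count change) and scaling so the noise-free maximum equals
#' `max_counts`; Poisson noise is optional.
#'
#' Frames sample the cycle at bin midpoints: frame k covers cycle angle
#' `[k-1, k) * 360 / n_frames` and takes the model value at the interval
#' midpoint.
#'
#' @param edv_ml end-diastolic cavity volume in mL. Default 75 (normal-range
#'   resting value).
#' @param ef_true target ejection fraction as a fraction in (0, 1). Default
#'   0.69.
#' @param matrix_size pixels per row/col (default 64).
#' @param pixel_mm pixel size in mm (default 6.4).
#' @param n_slices number of short-axis slices (default 24).
#' @param slice_mm slice thickness in mm (default 6.4).
#' @param n_frames frames per cardiac cycle (default 16, minimum 8).
#' @param wall_mm_ed end-diastolic wall thickness in mm (default 10).
#' @param thickening_mm systolic increase in wall thickness in mm (default 5).
#' @param delay_deg per-segment contraction delay, 17 values in `[0, 360)`.
#' @param uptake per-segment relative tracer uptake, 17 values in `(0, 1]`.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum in mm
#'   (default 12, typical reconstructed SPECT resolution).
#' @param max_counts target maximum myocardial counts per pixel in the
#'   noise-free study (default 123).
#' @param axis_ratio long-axis to short-axis semi-axis ratio of the cavity
#'   (default 2).
#' @param poisson apply Poisson count noise (default `TRUE`).
#' @param seed random seed used when Poisson noise is applied.
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(edv_ml = 75, ef_true = 0.69, poisson = FALSE)
#' truth <- true_function(spec)
#' truth$ef
#' @export
phantom_spec <- function(edv_ml = 75, ef_true = 0.69,
                         matrix_size = 64, pixel_mm = 6.4,
                         n_slices = 24, slice_mm = 6.4, n_frames = 16,
                         wall_mm_ed = 10, thickening_mm = 5,
                         delay_deg = rep(0, 17), uptake = rep(1, 17),
                         psf_fwhm_mm = 12, max_counts = 123,
                         axis_ratio = 2, poisson = TRUE, seed = 1L) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(edv_ml) || edv_ml <= 0) stop("validation error: edv_ml must be > 0")
  if (!num1(ef_true) || ef_true <= 0 || ef_true >= 1)
    stop("validation error: ef_true must be in (0, 1)")
  if (!num1(n_frames) || n_frames < 8)
    stop("validation error: n_frames must be >= 8")
  if (length(delay_deg) != 17 || any(!is.finite(delay_deg)) ||
      any(delay_deg < 0 | delay_deg >= 360))
    stop("validation error: delay_deg must be 17 values in [0, 360)")
  if (length(uptake) != 17 || any(!is.finite(uptake)) ||
      any(uptake <= 0 | uptake > 1))
    stop("validation error: uptake must be 17 values in (0, 1]")
  for (v in c(matrix_size, pixel_mm, n_slices, slice_mm, wall_mm_ed,
              psf_fwhm_mm, max_counts, axis_ratio))
    if (!num1(v) || v <= 0) stop("validation error: non-finite spec values")
  if (!num1(thickening_mm) || thickening_mm < 0)
    stop("validation error: thickening_mm must be >= 0")
  structure(list(
    edv_ml = edv_ml, ef_true = ef_true, matrix_size = as.integer(matrix_size),
    pixel_mm = pixel_mm, n_slices = as.integer(n_slices), slice_mm = slice_mm,
    n_frames = as.integer(n_frames), wall_mm_ed = wall_mm_ed,
    thickening_mm = thickening_mm, delay_deg = as.numeric(delay_deg),
    uptake = as.numeric(uptake), psf_fwhm_mm = psf_fwhm_mm,
    max_counts = max_counts, axis_ratio = axis_ratio,
    poisson = isTRUE(poisson), seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "LV phantom: EDV %.1f mL, EF %.2f, %dx%d x %d slices x %d frames\n",
    x$edv_ml, x$ef_true, x$matrix_size, x$matrix_size, x$n_slices,
    x$n_frames))
  cat(sprintf("  wall %.1f+%.1f mm, PSF %.1f mm FWHM, max counts %.0f, %s\n",
              x$wall_mm_ed, x$thickening_mm, x$psf_fwhm_mm, x$max_counts,
              if (x$poisson) "Poisson noise" else "noise-free"))
  if (any(x$delay_deg != 0))
    cat("  delayed segments:",
        paste(which(x$delay_deg != 0), collapse = ", "), "\n")
  invisible(x)
}

# Half-ellipsoid geometry: cavity semi-axes (a, a, c = axis_ratio * a); base
# plane fixed, apex toward slice 1. Raises a geometry error when the shell
# (plus its maximum wall thickness) does not fit in the field of view.
lv_geometry <- function(spec) {
  v_mm3 <- spec$edv_ml * 1000
  a_ed <- (3 * v_mm3 / (2 * pi * spec$axis_ratio))^(1 / 3)
  c_ed <- spec$axis_ratio * a_ed
  w_max <- spec$wall_mm_ed + spec$thickening_mm
  z_base <- spec$slice_mm + c_ed + w_max
  if (z_base > (spec$n_slices - 0.5) * spec$slice_mm)
    stop("geometry error: LV shell exceeds the slice coverage")
  if (a_ed + w_max > (spec$matrix_size / 2 - 2) * spec$pixel_mm)
    stop("geometry error: LV shell exceeds the in-plane field of view")
  list(a_ed = a_ed, c_ed = c_ed, z_base = z_base, w_max = w_max)
}

# Contraction model evaluated at frame midpoints: per-segment normalized
# shortening waveform s in [0,1], frame cavity volumes and radial scales.
lv_contraction <- function(spec) {
  n <- spec$n_frames
  theta <- 360 * (seq_len(n) - 0.5) / n
  s_seg <- (1 - cos(outer(spec$delay_deg, theta,
                          function(d, t) (t - d) * pi / 180))) / 2
  sbar <- colMeans(s_seg)
  # Radial contraction only (long axis fixed): cavity volume ~ a^2. Each
  # segment's endocardial radius follows its own delayed waveform, so
  # regional inward motion and regional thickening share one local clock;
  # the sector-mean of scale^2 makes the global volume interpolate
  # EDV -> ESV exactly.
  scale_seg <- sqrt(1 - spec$ef_true * s_seg)      # [17, n_frames]
  scale <- sqrt(1 - spec$ef_true * sbar)
  list(theta_deg = theta, s_seg = s_seg, sbar = sbar, scale = scale,
       scale_seg = scale_seg)
}

# Voxel scaffolding shared by the frame loop, restricted to a bounding box
# around the shell (plus 4 sigma of resolution margin): squared in-plane
# radius, angle, base-plane distance and slice index, as vectors over the
# in-box voxels, plus their linear indices into the full volume. sigma
# combines the PSF with the voxel footprint (box approximated by a Gaussian
# of matching variance), so the rasterized field is band-limited at the
# sampling grid.
phantom_grid <- function(spec) {
  M <- spec$matrix_size; S <- spec$n_slices
  cx <- (M + 1) / 2
  g <- lv_geometry(spec)
  sigma <- sqrt((spec$psf_fwhm_mm / 2.3548)^2 + spec$pixel_mm^2 / 12)
  margin <- 4 * sigma
  row <- matrix(seq_len(M), M, M)
  col <- t(row)
  r2 <- ((row - cx)^2 + (col - cx)^2) * spec$pixel_mm^2
  z <- (seq_len(S) - 0.5) * spec$slice_mm
  dz_s <- g$z_base - z
  r_max <- g$a_ed + g$w_max + margin
  z_keep <- which(dz_s > -margin & dz_s < g$c_ed + g$w_max + margin)
  xy_keep <- which(r2 <= r_max^2)
  idx <- as.vector(outer(xy_keep, (z_keep - 1) * M * M, "+"))
  nxy <- length(xy_keep)
  ang <- (atan2(col - cx, cx - row) * 180 / pi) %% 360  # 0 deg = anterior
  dz <- rep(dz_s[z_keep], each = nxy)
  list(geom = g, dims = c(M, M, S), idx = idx,
       r2 = rep(r2[xy_keep], length(z_keep)),
       ang = rep(ang[xy_keep], length(z_keep)),
       slice = rep(z_keep, each = nxy),
       dz = dz,
       base_soft = stats::pnorm(dz / sigma),
       sigma = sigma)
}

# Signed distance (mm, first order, positive outside) from each voxel centre
# to the half-ellipsoid surface with semi-axes (a, a, c_ax).
surface_distance <- function(grid, a, c_ax) {
  u <- sqrt(grid$r2 / a^2 + (grid$dz / c_ax)^2)
  g <- sqrt(grid$r2 / a^4 + (grid$dz / c_ax^2)^2) / pmax(u, 1e-9)
  (u - 1) / pmax(g, 1e-12)
}

# PSF-blurred myocardial shell evaluated analytically: a uniform slab
# between the endo- and epicardial surfaces convolved with a Gaussian of
# width sigma along the local surface normal (exact for a flat interface;
# curvature error is O(sigma^2 / radius)). The open base is feathered with
# the same resolution.
shell_mask <- function(grid, a, c_ax, w, sigma = grid$sigma) {
  d_endo <- surface_distance(grid, a, c_ax)
  d_epi <- if (length(w) == 1) surface_distance(grid, a + w, c_ax + w)
  else {
    aw <- a + w; cw <- c_ax + w
    u <- sqrt(grid$r2 / aw^2 + (grid$dz / cw)^2)
    g <- sqrt(grid$r2 / aw^4 + (grid$dz / cw^2)^2) / pmax(u, 1e-9)
    (u - 1) / pmax(g, 1e-12)
  }
  (stats::pnorm(d_endo / sigma) - stats::pnorm(d_epi / sigma)) *
    grid$base_soft
}

#' Generate a synthetic gated SPECT study
#'
#' Rasterizes the phantom's myocardial shell frame by frame, applies the
#' Gaussian PSF, scales the noise-free maximum to `spec$max_counts` and
#' optionally Poisson-samples the result. Ground-truth AHA segments are
#' painted with the same slice-banding rule that [aggregate_17seg()] applies
#' during analysis (determined from a noise-free end-diastolic pre-pass), so
#' injected per-segment delays land in the segments the analysis recovers.
#'
#' @param spec a [phantom_spec()].
#' @param seed random seed for the Poisson stage; defaults to `spec$seed`.
#' @return a [gated_study()] with provenance in `$meta`.
#' @examples
#' spec <- phantom_spec(matrix_size = 32, n_slices = 12, edv_ml = 60,
#'                      ef_true = 0.65, poisson = FALSE)
#' study <- generate_study(spec)
#' study
#' @export
generate_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  con <- lv_contraction(spec)
  M <- spec$matrix_size; S <- spec$n_slices; N <- spec$n_frames

  # Cycle-mean pre-pass: uniform-thickness shell at the mean contraction
  # state -> used slices -> segment painting. Matches the frame-summed
  # image the sampling stage uses to pick its slices, so painted and
  # recovered slice bands coincide.
  msc <- mean(con$scale)
  ed_val <- shell_mask(grid, grid$geom$a_ed * msc, grid$geom$c_ed,
                       spec$wall_mm_ed + spec$thickening_mm / 2)
  slice_tot <- rep(0, S)
  st <- rowsum(ed_val, grid$slice)
  slice_tot[as.integer(rownames(st))] <- st
  used <- which(slice_tot >= 0.10 * max(slice_tot))
  bands_used <- slice_bands(length(used))
  band_vox <- bands_used[pmin(pmax(findInterval(grid$slice, used), 1),
                              length(used))]
  seg_vox <- aha_sector(grid$ang, band_vox)
  upt_vox <- spec$uptake[seg_vox]

  nvox <- M * M * S
  frames <- matrix(0, nvox, N)
  for (k in seq_len(N)) {
    w_vox <- (spec$wall_mm_ed +
                spec$thickening_mm * con$s_seg[, k])[seg_vox]
    a_vox <- grid$geom$a_ed * con$scale_seg[seg_vox, k]
    fr <- numeric(nvox)
    fr[grid$idx] <- upt_vox * shell_mask(grid, a_vox, grid$geom$c_ed, w_vox)
    frames[, k] <- fr
  }
  frames <- frames * (spec$max_counts / max(frames))
  if (spec$poisson) {
    set.seed(seed)
    frames <- matrix(stats::rpois(length(frames), pmax(frames, 0)),
                     nvox, N)
  } else {
    frames <- round(frames)
  }
  counts <- aperm(array(frames, c(M, M, S, N)), c(4, 3, 1, 2))
  gated_study(counts, pixel_mm = spec$pixel_mm, slice_mm = spec$slice_mm,
              meta = list(generator = "spectsync phantom", seed = seed,
                          edv_ml = spec$edv_ml, ef_true = spec$ef_true,
                          poisson = spec$poisson))
}

#' Analytic ground truth of a phantom
#'
#' Pre-rasterization, pre-blur cavity volumes, ejection fraction, per-segment
#' true time to end-systole (cycle angle of maximal wall thickness,
#' `180 + delay` degrees) and the dispersion of the injected delays.
#' Independent of the random seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `edv_ml`, `esv_ml`, `ef`, `tes_true_deg` (17 values) and
#'   `psd_true_deg` (wrap-safe population SD of the injected delays).
#' @export
true_function <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  esv <- spec$edv_ml * (1 - spec$ef_true)
  delays <- spec$delay_deg
  list(edv_ml = spec$edv_ml, esv_ml = esv, ef = spec$ef_true,
       tes_true_deg = (180 + delays) %% 360,
       psd_true_deg = circular_pop_sd(delays))
}

# Analytic end-diastolic myocardial shell volume (mL); open base.
myocardial_volume_ml <- function(spec) {
  g <- lv_geometry(spec)
  w <- spec$wall_mm_ed
  (2 / 3) * pi * ((g$a_ed + w)^2 * (g$c_ed + w) - g$a_ed^2 * g$c_ed) / 1000
}

#' Specify a simulated normal cohort
#'
#' Subject-level EDV and EF are drawn from per-sex normal distributions
#' (truncated at physiologic bounds); per-segment contraction delays are
#' jittered with SD `delay_jitter_deg`. With `counts_scaling = "volume"`,
#' each subject's maximum myocardial count is inversely proportional to
#' myocardial volume (normalized to 123 counts/pixel at the cohort-mean
#' volume): for a fixed injected dose, larger hearts accumulate fewer counts
#' per pixel. This count-statistics channel — not any intrinsic sex term in
#' contraction timing — is what makes male (larger-hearted) phases noisier.
#' Systolic thickening is coupled to EF (`thickening_mm = wall_mm_ed * ef`),
#' reflecting that EF and systolic wall thickening track each other.
#'
#' @param n_male,n_female group sizes (defaults 36 and 33).
#' @param edv_mean_ml,edv_sd_ml length-2 vectors `(male, female)` of EDV
#'   distribution parameters in mL; defaults 84.4/64.1 and 15.7/12.1.
#' @param ef_mean,ef_sd length-2 vectors `(male, female)` of EF fractions;
#'   defaults 0.665/0.720 and 0.061/0.057.
#' @param counts_scaling `"volume"` (default) or `"none"`.
#' @param delay_jitter_deg SD of per-segment contraction delays in degrees
#'   (default 8, the normal-range segmental timing spread).
#' @param poisson apply Poisson noise in generated studies (default `TRUE`).
#' @param phantom named list of [phantom_spec()] overrides applied to every
#'   subject (e.g. `matrix_size` for small test phantoms).
#' @param seed cohort-level seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 36, n_female = 33,
                        edv_mean_ml = c(84.4, 64.1),
                        edv_sd_ml = c(15.7, 12.1),
                        ef_mean = c(0.665, 0.720),
                        ef_sd = c(0.061, 0.057),
                        counts_scaling = c("volume", "none"),
                        delay_jitter_deg = 8, poisson = TRUE,
                        phantom = list(), seed = 1L) {
  if (n_male < 0 || n_female < 0)
    stop("validation error: group sizes must be >= 0")
  if (any(edv_sd_ml < 0) || any(ef_sd < 0) || delay_jitter_deg < 0)
    stop("validation error: SDs must be >= 0")
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 edv_mean_ml = edv_mean_ml, edv_sd_ml = edv_sd_ml,
                 ef_mean = ef_mean, ef_sd = ef_sd,
                 counts_scaling = match.arg(counts_scaling),
                 delay_jitter_deg = delay_jitter_deg,
                 poisson = isTRUE(poisson), phantom = phantom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Draw a cohort of phantom specifications
#'
#' @param cohort a [cohort_spec()].
#' @return list of subjects; each element has `id`, `sex` (`"M"`/`"F"`),
#'   `spec` (a [phantom_spec()]) and `truth` ([true_function()] output).
#'   Deterministic under the cohort seed.
#' @export
make_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  n <- cohort$n_male + cohort$n_female
  sexes <- rep(c("M", "F"), c(cohort$n_male, cohort$n_female))
  out <- vector("list", n)
  if (n == 0) return(out)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  wall <- if (!is.null(cohort$phantom$wall_mm_ed))
    cohort$phantom$wall_mm_ed else 10
  for (i in seq_len(n)) {
    sx <- if (sexes[i] == "M") 1 else 2
    edv <- rnorm_trunc(1, cohort$edv_mean_ml[sx], cohort$edv_sd_ml[sx],
                       lo = max(30, cohort$edv_mean_ml[sx] -
                                  3 * cohort$edv_sd_ml[sx]),
                       hi = cohort$edv_mean_ml[sx] + 3 * cohort$edv_sd_ml[sx])
    ef <- rnorm_trunc(1, cohort$ef_mean[sx], cohort$ef_sd[sx], 0.40, 0.85)
    delays <- stats::rnorm(17, 0, cohort$delay_jitter_deg) %% 360
    args <- c(list(edv_ml = edv, ef_true = ef, delay_deg = delays,
                   thickening_mm = wall * ef, poisson = cohort$poisson,
                   seed = seeds[i]),
              cohort$phantom)
    args <- args[!duplicated(names(args))]
    spec <- do.call(phantom_spec, args)
    out[[i]] <- list(id = sprintf("S%03d", i), sex = sexes[i], spec = spec)
  }
  if (cohort$counts_scaling == "volume") {
    vols <- vapply(out, function(s) myocardial_volume_ml(s$spec), numeric(1))
    for (i in seq_len(n)) {
      mc <- 123 * mean(vols) / vols[i]
      out[[i]]$spec$max_counts <- min(1000, max(10, mc))
    }
  }
  for (i in seq_len(n)) out[[i]]$truth <- true_function(out[[i]]$spec)
  out
}
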