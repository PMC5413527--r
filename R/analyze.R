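#' Analysis configuration
#'
#' Bundles the tunable parameters of the per-study pipeline. Defaults are
#' the package's documented conventions; every parameter is a plain value so
#' a config can be serialized alongside results.
#'
#' @param n_angles angular samples per slice.
#' @param radial_window_mm radial search annulus half-width (mm).
#' @param base_cut `"auto"`, `"manual"` or `"none"`.
#' @param manual_slices slices removed when `base_cut = "manual"`.
#' @param base_cut_frac auto base-cut amplitude fraction.
#' @param smooth_kernel_deg phase-map smoothing FWHM in degrees (0 = off).
#' @param smooth_kernel_slices axial smoothing sigma in slices.
#' @param bin_deg phase histogram bin width.
#' @param amplitude_floor fraction of `a0` below which a sample's phase is
#'   undefined.
#' @param bandwidth_mode `"shortest_arc"` or `"trim"`.
#' @param threshold_frac endocardial threshold for [estimate_volumes()].
#' @param volumes `"estimated"` (threshold estimator) or `"truth"` (phantom
#'   ground truth, for simulation studies where estimator error must not
#'   confound volume analyses).
#' @param lateral,septal AHA ids for DTES-LS.
#' @return a list of class `dyssync_config`.
#' @export
dyssync_config <- function(n_angles = 36, radial_window_mm = 20,
                           base_cut = c("auto", "manual", "none"),
                           manual_slices = NULL, base_cut_frac = 0.5,
                           smooth_kernel_deg = 0, smooth_kernel_slices = 0,
                           bin_deg = 1, amplitude_floor = 0.02,
                           bandwidth_mode = c("shortest_arc", "trim"),
                           threshold_frac = 0.45,
                           volumes = c("estimated", "truth"),
                           lateral = aha_lateral_default(),
                           septal = aha_septal_default()) {
  structure(list(n_angles = n_angles, radial_window_mm = radial_window_mm,
                 base_cut = match.arg(base_cut),
                 manual_slices = manual_slices,
                 base_cut_frac = base_cut_frac,
                 smooth_kernel_deg = smooth_kernel_deg,
                 smooth_kernel_slices = smooth_kernel_slices,
                 bin_deg = bin_deg, amplitude_floor = amplitude_floor,
                 bandwidth_mode = match.arg(bandwidth_mode),
                 threshold_frac = threshold_frac,
                 volumes = match.arg(volumes),
                 lateral = lateral, septal = septal),
            class = "dyssync_config")
}

#' Run the full dyssynchrony analysis on one gated study
#'
#' Orchestrates sampling, base cut, per-sample order-1 harmonic fitting,
#' optional phase-map smoothing, the histogram indices (PSD, 95% bandwidth,
#' entropy), the 17-segment order-2 fits with the TES dispersion family,
#' and the threshold-based volume/EF estimate.
#'
#' @param study a [gated_study()].
#' @param config a [dyssync_config()].
#' @return object of class `dyssync`; see `print`, `summary` and `plot`
#'   methods. Key components: `$metrics` (psd_deg, bandwidth_deg, entropy,
#'   n_samples), `$tes` ([tes_metrics()]), `$volumes`
#'   ([estimate_volumes()]), `$phases` (per-sample table), `$histogram`.
#' @examples
#' spec <- phantom_spec(matrix_size = 32, n_slices = 12, edv_ml = 60,
#'                      ef_true = 0.65, poisson = FALSE)
#' fit <- analyze_study(generate_study(spec))
#' fit
#' @export
analyze_study <- function(study, config = dyssync_config()) {
  stopifnot(inherits(study, "gated_study"))
  grid <- sampling_grid(n_angles = config$n_angles,
                        radial_window_mm = config$radial_window_mm)
  rays <- ray_profiles(study, grid)
  samples <- sample_profiles(study, grid)
  samples <- switch(config$base_cut,
    auto = base_cut(samples, "auto", frac = config$base_cut_frac),
    manual = base_cut(samples, "manual",
                      manual_slices = config$manual_slices),
    none = samples)

  fits <- fit_harmonics_mat(samples$tac, order = 1,
                            amplitude_floor = config$amplitude_floor)
  phases <- ifelse(fits$phase_defined, fits$phi1_deg, NA_real_)
  if (config$smooth_kernel_deg > 0 || config$smooth_kernel_slices > 0) {
    pm <- matrix(NA_real_, length(samples$slices), samples$n_angles)
    idx <- cbind(match(samples$slice, samples$slices),
                 match(samples$angle_deg,
                       sort(unique(samples$angle_deg))))
    pm[idx] <- phases
    pm <- smooth_phases(pm, config$smooth_kernel_deg,
                        config$smooth_kernel_slices)
    phases <- pm[idx]
  }

  hist <- build_histogram(phases, bin_deg = config$bin_deg)
  metrics <- list(psd_deg = psd(phases),
                  bandwidth_deg = bandwidth95(phases,
                                              mode = config$bandwidth_mode),
                  entropy = phase_entropy(hist),
                  n_samples = sum(!is.na(phases)))

  segs <- aggregate_17seg(samples)
  tes <- rep(NA_real_, 17)
  for (g in which(segs$present)) {
    f2 <- fit_harmonics(segs$tac[g, ], order = 2,
                        amplitude_floor = config$amplitude_floor)
    t <- tes_deg(f2)
    tes[g] <- if (is.na(t)) NA_real_ else as.numeric(t)
  }
  tes_m <- tryCatch(
    tes_metrics(tes, lateral = config$lateral, septal = config$septal,
                strict = FALSE),
    error = function(e) NULL)

  vols <- estimate_volumes(study, threshold_frac = config$threshold_frac,
                           grid = grid, rays = rays)

  structure(list(
    metrics = metrics, histogram = hist,
    phases = data.frame(slice = samples$slice,
                        angle_deg = samples$angle_deg,
                        phase_deg = phases, a0 = fits$a0, a1 = fits$a1),
    tes = tes_m, tes_by_segment = tes, volumes = vols,
    segments = segs, config = config),
    class = "dyssync")
}

#' @export
print.dyssync <- function(x, ...) {
  m <- x$metrics
  cat("Gated SPECT dyssynchrony analysis\n")
  cat(sprintf("  phase samples: %d\n", m$n_samples))
  cat(sprintf("  PSD %.1f deg | 95%% bandwidth %.0f deg | entropy %.1f%%\n",
              m$psd_deg, m$bandwidth_deg, 100 * m$entropy))
  if (!is.null(x$tes))
    cat(sprintf("  MDTES %.2f%% | SDTES %.2f%% | DTES-LS %+.2f%%\n",
                x$tes$mdtes_pct, x$tes$sdtes_pct, x$tes$dtes_ls_pct))
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL, EF %.1f%%\n",
              x$volumes$edv_ml, x$volumes$esv_ml, x$volumes$ef_pct))
  invisible(x)
}

#' @export
summary.dyssync <- function(object, ...) {
  print(object)
  cat("\nPer-segment TES (deg):\n")
  tes <- object$tes_by_segment
  for (g in seq_len(17))
    cat(sprintf("  %2d %-22s %s\n", g, aha_segment_names()[g],
                if (is.na(tes[g])) "absent" else sprintf("%6.1f", tes[g])))
  invisible(object)
}

#' @export
plot.dyssync <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  h <- x$histogram
  mids <- h$start_deg + (seq_len(h$n_bins) - 0.5) * h$bin_deg
  barplot(h$freq, names.arg = NULL, space = 0, border = NA,
          main = "Phase histogram", xlab = "phase (deg)", ylab = "frequency")
  axis(1, at = seq(0, h$n_bins, length.out = 5),
       labels = seq(0, 360, length.out = 5))
  plot(x$volumes$per_frame_ml, type = "b", xlab = "frame",
       ylab = "cavity volume (mL)", main = "Volume curve")
  abline(v = c(x$volumes$ed_frame, x$volumes$es_frame), lty = 3)
  tes <- x$tes_by_segment
  plot(seq_len(17), tes, xlab = "AHA segment", ylab = "TES (deg)",
       main = "Segmental TES", pch = 19)
  matplot(t(x$segments$tac), type = "l", lty = 1,
          xlab = "frame", ylab = "counts", main = "Segment TACs")
  invisible(x)
}
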