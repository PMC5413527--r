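#' Phase histogram
#'
#' Bins phase values (degrees) into half-open bins `[edge, edge + bin_deg)`
#' covering one full cycle; a value exactly on an edge belongs to the bin
#' whose lower edge it is. Frequencies are normalized to sum to 1.
#'
#' @param phases phase values in degrees; `NA` (excluded samples) dropped.
#' @param bin_deg bin width in degrees; must divide 360 (default 1).
#' @param start_deg lower edge of the first bin (default 0).
#' @return object of class `phase_histogram` with `freq`, `n_bins`,
#'   `bin_deg`, `start_deg`, `n_samples`.
#' @examples
#' h <- build_histogram(c(10, 10.4, 200))
#' phase_entropy(h)
#' @export
build_histogram <- function(phases, bin_deg = 1, start_deg = 0) {
  phases <- phases[!is.na(phases)]
  if (!length(phases)) stop("validation error: no phase samples")
  n_bins <- round(360 / bin_deg)
  if (abs(n_bins * bin_deg - 360) > 1e-9)
    stop("validation error: bin_deg must divide 360")
  idx <- floor(((phases - start_deg) %% 360) / bin_deg) + 1
  idx[idx > n_bins] <- n_bins  # guard against FP roundup at the seam
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_deg = bin_deg, start_deg = start_deg,
                 freq = counts / length(phases), n_bins = as.integer(n_bins),
                 n_samples = length(phases)),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("Phase histogram: %d samples in %d bins of %g deg\n",
              x$n_samples, x$n_bins, x$bin_deg))
  invisible(x)
}

#' Normalized phase entropy
#'
#' Shannon entropy of the phase histogram normalized by the number of bins:
#' \deqn{E = -\sum_i f_i \log f_i / \log n,}
#' with the `0 log 0 = 0` convention. E ranges from 0 (all phases in one bin,
#' complete order) to 1 (uniform histogram, complete disorder); tables
#' conventionally report it in percent.
#'
#' @param hist a [build_histogram()] result.
#' @return entropy as a fraction in `[0, 1]`.
#' @export
phase_entropy <- function(hist) {
  stopifnot(inherits(hist, "phase_histogram"))
  if (hist$n_bins < 2) stop("validation error: need at least 2 bins")
  f <- hist$freq[hist$freq > 0]
  -sum(f * log(f)) / log(hist$n_bins) + 0  # +0 avoids signed zero
}

# Circular mean (degrees) of phase values.
circular_mean_deg <- function(x) {
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
}

# Rotate phases so their circular mean sits at 180 degrees; wrap-safe.
recenter_deg <- function(x) (x - circular_mean_deg(x) + 180) %% 360

# Population SD after recentring at the circular mean.
circular_pop_sd <- function(x) {
  y <- recenter_deg(x)
  sqrt(mean((y - mean(y))^2))
}

#' Phase standard deviation (PSD)
#'
#' Standard deviation of the per-sample phase distribution in degrees. The
#' distribution is first rotated so its circular mean sits at 180 degrees
#' (wrap-safe: the pair \{350, 10\} has PSD 10, not 170), then the population
#' standard deviation of the recentred values is returned. Set
#' `recenter = FALSE` for the plain linear SD.
#'
#' @param phases phase values in degrees; `NA` dropped.
#' @param recenter rotate to the circular mean before taking the SD
#'   (default `TRUE`).
#' @return PSD in degrees.
#' @examples
#' psd(c(350, 10))   # 10
#' @export
psd <- function(phases, recenter = TRUE) {
  phases <- phases[!is.na(phases)]
  if (length(phases) < 2) stop("validation error: need >= 2 phase samples")
  if (!recenter) return(sqrt(mean((phases - mean(phases))^2)))
  circular_pop_sd(phases)
}

#' 95% phase bandwidth
#'
#' Width in degrees of the shortest circular arc containing at least 95% of
#' the phase samples, found by sweeping all sorted sample positions. With
#' `mode = "trim"` the alternative convention — symmetric 2.5% trimming about
#' the circular mean — is used instead. Fewer than 20 samples make a 95%
#' width ill-defined; the full circular range is then returned with
#' attribute `insufficient = TRUE`.
#'
#' @param phases phase values in degrees; `NA` dropped.
#' @param coverage fraction of samples the arc must contain (default 0.95).
#' @param mode `"shortest_arc"` (default) or `"trim"`.
#' @return bandwidth in degrees.
#' @examples
#' bandwidth95(c(rep(180, 95), rep(0, 5)))  # 0: the 5% outliers fall outside
#' @export
bandwidth95 <- function(phases, coverage = 0.95,
                        mode = c("shortest_arc", "trim")) {
  mode <- match.arg(mode)
  phases <- phases[!is.na(phases)] %% 360
  n <- length(phases)
  if (n < 1) stop("validation error: no phase samples")
  insufficient <- n < 20
  m <- if (insufficient) n else ceiling(coverage * n)
  bw <- if (mode == "shortest_arc" || insufficient) {
    x <- sort(phases)
    ext <- c(x, x + 360)
    min(ext[seq_len(n) + m - 1] - ext[seq_len(n)])
  } else {
    y <- sort(recenter_deg(phases))
    k <- n - m
    lo <- k %/% 2; hi <- k - lo
    max(y[(1 + lo):(n - hi)]) - min(y[(1 + lo):(n - hi)])
  }
  if (insufficient) attr(bw, "insufficient") <- TRUE
  bw
}

#' Segmental time-to-end-systole metrics
#'
#' From the 17 per-segment TES values (degrees of the cardiac cycle) computes
#' the TES dispersion family, each expressed as percent of the cycle
#' (division by 360): MDTES (maximum segmental difference), SDTES
#' (population SD) and DTES-LS (mean lateral minus mean septal TES, signed).
#' Values are first rotated so their circular mean sits at 180 degrees, so a
#' 359/1 degree pair does not read as a 358-degree spread.
#'
#' @param tes_deg 17 per-segment TES values in degrees (AHA order).
#' @param lateral,septal AHA segment ids averaged for DTES-LS; defaults
#'   anterolateral + inferolateral `{5, 6, 11, 12}` and anteroseptal +
#'   inferoseptal `{2, 3, 8, 9}`.
#' @param strict require all 17 values defined (default `TRUE`); otherwise
#'   `NA` segments are dropped from MDTES/SDTES but must not occur in the
#'   lateral or septal sets.
#' @return object of class `tes_metrics`: `tes_deg`, `mdtes_pct`,
#'   `sdtes_pct`, `dtes_ls_pct`.
#' @export
tes_metrics <- function(tes_deg, lateral = aha_lateral_default(),
                        septal = aha_septal_default(), strict = TRUE) {
  if (length(tes_deg) != 17)
    stop("validation error: need 17 segmental TES values")
  if (strict && any(is.na(tes_deg)))
    stop("validation error: missing segment in strict mode")
  if (any(is.na(tes_deg[c(lateral, septal)])))
    stop("validation error: lateral/septal segment undefined")
  ok <- !is.na(tes_deg)
  sh <- rep(NA_real_, 17)
  sh[ok] <- (tes_deg[ok] - circular_mean_deg(tes_deg[ok]) + 180) %% 360
  structure(list(
    tes_deg = tes_deg,
    mdtes_pct = (max(sh[ok]) - min(sh[ok])) / 360 * 100,
    sdtes_pct = sqrt(mean((sh[ok] - mean(sh[ok]))^2)) / 360 * 100,
    dtes_ls_pct = (mean(sh[lateral]) - mean(sh[septal])) / 360 * 100),
    class = "tes_metrics")
}

#' @export
print.tes_metrics <- function(x, ...) {
  cat(sprintf("TES metrics: MDTES %.2f%%, SDTES %.2f%%, DTES-LS %+.2f%%\n",
              x$mdtes_pct, x$sdtes_pct, x$dtes_ls_pct))
  invisible(x)
}

#' Normal limits (mean +/- 2 SD)
#'
#' Normal-database limits as conventionally quoted: lower = mean - 2 SD,
#' upper = mean + 2 SD, using the sample standard deviation (n - 1),
#' unrounded.
#'
#' @param values numeric vector, at least 2 values.
#' @return named list `mean`, `sd`, `lower`, `upper`.
#' @examples
#' normal_limits(c(0, 4))
#' @export
normal_limits <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("validation error: need >= 2 values")
  m <- mean(values); s <- stats::sd(values)
  list(mean = m, sd = s, lower = m - 2 * s, upper = m + 2 * s)
}
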