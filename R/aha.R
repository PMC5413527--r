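#' AHA 17-segment model helpers
#'
#' The package maps short-axis samples onto the standard AHA 17-segment model:
#' basal segments 1-6, mid-cavity 7-12, apical 13-16, apical cap 17. Angle 0
#' degrees is the anterior wall, increasing counter-clockwise as viewed from
#' the apex (anterior -> anteroseptal -> inferoseptal -> inferior ->
#' inferolateral -> anterolateral). Basal/mid rings use 60-degree sectors
#' centred on those walls; the apical ring uses four 90-degree sectors
#' (anterior, septal, inferior, lateral).
#'
#' @section Slice banding:
#' `slice_bands()` partitions `n` short-axis slices ordered apex-to-base into
#' the apical cap (the most apical ~15% of slices, at least one), then
#' apical / mid / basal thirds of the remainder. The same rule is used when
#' the phantom paints its ground-truth segments and when
#' [aggregate_17seg()] assigns samples, so simulated and recovered segment
#' memberships align.
#'
#' @param n number of slices, ordered apex first.
#' @return `slice_bands()`: character vector of length `n` with values
#'   `"cap"`, `"apical"`, `"mid"`, `"basal"`.
#' @examples
#' slice_bands(11)
#' aha_sector(300, "basal")   # anterolateral = segment 6
#' @export
slice_bands <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 4)
  n <- as.integer(n)
  n_cap <- max(1L, as.integer(round(0.15 * n)))
  rest <- n - n_cap
  sizes <- diff(round(seq(0, rest, length.out = 4)))
  c(rep("cap", n_cap),
    rep("apical", sizes[1]), rep("mid", sizes[2]), rep("basal", sizes[3]))
}

#' @rdname slice_bands
#' @param angle_deg sample angle in degrees (0 = anterior, counter-clockwise
#'   from apex).
#' @param band slice band: `"basal"`, `"mid"`, `"apical"` or `"cap"`.
#' @return `aha_sector()`: integer AHA segment id 1-17.
#' @export
aha_sector <- function(angle_deg, band) {
  a <- angle_deg %% 360
  if (length(band) == 1) band <- rep(band, length(a))
  seg <- integer(length(a))
  bm <- band %in% c("basal", "mid")
  if (any(bm)) {
    k <- floor(((a[bm] + 30) %% 360) / 60) + 1L  # 1..6, anterior at 0
    seg[bm] <- ifelse(band[bm] == "mid", k + 6L, k)
  }
  ap <- band == "apical"
  if (any(ap)) seg[ap] <- 13L + floor(((a[ap] + 45) %% 360) / 90)
  seg[band == "cap"] <- 17L
  seg
}

#' @rdname slice_bands
#' @export
aha_segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior",
    "apical lateral", "apex")
}

# Default lateral/septal memberships for DTES-LS: anterolateral +
# inferolateral vs anteroseptal + inferoseptal, basal and mid levels.
aha_lateral_default <- function() c(5L, 6L, 11L, 12L)
aha_septal_default <- function() c(2L, 3L, 8L, 9L)
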