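#' Gated short-axis SPECT study container
#'
#' A `gated_study` holds an ECG-gated short-axis count volume as a 4-D array
#' indexed `[frame, slice, row, col]`, together with its spatial and temporal
#' calibration. Slice 1 is the apex; frames cover one cardiac cycle.
#'
#' @param counts 4-D array of nonnegative finite counts,
#'   `[frame, slice, row, col]`.
#' @param pixel_mm in-plane pixel size in mm (> 0).
#' @param slice_mm slice thickness in mm (> 0).
#' @param frame_ms optional frame duration in ms.
#' @param meta free-form provenance list.
#' @return an object of class `gated_study`.
#' @examples
#' s <- gated_study(array(1, c(8, 2, 4, 4)), pixel_mm = 6.4, slice_mm = 6.4)
#' s
#' @export
gated_study <- function(counts, pixel_mm, slice_mm, frame_ms = NULL,
                        meta = list()) {
  if (!is.array(counts) || length(dim(counts)) != 4)
    stop("`counts` must be a 4-D array [frame, slice, row, col]")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be nonnegative and finite")
  if (!is.numeric(pixel_mm) || length(pixel_mm) != 1 || pixel_mm <= 0)
    stop("`pixel_mm` must be a positive scalar")
  if (!is.numeric(slice_mm) || length(slice_mm) != 1 || slice_mm <= 0)
    stop("`slice_mm` must be a positive scalar")
  structure(list(counts = counts, pixel_mm = pixel_mm, slice_mm = slice_mm,
                 n_frames = dim(counts)[1], frame_ms = frame_ms, meta = meta),
            class = "gated_study")
}

#' @export
print.gated_study <- function(x, ...) {
  d <- dim(x$counts)
  cat("Gated SPECT study:", d[1], "frames x", d[2], "slices x",
      d[3], "x", d[4], "pixels\n")
  cat(sprintf("  pixel %.2f mm, slice %.2f mm%s\n", x$pixel_mm, x$slice_mm,
              if (!is.null(x$frame_ms)) sprintf(", frame %.0f ms", x$frame_ms)
              else ""))
  cat(sprintf("  counts: max %.0f, total %.3g\n",
              max(x$counts), sum(x$counts)))
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read and write gated studies as 4-D NIfTI with a JSON sidecar
#'
#' `write_gated()` stores the count volume as a 4-D NIfTI file (axes
#' x = col, y = row, z = slice, t = frame) plus a JSON sidecar named
#' `<stem>.json` that carries the calibration (`pixel_mm`, `slice_mm`,
#' `n_frames`, optional `frame_ms`) and provenance. `read_gated()` reverses
#' the operation; a round trip reproduces the study exactly for integer
#' count volumes.
#'
#' @param study a [gated_study()].
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `write_gated()` returns `path` invisibly; `read_gated()` returns a
#'   `gated_study`.
#' @export
write_gated <- function(study, path) {
  stopifnot(inherits(study, "gated_study"))
  arr <- aperm(study$counts, c(4, 3, 2, 1))  # [col,row,slice,frame]
  if (max(arr) < .Machine$integer.max && all(arr == round(arr)))
    storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(study$pixel_mm, study$pixel_mm, study$slice_mm,
                           if (is.null(study$frame_ms)) 1
                           else study$frame_ms / 1000)
  RNifti::writeNifti(img, path)
  side <- list(pixel_mm = study$pixel_mm, slice_mm = study$slice_mm,
               n_frames = study$n_frames)
  if (!is.null(study$frame_ms)) side$frame_ms <- study$frame_ms
  if (length(study$meta)) side$meta <- study$meta
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gated
#' @export
read_gated <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    stop("format error: expected a 4-D NIfTI volume, got ", length(d), "-D")
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata error: missing JSON sidecar ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (key in c("pixel_mm", "slice_mm"))
    if (is.null(side[[key]]))
      stop("metadata error: sidecar is missing required key '", key, "'")
  counts <- aperm(array(as.vector(img), d), c(4, 3, 2, 1))
  if (any(counts < 0)) stop("format error: negative voxel values")
  gated_study(counts, pixel_mm = side$pixel_mm, slice_mm = side$slice_mm,
              frame_ms = side$frame_ms,
              meta = if (is.null(side$meta)) list() else side$meta)
}

#' Write and read tabular records as CSV at full precision
#'
#' Numeric columns are serialized with `%.17g` so that doubles round-trip
#' exactly through the text file. `rows` may be a data frame or a list of
#' records sharing one schema.
#'
#' @param rows data frame, or list of named lists/data frames with identical
#'   names.
#' @param path output CSV path.
#' @return `write_table()` returns `path` invisibly; `read_table_csv()`
#'   returns a data frame.
#' @export
write_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    if (!length(rows)) stop("validation error: no rows")
    schemas <- lapply(rows, names)
    if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]])))
      stop("validation error: rows have mixed schemas")
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  if (!is.data.frame(rows) || ncol(rows) == 0)
    stop("validation error: empty schema")
  fmt <- lapply(rows, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- do.call(cbind, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = ","), con)
  if (nrow(rows)) writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
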