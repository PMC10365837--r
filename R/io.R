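#' Read a multi-page grayscale TIFF stack
#'
#' Loads a movie written by [write_stack()] (or any grayscale multi-page
#' TIFF) as an array `[y, x, frame]`. Pixel size and frame interval are taken
#' from the JSON sidecar `<path>.json` when present; otherwise package
#' defaults (0.1 um/px, 0.2 s) are applied with a warning. RGB input is
#' rejected.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval Fallback metadata when no sidecar exists.
#' @return Numeric array with attributes `pixel_size` and `frame_interval`.
#' @export
read_stack <- function(path, pixel_size = 0.1, frame_interval = 0.2) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L)
    stopf("RGB TIFF input is not supported; supply grayscale stacks")
  scale <- 65535
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size <- meta$pixel_size %||% pixel_size
    frame_interval <- meta$frame_interval %||% frame_interval
    scale <- meta$scale %||% scale
  } else {
    warnf("no metadata sidecar for %s: using pixel_size = %g um/px, frame_interval = %g s",
          basename(path), pixel_size, frame_interval)
  }
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * scale
  if (isTRUE(all.equal(stack, round(stack), tolerance = 1e-6)))
    stack <- round(stack)
  attr(stack, "pixel_size") <- pixel_size
  attr(stack, "frame_interval") <- frame_interval
  stack
}

#' Write a movie stack as a multi-page TIFF with a metadata sidecar
#'
#' Pixel values are stored as 16-bit samples scaled by the recorded `scale`
#' (values must lie in `[0, scale]`); integer-valued photon-count stacks
#' round-trip exactly. Metadata (`pixel_size`, `frame_interval`, `scale`)
#' goes to `<path>.json`.
#'
#' @param movie Array `[y, x, frame]` (a single frame matrix is accepted).
#' @param path Output path.
#' @param scale Full-scale value of the 16-bit encoding.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path, scale = 65535) {
  if (length(dim(movie)) == 2L) movie <- array(movie, c(dim(movie), 1L))
  if (min(movie) < 0 || max(movie) > scale) {
    warnf("pixel values clipped to [0, %g] on write", scale)
    movie <- pmin(pmax(movie, 0), scale)
  }
  pages <- purrr::map(seq_len(dim(movie)[3]),
                      function(f) movie[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size = attr(movie, "pixel_size") %||% 0.1,
         frame_interval = attr(movie, "frame_interval") %||% 0.2,
         scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tabular results with deterministic formatting
#'
#' CSV output has a deterministic column order (as given), numeric columns
#' rendered with 9 significant digits, and re-reading then re-writing is
#' byte-identical. JSON output uses the same digit convention.
#'
#' @param records Data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "csv") {
    fmt <- records
    num <- vapply(fmt, is.numeric, logical(1)) &
      !vapply(fmt, is.integer, logical(1))
    fmt[num] <- lapply(fmt[num],
                       function(x) as.character(signif(x, digits = 9)))
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = 9, dataframe = "rows")
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A tibble.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv")
    readr::read_csv(path, show_col_types = FALSE)
  else
    tibble::as_tibble(jsonlite::fromJSON(path))
}
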