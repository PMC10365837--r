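#' Difference-of-Gaussians enhancement adapted to the vesicle size
#'
#' Band-pass filters an image with a DoG whose centre sigma matches the
#' expected punctum: `sigma = vesicle_diameter / (2 sqrt(2 ln 2))` (so the
#' diameter is the FWHM) and surround `1.6 sigma`. A constant image maps to
#' (numerically) zero and the response is linear in spot amplitude.
#'
#' @param image Numeric matrix `[y, x]`.
#' @param vesicle_diameter Expected punctum diameter, pixels (`>= 2`).
#' @return Filtered matrix, same shape.
#' @export
dog_enhance <- function(image, vesicle_diameter) {
  if (vesicle_diameter < 2) stopf("`vesicle_diameter` must be >= 2 px")
  sigma <- vesicle_diameter / (2 * sqrt(2 * log(2)))
  dog_filter(image, sigma, k = 1.6)
}

#' Threshold DoG-enhanced channels, count puncta and measure colocalization
#'
#' Each channel is masked at a constant threshold (kept constant across the
#' replicates of an experiment), connected components smaller than `min_size`
#' pixels are dropped, and particles are counted per channel. A particle of
#' the reference channel is colocalized when its component overlaps at least
#' one pixel of the other channel's mask; percent colocalization is
#' `100 * dual / n_reference`.
#'
#' @param filtered List of two DoG-enhanced matrices (see [dog_enhance()]).
#' @param thresholds Numeric length 2, one constant threshold per channel.
#' @param min_size Minimum component size in pixels.
#' @param reference Which channel (1 or 2) provides the denominator.
#' @return List of class `axq_coloc`: `masks` (labelled integer matrices),
#'   `counts` tibble `(channel, n_particles)`, `dual_count` and
#'   `percent_colocalization` (`NA` with a warning when the reference channel
#'   is empty).
#' @export
make_masks_and_count <- function(filtered, thresholds, min_size = 4L,
                                 reference = 1L) {
  stopifnot(length(filtered) == 2L, length(thresholds) == 2L)
  reference <- as.integer(reference)
  if (!reference %in% 1:2) stopf("`reference` must be 1 or 2")

  label_channel <- function(img, thr) {
    lab <- EBImage::bwlabel(img > thr)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel compactly
    ids <- sort(unique(lab[lab > 0]))
    lab[] <- match(lab, ids, nomatch = 0L)
    lab
  }
  labs <- purrr::map2(filtered, as.list(thresholds), label_channel)
  counts <- vapply(labs, max, numeric(1))

  other <- if (reference == 1L) 2L else 1L
  ref_lab <- labs[[reference]]
  other_mask <- labs[[other]] > 0
  dual <- length(unique(ref_lab[ref_lab > 0 & other_mask]))
  pct <- if (counts[reference] == 0) {
    warnf("reference channel has zero particles: percent colocalization undefined")
    NA_real_
  } else 100 * dual / counts[reference]

  structure(list(
    masks = labs,
    counts = tibble::tibble(channel = 1:2, n_particles = as.integer(counts)),
    dual_count = as.integer(dual),
    reference = reference,
    percent_colocalization = pct), class = "axq_coloc")
}

#' PLA dot density per nucleus
#'
#' The number of proximity-ligation dots per 100 um^2 normalized by the
#' number of DAPI-positive nuclei in the field.
#'
#' @param dot_count Number of fluorescent dots (`>= 0`).
#' @param field_area Field area, um^2 (`> 0`).
#' @param nuclei_count Number of nuclei (`>= 1`).
#' @return Dots per 100 um^2 per nucleus.
#' @export
pla_density <- function(dot_count, field_area, nuclei_count) {
  if (field_area <= 0) stopf("`field_area` must be > 0")
  if (nuclei_count < 1) stopf("`nuclei_count` must be >= 1")
  (100 * dot_count / field_area) / nuclei_count
}
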