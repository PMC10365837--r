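#' Detect exocytosis events in a pHluorin movie
#'
#' For each synapse ROI (a disc), the per-frame mean-intensity trace is
#' baseline-corrected with a trailing (causal) rolling median and scanned for
#' positive excursions: an event starts where the baseline-subtracted trace
#' first exceeds `dF_threshold`, and a fresh rise of at least `dF_threshold`
#' within an ongoing excursion (a new fusion landing on the decaying tail of
#' the previous one) starts another. Each event's peak dF is the maximum of
#' its stretch of the excursion. Successive events in one ROI must be
#' separated by at least `min_separation` frames (the detector's dead
#' time).
#'
#' @param movie Array `[y, x, frame]`.
#' @param rois Tibble `(roi, x, y, radius)` in pixel coordinates (e.g. the
#'   `rois` table of [simulate_phluorin_movie()], one field at a time).
#' @param dF_threshold Minimum peak dF of an event, fluorescence units
#'   (`> 0`).
#' @param min_separation Minimum frames between event onsets (`> 0`).
#' @param baseline_window Frames in the trailing median baseline.
#' @return Tibble `(roi, onset_frame, peak_df)`.
#' @export
detect_events <- function(movie, rois,
                          dF_threshold = 20,
                          min_separation = 3L,
                          baseline_window = 25L) {
  if (dF_threshold <= 0 || min_separation <= 0)
    stopf("`dF_threshold` and `min_separation` must be > 0")
  ny <- dim(movie)[1]; nx <- dim(movie)[2]; nf <- dim(movie)[3]
  rois <- tibble::as_tibble(rois)
  flat <- matrix(movie, ny * nx, nf)

  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    cx <- rois$x[i]; cy <- rois$y[i]; rr <- rois$radius[i]
    if (cx - rr < 1 || cx + rr > nx || cy - rr < 1 || cy + rr > ny)
      stopf("ROI %s lies outside the image", rois$roi[i])
    xs <- floor(cx - rr):ceiling(cx + rr)
    ys <- floor(cy - rr):ceiling(cy + rr)
    grid <- expand.grid(y = ys, x = xs)
    keep <- (grid$x - cx)^2 + (grid$y - cy)^2 <= rr^2
    idx <- (grid$x[keep] - 1L) * ny + grid$y[keep]
    trace <- colMeans(flat[idx, , drop = FALSE])

    base <- numeric(nf)
    base[1L] <- trace[1L]
    for (f in 2:nf)
      base[f] <- stats::median(trace[max(1L, f - baseline_window):(f - 1L)])
    df <- trace - base

    # An event is a genuine step: dF above threshold AND risen by at least
    # the threshold within the last three frames. This counts fusions that
    # land on the decaying tail of a previous event, while noise wobbling
    # around the threshold during a decay never re-triggers.
    onsets <- integer(0)
    last <- -Inf
    for (f in 2:nf) {
      if (df[f] <= dF_threshold) next
      if (f - last < min_separation) next
      rise <- df[f] - min(df[max(1L, f - 3L):(f - 1L)])
      if (rise >= dF_threshold) {
        onsets <- c(onsets, f)
        last <- f
      }
    }
    if (df[1L] > dF_threshold) onsets <- c(1L, onsets)  # step before frame 1
    if (length(onsets) == 0L) return(NULL)
    peak_until <- c(onsets[-1L] - 1L, nf)
    ev <- tibble::tibble(
      onset_frame = onsets,
      peak_df = vapply(seq_along(onsets), function(j) {
        seg <- onsets[j]:peak_until[j]
        below <- which(df[seg] <= dF_threshold)
        if (length(below)) seg <- seg[seq_len(below[1L])]
        max(df[seg])
      }, numeric(1)))
    dplyr::mutate(ev, roi = rois$roi[i], .before = 1L)
  })
}

#' Tally exocytosis events for one field
#'
#' One acquisition precedes stimulation and three follow it; the post count
#' is the mean over the three post acquisitions so that pre and post stay on
#' the same per-acquisition scale.
#'
#' @param pre_events Event table (or bare count) of the pre acquisition.
#' @param post_events_by_acquisition List of exactly three event tables (or
#'   bare counts), one per post acquisition.
#' @param field Optional field identifier carried through.
#' @return One-row tibble `(field, y_pre, y_post, delta)` with
#'   `delta = y_post - y_pre`.
#' @export
tally_field <- function(pre_events, post_events_by_acquisition, field = 1L) {
  count_of <- function(x) if (is.data.frame(x)) nrow(x) else as.numeric(x)
  if (length(post_events_by_acquisition) != 3L)
    stopf("exactly three post-stimulation acquisitions are required")
  y_pre <- count_of(pre_events)
  y_post <- mean(vapply(post_events_by_acquisition, count_of, numeric(1)))
  tibble::tibble(field = field, y_pre = y_pre, y_post = y_post,
                 delta = y_post - y_pre)
}

#' Reference-normalized exocytosis activity
#'
#' Implements the normalized activity statistic: for test field `i` with
#' post-minus-pre event-count change `delta_i`, and reference (control) field
#' changes `x_1..x_n`,
#' \deqn{y_i = \frac{(\Delta_i - \bar x) + 100}{100}.}
#' A test field whose activity increased exactly as much as the average
#' reference field scores 1.
#'
#' @param test_fields Tibble with a `delta` column (e.g. from
#'   [tally_field()]), one row per test field.
#' @param reference_fields Non-empty tibble with a `delta` column for the
#'   reference group.
#' @return `test_fields` with `y_norm`, `ref_mean` and `n_ref` appended.
#' @export
normalize_activity <- function(test_fields, reference_fields) {
  test_fields <- tibble::as_tibble(test_fields)
  reference_fields <- tibble::as_tibble(reference_fields)
  if (nrow(reference_fields) == 0L) stopf("reference field set is empty")
  ref_mean <- mean(reference_fields$delta)
  dplyr::mutate(test_fields,
                y_norm = ((.data$delta - ref_mean) + 100) / 100,
                ref_mean = ref_mean,
                n_ref = nrow(reference_fields))
}

#' Post/pre amplitude normalization per ROI
#'
#' The amplitude of the signal after stimulation is normalized by that of the
#' same synapse before stimulation.
#'
#' @param post_amplitudes,pre_amplitudes Tibbles `(roi, amplitude)` holding
#'   the per-ROI mean peak dF after and before stimulation.
#' @return Tibble `(roi, pre, post, ratio)`; the ratio is `NA` (with a
#'   warning) for ROIs missing from either epoch or with non-positive pre
#'   amplitude.
#' @export
normalize_amplitude <- function(post_amplitudes, pre_amplitudes) {
  out <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(pre_amplitudes), pre = "amplitude"),
    dplyr::rename(tibble::as_tibble(post_amplitudes), post = "amplitude"),
    by = "roi") |>
    dplyr::mutate(ratio = dplyr::if_else(
      !is.na(.data$pre) & .data$pre > 0 & !is.na(.data$post),
      .data$post / .data$pre, NA_real_))
  bad <- sum(is.na(out$ratio))
  if (bad > 0)
    warnf("%d ROI(s) with zero/missing pre amplitude or unmatched epochs: ratio set to NA",
          bad)
  out
}
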