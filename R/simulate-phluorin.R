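#' Simulate pHluorin exocytosis movies for one or more fields
#'
#' Each field is imaged four times (one acquisition before and three after
#' chemical stimulation), every 200 ms for 1 min by default. Synapse ROIs are
#' discs at integer pixel centres; an exocytosis event is a step rise of
#' `event_amplitude` at the ROI centre followed by exponential decay with time
#' constant `decay_tau`. Event onsets are Poisson in time at `pre_rate`
#' (events/min/ROI) in the pre acquisition and `post_rate` in each post
#' acquisition.
#'
#' @param n_fields Number of fields to simulate.
#' @param rois_per_field Synapse ROIs per field.
#' @param pre_rate,post_rate Events per minute per ROI before/after
#'   stimulation. Must be `>= 0`.
#' @param event_amplitude Peak fluorescence step above baseline (dF).
#' @param decay_tau Decay time constant, seconds (`> 0`).
#' @param frame_interval,duration Acquisition timing, seconds.
#' @param field_size Image side, pixels.
#' @param roi_radius ROI disc radius, pixels.
#' @param background Baseline intensity, photons/pixel.
#' @param psf_sigma Spot width (s.d.), pixels.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sd See [transport_sim_config()].
#' @param seed Integer seed.
#'
#' @return A list with:
#'   * `fields`: one element per field, each a named list of four stacks
#'     `pre`, `post1`, `post2`, `post3` (arrays `[y, x, frame]`);
#'   * `rois`: tibble `(field, roi, x, y, radius)`;
#'   * `truth`: tibble `(field, acquisition, epoch, roi, onset_frame,
#'     amplitude)` with one row per injected event.
#' @export
simulate_phluorin_movie <- function(n_fields = 1,
                                    rois_per_field = 10,
                                    pre_rate = 2,
                                    post_rate = 4,
                                    event_amplitude = 80,
                                    decay_tau = 2,
                                    frame_interval = 0.2,
                                    duration = 60,
                                    field_size = 120,
                                    roi_radius = 3,
                                    background = 100,
                                    psf_sigma = 1.3,
                                    noise_model = "poisson",
                                    noise_sd = NULL,
                                    seed = 1L) {
  if (pre_rate < 0 || post_rate < 0) stopf("event rates must be >= 0")
  if (decay_tau <= 0) stopf("`decay_tau` must be > 0")
  set.seed(as.integer(seed))
  n_frames <- as.integer(round(duration / frame_interval))
  acqs <- c(pre = pre_rate, post1 = post_rate, post2 = post_rate,
            post3 = post_rate)

  # ROI centres on a jittered grid, at integer pixels, away from edges.
  grid_n <- ceiling(sqrt(rois_per_field))
  pitch <- (field_size - 20) / grid_n
  centres <- expand.grid(gx = seq_len(grid_n), gy = seq_len(grid_n))
  centres <- centres[seq_len(rois_per_field), , drop = FALSE]

  rois <- purrr::map_dfr(seq_len(n_fields), function(fld) {
    tibble::tibble(
      field = fld, roi = seq_len(rois_per_field),
      x = round(10 + (centres$gx - 0.5) * pitch +
                  stats::runif(rois_per_field, -2, 2)),
      y = round(10 + (centres$gy - 0.5) * pitch +
                  stats::runif(rois_per_field, -2, 2)),
      radius = roi_radius)
  })

  truth_rows <- list()
  fields <- purrr::map(seq_len(n_fields), function(fld) {
    froi <- dplyr::filter(rois, .data$field == fld)
    stacks <- purrr::imap(acqs, function(rate, acq) {
      stack <- array(background, dim = c(field_size, field_size, n_frames))
      for (r in seq_len(nrow(froi))) {
        n_ev <- stats::rpois(1L, rate * duration / 60)
        if (n_ev == 0) next
        onsets <- sort(sample.int(n_frames, min(n_ev, n_frames)))
        for (on in onsets) {
          t_rel <- (seq(from = on, to = n_frames) - on) * frame_interval
          amp_t <- event_amplitude * exp(-t_rel / decay_tau)
          for (k in seq_along(amp_t)) {
            f <- on + k - 1L
            stack[, , f] <- add_spot(stack[, , f], froi$x[r], froi$y[r],
                                     amp_t[k], psf_sigma)
          }
          truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
            field = fld, acquisition = acq,
            epoch = if (acq == "pre") "pre" else "post",
            roi = froi$roi[r], onset_frame = on,
            amplitude = event_amplitude)
        }
      }
      stack <- apply_noise(stack, noise_model, noise_sd)
      attr(stack, "frame_interval") <- frame_interval
      stack
    })
    stacks
  })

  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble::tibble(field = integer(), acquisition = character(),
                   epoch = character(), roi = integer(),
                   onset_frame = integer(), amplitude = numeric())
  list(fields = fields, rois = rois, truth = truth)
}
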