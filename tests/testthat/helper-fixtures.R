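# Shared builders for small deterministic fixtures.

straight_path <- function(movie, y = NULL) {
  y <- y %||% ((dim(movie)[1] + 1) / 2)
  axonquant::axon_path(data.frame(x = c(4, dim(movie)[2] - 4), y = c(y, y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clean single-vesicle transport configuration (no noise, no switching).
clean_one_vesicle_config <- function(speed = 1.0, direction = "antero",
                                     duration = 10, seed = 1L) {
  probs <- c(antero = 0, retro = 0, pause = 0)
  probs[direction] <- 1
  axonquant::transport_sim_config(
    n_vesicles = 1, duration = duration,
    speed_antero = c(speed, 0), speed_retro = c(speed, 0),
    state_switch_rates = c(antero_retro = 0, antero_pause = 0,
                           retro_antero = 0, retro_pause = 0,
                           pause_antero = 0, pause_retro = 0),
    fraction_static = 0, initial_state_probs = probs,
    noise_model = "none", seed = seed)
}

# Rectangle terminal with the active zone along the full bottom edge.
rect_geometry <- function(width = 400, height = 200, n_ves = 0) {
  structure(list(
    terminal = cbind(x = c(0, width, width, 0), y = c(0, 0, height, height)),
    active_zone = cbind(x = c(0, width), y = c(0, 0)),
    vesicles = tibble::tibble(x = numeric(n_ves), y = numeric(n_ves)),
    vesicle_radius = 20), class = "axq_synapse_geometry")
}

# Build a track tibble from per-frame positions.
track_tbl <- function(positions, track = 1L) {
  tibble::tibble(track = track, frame = seq_along(positions),
                 position_um = positions)
}

# ROI-mean gain of a unit-peak Gaussian spot centred on the ROI: converts a
# spot's peak amplitude into the expected jump of the disc-averaged trace.
mean_disc_gain <- function(roi, sigma = 1.3) {
  xs <- floor(roi$x - roi$radius):ceiling(roi$x + roi$radius)
  ys <- floor(roi$y - roi$radius):ceiling(roi$y + roi$radius)
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$x - roi$x)^2 + (grid$y - roi$y)^2 <= roi$radius^2
  g <- exp(-((grid$x[keep] - roi$x)^2 + (grid$y[keep] - roi$y)^2) /
             (2 * sigma^2))
  mean(g)
}

# Match detected exocytosis events to truth onsets (per ROI, +/- tol frames).
event_match_stats <- function(detected, truth, tol = 2L) {
  tp <- 0L
  for (r in unique(truth$roi)) {
    t_on <- sort(truth$onset_frame[truth$roi == r])
    d_on <- sort(detected$onset_frame[detected$roi == r])
    for (on in t_on) {
      hit <- which(abs(d_on - on) <= tol)
      if (length(hit)) { tp <- tp + 1L; d_on <- d_on[-hit[1L]] }
    }
  }
  list(recall = if (nrow(truth)) tp / nrow(truth) else 1,
       precision = if (nrow(detected)) tp / nrow(detected) else 1)
}
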