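#' Configuration for the axonal transport simulator
#'
#' Bundles every knob of the vesicle transport movie generator. Defaults
#' reproduce the acquisition used for axonal transport recordings of
#' fluorescently tagged synaptic vesicle precursors in microfluidic devices:
#' one frame every 200 ms for 1 min over a 100 um stretch of axon imaged at
#' 0.1 um/px (63x objective scale).
#'
#' Vesicles switch among anterograde, retrograde and paused states as a
#' continuous-time Markov chain sampled at the frame interval; a configurable
#' fraction never moves at all (static pool). Segmental speeds are drawn per
#' state entry from truncated normal distributions. By the package's axis
#' convention, position increases toward the presynapse, so anterograde
#' displacement is positive.
#'
#' @param n_vesicles Number of vesicles in the field.
#' @param frame_interval Seconds between frames. Must divide `duration`.
#' @param duration Total recording length in seconds.
#' @param pixel_size Micrometers per pixel.
#' @param axon_length Length of the simulated axon window, micrometers.
#' @param speed_antero,speed_retro Length-2 numeric `(mean, sd)` of unsigned
#'   segmental speed in um/s for each moving state.
#' @param state_switch_rates Named per-second hazards of the six transitions
#'   among `antero`, `retro` and `pause` (names like `"antero_pause"`).
#' @param fraction_static Fraction of vesicles that never move, in `[0, 1]`.
#' @param initial_state_probs Named probabilities over the three states for a
#'   moving vesicle's first frame.
#' @param psf_sigma Gaussian spot width (s.d.) in pixels.
#' @param background Background level, photons/pixel.
#' @param amplitude Peak spot amplitude above background, photons.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sd Gaussian read-noise s.d. (only used when
#'   `noise_model = "gaussian"`; default `sqrt(background)`).
#' @param seed Integer seed; every random draw of the simulator flows from it.
#'
#' @return A list of class `axq_transport_config`.
#' @seealso [simulate_axonal_movie()]
#' @export
transport_sim_config <- function(n_vesicles = 30,
                                 frame_interval = 0.2,
                                 duration = 60,
                                 pixel_size = 0.1,
                                 axon_length = 100,
                                 speed_antero = c(1.2, 0.2),
                                 speed_retro = c(1.0, 0.2),
                                 state_switch_rates = c(
                                   antero_retro = 0.01, antero_pause = 0.06,
                                   retro_antero = 0.01, retro_pause = 0.06,
                                   pause_antero = 0.10, pause_retro = 0.08),
                                 fraction_static = 0.2,
                                 initial_state_probs = c(
                                   antero = 0.45, retro = 0.35, pause = 0.20),
                                 psf_sigma = 1.3,
                                 background = 100,
                                 amplitude = 120,
                                 noise_model = "poisson",
                                 noise_sd = NULL,
                                 seed = 1L) {
  if (frame_interval <= 0) stopf("`frame_interval` must be > 0")
  n_frames <- duration / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-8)
    stopf("`duration` (%g s) is not an integer number of frames at frame_interval %g s",
          duration, frame_interval)
  if (any(speed_antero < 0) || any(speed_retro < 0))
    stopf("segmental speeds must be >= 0")
  assert_prob(fraction_static, "fraction_static")
  needed <- c("antero_retro", "antero_pause", "retro_antero",
              "retro_pause", "pause_antero", "pause_retro")
  if (!all(needed %in% names(state_switch_rates)))
    stopf("`state_switch_rates` must name all of: %s",
          paste(needed, collapse = ", "))
  if (any(state_switch_rates < 0)) stopf("switch hazards must be >= 0")
  structure(list(
    n_vesicles = as.integer(n_vesicles),
    frame_interval = frame_interval, duration = duration,
    pixel_size = pixel_size, axon_length = axon_length,
    speed_antero = speed_antero, speed_retro = speed_retro,
    state_switch_rates = state_switch_rates,
    fraction_static = fraction_static,
    initial_state_probs = initial_state_probs / sum(initial_state_probs),
    psf_sigma = psf_sigma, background = background, amplitude = amplitude,
    noise_model = noise_model, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "axq_transport_config")
}

# Sample one vesicle's state/speed sequence; returns tibble rows while the
# vesicle remains inside [0, axon_length]. speed_um_s governs the step from
# frame k to k + 1, so position[k + 1] = position[k] + speed[k] * dt exactly.
simulate_vesicle_path <- function(cfg, start, static, n_frames) {
  dt <- cfg$frame_interval
  states <- character(n_frames)
  speeds <- numeric(n_frames)
  pos <- numeric(n_frames)
  draw_speed <- function(state) {
    if (state == "pause") return(0)
    p <- if (state == "antero") cfg$speed_antero else cfg$speed_retro
    s <- stats::rnorm(1L, p[1], p[2])
    max(s, 0.05)
  }
  state <- if (static) "pause" else
    sample(c("antero", "retro", "pause"), 1L, prob = cfg$initial_state_probs)
  speed <- if (static) 0 else draw_speed(state)
  pos[1L] <- start
  k <- 1L
  repeat {
    states[k] <- state
    speeds[k] <- if (state == "retro") -speed else speed
    if (k == n_frames) break
    nxt <- pos[k] + speeds[k] * dt
    if (nxt < 0 || nxt > cfg$axon_length) break  # vesicle leaves the window
    pos[k + 1L] <- nxt
    k <- k + 1L
    if (!static) {
      r <- cfg$state_switch_rates
      out_rates <- switch(state,
        antero = c(retro = r[["antero_retro"]], pause = r[["antero_pause"]]),
        retro  = c(antero = r[["retro_antero"]], pause = r[["retro_pause"]]),
        pause  = c(antero = r[["pause_antero"]], retro = r[["pause_retro"]]))
      p_switch <- pmin(out_rates * dt, 1)
      u <- stats::runif(2L)
      hit <- which(u < p_switch)
      if (length(hit)) {
        state <- names(out_rates)[hit[1L]]
        speed <- draw_speed(state)
      }
    }
  }
  tibble::tibble(frame = seq_len(k), position_um = pos[seq_len(k)],
                 state = states[seq_len(k)], speed_um_s = speeds[seq_len(k)])
}

#' Simulate a time-lapse movie of vesicles moving along a straight axon
#'
#' Renders `n_vesicles` Gaussian spots on a noisy background while each
#' vesicle performs state-switching motion along the axon axis. Vesicles that
#' reach either end of the window leave the field (their truth record stops at
#' the last visible frame). The returned ground truth carries the per-frame
#' position, state and signed speed of every vesicle plus a per-vesicle
#' summary including its motion class under the same dominant-displacement
#' rule used by [classify_vesicle()].
#'
#' @param config An [transport_sim_config()] object.
#'
#' @return A list with elements
#'   * `movie`: numeric array `[y, x, frame]` with attributes `pixel_size`,
#'     `frame_interval`, `x_margin_px` (pixels before arc-length 0) and
#'     `axon_row` (the image row of the axon axis);
#'   * `truth`: list with tibbles `frames` (vesicle, frame, time_s,
#'     position_um, state, speed_um_s) and `vesicles` (vesicle, static, class,
#'     start_um, net_displacement_um, n_frames).
#' @examples
#' cfg <- transport_sim_config(n_vesicles = 3, duration = 10, seed = 7)
#' sim <- simulate_axonal_movie(cfg)
#' dim(sim$movie)
#' @export
simulate_axonal_movie <- function(config) {
  stopifnot(inherits(config, "axq_transport_config"))
  set.seed(config$seed)
  n_frames <- as.integer(round(config$duration / config$frame_interval))
  margin <- 4L
  ny <- 15L
  nx <- as.integer(round(config$axon_length / config$pixel_size)) + 2L * margin
  y0 <- (ny + 1) / 2

  n_static <- round(config$fraction_static * config$n_vesicles)
  static <- rep(FALSE, config$n_vesicles)
  if (config$n_vesicles > 0 && n_static > 0)
    static[sample.int(config$n_vesicles, n_static)] <- TRUE

  frames_tb <- purrr::map_dfr(seq_len(config$n_vesicles), function(i) {
    start <- stats::runif(1L, 0, config$axon_length)
    dplyr::mutate(
      simulate_vesicle_path(config, start, static[i], n_frames),
      vesicle = i, .before = 1L)
  })

  stack <- array(config$background, dim = c(ny, nx, n_frames))
  if (nrow(frames_tb) > 0) {
    for (r in seq_len(nrow(frames_tb))) {
      f <- frames_tb$frame[r]
      x <- margin + frames_tb$position_um[r] / config$pixel_size
      stack[, , f] <- add_spot(stack[, , f], x, y0,
                               config$amplitude, config$psf_sigma)
    }
  }
  stack <- apply_noise(stack, config$noise_model, config$noise_sd)
  attr(stack, "pixel_size") <- config$pixel_size
  attr(stack, "frame_interval") <- config$frame_interval
  attr(stack, "x_margin_px") <- margin
  attr(stack, "axon_row") <- y0

  vesicles <- if (nrow(frames_tb) == 0) {
    tibble::tibble(vesicle = integer(), static = logical(),
                   class = character(), start_um = numeric(),
                   net_displacement_um = numeric(), n_frames = integer())
  } else {
    frames_tb |>
      dplyr::mutate(time_s = (.data$frame - 1) * config$frame_interval) |>
      dplyr::group_by(.data$vesicle) |>
      dplyr::summarise(
        start_um = .data$position_um[1L],
        net_displacement_um = dplyr::last(.data$position_um) -
          .data$position_um[1L],
        disp_antero = sum(pmax(diff(.data$position_um), 0)),
        disp_retro = sum(pmax(-diff(.data$position_um), 0)),
        max_excursion = max(abs(.data$position_um - .data$position_um[1L])),
        n_frames = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        static = static[.data$vesicle],
        class = dplyr::case_when(
          .data$max_excursion < 0.4 ~ "static",
          .data$disp_antero > .data$disp_retro ~ "anterograde",
          .data$disp_retro > .data$disp_antero ~ "retrograde",
          TRUE ~ "anterograde")) |>
      dplyr::select("vesicle", "static", "class", "start_um",
                    "net_displacement_um", "n_frames")
  }
  if (nrow(frames_tb) > 0) {
    frames_tb <- dplyr::mutate(
      frames_tb, time_s = (.data$frame - 1) * config$frame_interval,
      .after = "frame")
  } else {
    frames_tb <- tibble::tibble(vesicle = integer(), frame = integer(),
                                time_s = numeric(), position_um = numeric(),
                                state = character(), speed_um_s = numeric())
  }

  list(movie = stack, truth = list(frames = frames_tb, vesicles = vesicles))
}

#' Convert simulator ground truth into analysis-ready tracks
#'
#' Bypasses detection/linking so downstream segmentation and summaries can be
#' validated against exact kinematics.
#'
#' @param truth The `truth` element returned by [simulate_axonal_movie()].
#' @return A tibble `(track, frame, position_um)` with one track per vesicle.
#' @export
tracks_from_truth <- function(truth) {
  tibble::as_tibble(truth$frames) |>
    dplyr::transmute(track = .data$vesicle, frame = .data$frame,
                     position_um = .data$position_um)
}
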