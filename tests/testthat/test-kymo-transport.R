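test_that("kymograph extraction reproduces direct indexing", {
  movie <- array(0, dim = c(15, 60, 5))
  path <- straight_path(movie)
  k0 <- extract_kymograph(movie, path)
  expect_true(all(k0 == 0))
  expect_equal(nrow(k0), 5)

  # single static bright pixel on the path -> one constant bright column
  movie[8, 30, ] <- 10
  k1 <- extract_kymograph(movie, straight_path(movie))
  bright <- which(unclass(k1) > 0, arr.ind = TRUE)
  expect_equal(sort(unique(bright[, 1])), 1:5)       # present in all frames
  expect_equal(length(unique(bright[, 2])), 1)       # single position bin
  expect_equal(unique(bright[, 2]), 30 - 4 + 1)      # bin of pixel x = 30

  expect_error(extract_kymograph(movie,
    axon_path(data.frame(x = c(-10, 200), y = c(8, 8)))), "exits the image")
})

test_that("a constant-velocity vesicle traces a line of the right slope", {
  sim <- simulate_axonal_movie(clean_one_vesicle_config(speed = 1.0,
                                                        duration = 10))
  kym <- extract_kymograph(sim$movie, straight_path(sim$movie))
  peak_bin <- apply(unclass(kym), 1L, which.max)
  px <- attr(kym, "bin_size_um")
  slope <- stats::coef(stats::lm(peak_bin ~ seq_along(peak_bin)))[2]
  # v * dt / bin_size bins per frame
  expect_equal(unname(slope), 1.0 * 0.2 / px, tolerance = 0.05)
})

test_that("segment_track recovers hand-computed segmental motion", {
  # 10 intervals at +1 um/s, 10 paused, 10 at +1 um/s (dt = 0.2 s)
  pos <- cumsum(c(0, rep(0.2, 10), rep(0, 10), rep(0.2, 10)))
  seg <- segment_track(track_tbl(pos), frame_interval = 0.2)
  expect_equal(seg$direction, c("anterograde", "pause", "anterograde"))
  expect_equal(seg$mean_speed_um_s[c(1, 3)], c(1, 1), tolerance = 1e-12)

  seg_r <- segment_track(track_tbl(seq(10, 7, by = -0.1)),
                         frame_interval = 0.2)
  expect_equal(seg_r$direction, "retrograde")
  expect_equal(seg_r$mean_speed_um_s, 0.5, tolerance = 1e-12)
  expect_equal(seg_r$signed_displacement_um, -3, tolerance = 1e-12)

  seg_p <- segment_track(track_tbl(rep(5, 20)), frame_interval = 0.2)
  expect_equal(seg_p$direction, "pause")
  expect_warning(segment_track(track_tbl(c(1, 2))), "too short")
})

test_that("classify_vesicle follows the dominant-displacement rule", {
  expect_equal(classify_vesicle(track_tbl(rep(3, 50))), "static")
  # net +12 um with a brief 1 um retrograde excursion
  pos <- c(seq(0, 6, by = 0.2), seq(5.8, 5, by = -0.2),
           seq(5.2, 12, by = 0.2))
  expect_equal(classify_vesicle(track_tbl(pos)), "anterograde")
  # symmetric back-and-forth: tie broken to the later direction
  pos_tie <- c(seq(0, 2, by = 0.2), seq(1.8, 0, by = -0.2))
  expect_equal(classify_vesicle(track_tbl(pos_tie)), "retrograde")
})

test_that("summarize_axon computes counts, flux, flow and directionality", {
  mk <- function(id, v) track_tbl(seq(20, by = v * 0.2, length.out = 61), id)
  tracks <- dplyr::bind_rows(
    mk(1, 1.0), mk(2, 1.2), mk(3, 0.8),     # anterograde
    mk(4, -1.0),                            # retrograde
    mk(5, 0), mk(6, 0))                     # static
  s <- summarize_axon(tracks, window_length_um = 100, duration_s = 60)
  expect_equal(s$n_anterograde, 3)
  expect_equal(s$n_retrograde, 1)
  expect_equal(s$n_static, 2)
  expect_equal(s$net_flux_per_100um_min, 2)
  expect_equal(s$mean_speed_antero_um_s, 1.0, tolerance = 1e-9)
  expect_equal(s$mean_speed_retro_um_s, 1.0, tolerance = 1e-9)

  # symmetric traffic: zero flux and directionality
  sym <- dplyr::bind_rows(mk(1, 1.0), mk(2, -1.0))
  s2 <- summarize_axon(sym, 100, 60)
  expect_equal(s2$net_flux_per_100um_min, 0)
  expect_equal(s2$directionality, 0, tolerance = 1e-12)

  # nothing moves -> directionality undefined
  s3 <- summarize_axon(dplyr::bind_rows(mk(1, 0), mk(2, 0)), 100, 60)
  expect_true(is.na(s3$directionality))
})

test_that("truth-fed tracks reproduce simulator truth exactly", {
  cfg <- transport_sim_config(n_vesicles = 25, noise_model = "none", seed = 3)
  sim <- simulate_axonal_movie(cfg)
  tt <- tracks_from_truth(sim$truth)
  s <- suppressWarnings(summarize_axon(
    tt, pause_speed_threshold = 0.025, min_segment_frames = 1L))
  truth_counts <- table(sim$truth$vesicles$class)
  expect_equal(s$n_anterograde, unname(truth_counts["anterograde"]))
  expect_equal(s$n_retrograde, unname(truth_counts["retrograde"]))
  expect_equal(s$n_static, unname(truth_counts["static"]))
  expect_equal(s$net_flux_per_100um_min,
               unname(truth_counts["anterograde"] -
                        truth_counts["retrograde"]))

  # independent oracle for segmental speeds: state runs of the truth table
  oracle_speeds <- sim$truth$frames |>
    dplyr::group_by(.data$vesicle) |>
    dplyr::group_map(function(tv, key) {
      lab <- tv$state[-nrow(tv)]              # state governing each interval
      runs <- rle(lab)
      ends <- cumsum(runs$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      disp <- tv$position_um[ends + 1] - tv$position_um[starts]
      dur <- (tv$frame[ends + 1] - tv$frame[starts]) * 0.2
      tibble::tibble(state = runs$values, speed = abs(disp) / dur)
    }) |> dplyr::bind_rows()
  expect_equal(s$mean_speed_antero_um_s,
               mean(oracle_speeds$speed[oracle_speeds$state == "antero"]),
               tolerance = 1e-9)
  expect_equal(s$mean_speed_retro_um_s,
               mean(oracle_speeds$speed[oracle_speeds$state == "retro"]),
               tolerance = 1e-9)
})

test_that("transport metrics obey mirror and reversal symmetries", {
  cfg <- transport_sim_config(n_vesicles = 15, noise_model = "none", seed = 9)
  sim <- simulate_axonal_movie(cfg)
  tt <- tracks_from_truth(sim$truth)
  args <- list(pause_speed_threshold = 0.025, min_segment_frames = 1L)
  s <- suppressWarnings(do.call(summarize_axon, c(list(tt), args)))

  # mirror reflection of the axial coordinate flips flux and flow
  mirrored <- dplyr::mutate(tt, position_um = 100 - .data$position_um)
  sm <- suppressWarnings(do.call(summarize_axon, c(list(mirrored), args)))
  expect_equal(sm$net_flux_per_100um_min, -s$net_flux_per_100um_min)
  expect_equal(sm$linear_flow_um_per_min, -s$linear_flow_um_per_min,
               tolerance = 1e-9)
  expect_equal(sm$directionality, -s$directionality, tolerance = 1e-9)
  expect_equal(sm$n_anterograde, s$n_retrograde)
  expect_equal(sm$n_static, s$n_static)

  # reversing time swaps the class counts the same way
  reversed <- tt |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(frame = rev(.data$frame)) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::ungroup()
  sr <- suppressWarnings(do.call(summarize_axon, c(list(reversed), args)))
  expect_equal(sr$n_anterograde, s$n_retrograde)
  expect_equal(sr$n_retrograde, s$n_anterograde)
  expect_equal(sr$n_static, s$n_static)
})

test_that("detection and linking recover clean trajectories", {
  # empty movie -> no tracks
  empty <- array(100, dim = c(15, 200, 20))
  expect_equal(nrow(detect_and_link(empty, straight_path(empty))), 0)

  # one clean vesicle: a single track within one pixel of truth
  cfg <- clean_one_vesicle_config(speed = 1.0, duration = 20, seed = 2)
  sim <- simulate_axonal_movie(cfg)
  tr <- detect_and_link(sim$movie, straight_path(sim$movie))
  expect_equal(dplyr::n_distinct(tr$track), 1)
  j <- dplyr::inner_join(tr, sim$truth$frames, by = "frame")
  expect_lt(max(abs(j$position_um.x - j$position_um.y)), 0.1)

  # two well-separated static vesicles: two tracks, no identity swaps
  movie <- array(100, dim = c(15, 300, 50))
  for (f in 1:50) {
    movie[, , f] <- axonquant:::add_spot(movie[, , f], 50, 8, 120, 1.3)
    movie[, , f] <- axonquant:::add_spot(movie[, , f], 250, 8, 120, 1.3)
  }
  attr(movie, "pixel_size") <- 0.1; attr(movie, "frame_interval") <- 0.2
  tr2 <- detect_and_link(movie, straight_path(movie))
  expect_equal(dplyr::n_distinct(tr2$track), 2)
  spreads <- tapply(tr2$position_um, tr2$track, function(p) diff(range(p)))
  expect_true(all(spreads < 0.2))
})
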