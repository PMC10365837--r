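test_that("transport config validates timing and rates", {
  cfg <- transport_sim_config()
  expect_equal(cfg$duration / cfg$frame_interval, 300)
  expect_error(transport_sim_config(duration = 61.3), "integer number of frames")
  expect_error(transport_sim_config(speed_antero = c(-1, 0)), ">= 0")
  expect_error(transport_sim_config(fraction_static = 1.4), "\\[0, 1\\]")
})

test_that("axonal movie has the requested geometry and empty case works", {
  cfg <- transport_sim_config(n_vesicles = 0, duration = 2,
                              noise_model = "none", seed = 1)
  sim <- simulate_axonal_movie(cfg)
  expect_equal(dim(sim$movie)[3], 10)
  expect_true(all(sim$movie == cfg$background))  # pure background
  expect_equal(nrow(sim$truth$frames), 0)
  expect_equal(nrow(sim$truth$vesicles), 0)
})

test_that("pure anterograde vesicle advances by speed * frame_interval", {
  sim <- simulate_axonal_movie(clean_one_vesicle_config(speed = 1.0))
  steps <- diff(sim$truth$frames$position_um)
  expect_equal(steps, rep(0.2, length(steps)), tolerance = 1e-12)
  expect_equal(sim$truth$vesicles$class, "anterograde")
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- transport_sim_config(n_vesicles = 5, duration = 4, seed = 11)
  s1 <- simulate_axonal_movie(cfg)
  s2 <- simulate_axonal_movie(cfg)
  expect_identical(s1$movie, s2$movie)
  expect_identical(s1$truth, s2$truth)

  p1 <- simulate_phluorin_movie(duration = 10, seed = 5)
  p2 <- simulate_phluorin_movie(duration = 10, seed = 5)
  expect_identical(p1$fields, p2$fields)

  e1 <- simulate_em_synapse(seed = 9)
  e2 <- simulate_em_synapse(seed = 9)
  expect_identical(e1$truth, e2$truth)
})

test_that("transport truth is complete and kinematically consistent", {
  cfg <- transport_sim_config(n_vesicles = 20, seed = 4)
  sim <- simulate_axonal_movie(cfg)
  # every rendered vesicle appears exactly once in the vesicle table
  expect_equal(sort(unique(sim$truth$frames$vesicle)),
               sim$truth$vesicles$vesicle)
  expect_equal(anyDuplicated(sim$truth$vesicles$vesicle), 0L)
  # integrating per-frame speeds reproduces positions
  by_v <- split(sim$truth$frames, sim$truth$frames$vesicle)
  for (tv in by_v) {
    rebuilt <- tv$position_um[1L] +
      cumsum(c(0, tv$speed_um_s[-nrow(tv)] * cfg$frame_interval))
    expect_lt(max(abs(rebuilt - tv$position_um)), 1e-9)
  }
})

test_that("pHluorin simulator renders step events with the stated amplitude", {
  # zero post rate -> no post events
  sim0 <- simulate_phluorin_movie(post_rate = 0, duration = 20, seed = 2)
  expect_equal(sum(sim0$truth$epoch == "post"), 0)

  # expected number of pre events: Poisson with mean rate * rois (over seeds)
  counts <- vapply(1:25, function(s) {
    tr <- simulate_phluorin_movie(pre_rate = 2, post_rate = 0,
                                  rois_per_field = 10, duration = 60,
                                  field_size = 80, noise_model = "none",
                                  seed = s)$truth
    sum(tr$epoch == "pre")
  }, numeric(1))
  expect_equal(mean(counts), 20, tolerance = 0.15)

  # noise-free peak dF equals the configured amplitude at the ROI centre
  sim <- simulate_phluorin_movie(n_fields = 1, rois_per_field = 1,
                                 pre_rate = 1, post_rate = 0, duration = 60,
                                 event_amplitude = 50, background = 100,
                                 noise_model = "none", seed = 3)
  stopifnot(sum(sim$truth$epoch == "pre") >= 1)
  expect_equal(max(sim$fields[[1]]$pre) - 100, 50, tolerance = 1e-9)
  expect_error(simulate_phluorin_movie(decay_tau = 0), "decay_tau")
  expect_error(simulate_phluorin_movie(pre_rate = -1), ">= 0")
})

test_that("EM simulator places vesicles in the requested bands", {
  sim1 <- simulate_em_synapse(n_vesicles = 8,
                              zone_mix = c(1, 0, 0, 0), seed = 7)
  d <- dist_to_polyline <- axonquant:::dist_to_polyline(
    sim1$geometry$vesicles$x, sim1$geometry$vesicles$y,
    sim1$geometry$active_zone)
  expect_true(all(d < 40))

  sim3 <- simulate_em_synapse(n_vesicles = 10,
                              zone_mix = c(0, 0, 1, 0), seed = 8)
  d3 <- axonquant:::dist_to_polyline(sim3$geometry$vesicles$x,
                                     sim3$geometry$vesicles$y,
                                     sim3$geometry$active_zone)
  expect_true(all(d3 >= 80 & d3 < 120))

  empty <- simulate_em_synapse(n_vesicles = 0, seed = 1)
  expect_equal(nrow(empty$geometry$vesicles), 0)

  # hard-core constraint: centres at least one diameter apart
  sim <- simulate_em_synapse(n_vesicles = 40, vesicle_radius = 20, seed = 2)
  dmat <- as.matrix(stats::dist(sim$geometry$vesicles))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 40)

  expect_error(simulate_em_synapse(zone_mix = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("two-channel puncta simulator controls the shared fraction", {
  sim <- simulate_two_channel_puncta(n_puncta = 100, coloc_fraction = 0.5,
                                     field_size = 512, seed = 3)
  expect_equal(sum(sim$truth$shared & sim$truth$channel == 1), 50)
  sim1 <- simulate_two_channel_puncta(n_puncta = 30, coloc_fraction = 1,
                                      jitter = 0, seed = 4)
  t1 <- dplyr::filter(sim1$truth, channel == 1)
  t2 <- dplyr::filter(sim1$truth, channel == 2)
  expect_equal(t1$x[order(t1$pair)], t2$x[order(t2$pair)])
  expect_warning(simulate_two_channel_puncta(n_puncta = 500, field_size = 64,
                                             seed = 1),
                 "overcrowded")
})

test_that("EPSC pair simulator renders the requested peak amplitudes", {
  sw <- simulate_epsc_pair(isi = 500, a1 = 100, ppr_true = 1.5,
                           noise_sd = 0, n_sweeps = 1, seed = 1)
  tr <- sw$trace[[1]]
  before_t2 <- tr$current_pa[tr$time_ms < sw$t2_ms[1]]
  after_t2 <- tr$current_pa[tr$time_ms >= sw$t2_ms[1]]
  # peaks are sampling-limited (10 kHz grid); the ratio cancels the bias
  expect_equal(min(before_t2), -100, tolerance = 2e-4)
  expect_equal(min(after_t2), -150, tolerance = 2e-4)
  expect_equal(min(after_t2) / min(before_t2), 1.5, tolerance = 1e-6)

  eq <- simulate_epsc_pair(isi = 250, a1 = 80, ppr_true = 1, noise_sd = 0,
                           n_sweeps = 2, seed = 1)
  t1 <- eq$trace[[1]]
  p1 <- min(t1$current_pa[t1$time_ms < eq$t2_ms[1]])
  p2 <- min(t1$current_pa[t1$time_ms >= eq$t2_ms[1]])
  expect_equal(p1, p2, tolerance = 1e-6)

  expect_equal(nrow(simulate_epsc_pair(n_sweeps = 20, seed = 1)), 20)
  expect_true(simulate_epsc_pair(isi = 3, seed = 1)$overlap[1])
  expect_error(simulate_epsc_pair(isi = -5), "isi")
  expect_error(simulate_epsc_pair(a1 = 0), "a1")
})
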