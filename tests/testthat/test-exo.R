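test_that("event detection finds injected step rises and their amplitude", {
  # constant movie -> no events
  flat <- array(100, dim = c(40, 40, 100))
  rois <- tibble::tibble(roi = 1L, x = 20, y = 20, radius = 3)
  expect_equal(nrow(detect_events(flat, rois)), 0)

  # noise-free movie with known events: onsets and peak dF recovered
  sim <- simulate_phluorin_movie(n_fields = 1, rois_per_field = 6,
                                 pre_rate = 3, post_rate = 0, duration = 60,
                                 event_amplitude = 50, noise_model = "none",
                                 seed = 6)
  froi <- sim$rois
  ev <- detect_events(sim$fields[[1]]$pre, froi, dF_threshold = 10)
  truth <- dplyr::filter(sim$truth, acquisition == "pre")
  st <- event_match_stats(ev, truth, tol = 1L)
  expect_equal(st$recall, 1)
  expect_equal(st$precision, 1)
  # isolated events: the recorded peak dF equals the injected amplitude
  iso <- truth |>
    dplyr::group_by(roi) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  for (r in iso$roi) {
    peak <- ev$peak_df[ev$roi == r]
    expect_equal(max(peak), 50 * mean_disc_gain(froi[froi$roi == r, ]),
                 tolerance = 0.02)
  }
  expect_error(detect_events(flat, tibble::tibble(roi = 1, x = 39, y = 39,
                                                  radius = 5)),
               "outside the image")
})

test_that("field tallies average the three post acquisitions", {
  mk <- function(n) tibble::tibble(roi = seq_len(n), onset_frame = 1,
                                   peak_df = 1)
  t1 <- tally_field(mk(4), list(mk(6), mk(8), mk(10)))
  expect_equal(t1$y_pre, 4)
  expect_equal(t1$y_post, 8)
  expect_equal(t1$delta, 4)
  expect_equal(tally_field(mk(0), list(mk(0), mk(0), mk(0)))$y_post, 0)
  expect_equal(tally_field(mk(2), list(mk(5), mk(5), mk(5)))$y_post, 5)
  expect_error(tally_field(mk(1), list(mk(1), mk(1))), "three")
})

test_that("normalized activity is 1 at the reference mean and affine in delta", {
  refs <- tibble::tibble(field = 1:4, delta = c(3, 7, 5, 9))  # mean 6
  test1 <- tibble::tibble(field = 9, delta = 6)
  expect_identical(normalize_activity(test1, refs)$y_norm, 1)
  expect_identical(normalize_activity(dplyr::mutate(test1, delta = 106),
                                      refs)$y_norm, 2)
  expect_identical(normalize_activity(dplyr::mutate(test1, delta = -94),
                                      refs)$y_norm, 0)

  # slope exactly 1/100 in delta; adding c to all references shifts by -c/100
  set.seed(42)
  for (i in 1:10) {
    refs_i <- tibble::tibble(delta = rnorm(5, sd = 10))
    d <- rnorm(1, sd = 10)
    y0 <- normalize_activity(tibble::tibble(delta = d), refs_i)$y_norm
    y1 <- normalize_activity(tibble::tibble(delta = d + 1), refs_i)$y_norm
    expect_equal(y1 - y0, 1 / 100, tolerance = 1e-12)
    cshift <- 17
    ys <- normalize_activity(tibble::tibble(delta = d),
                             dplyr::mutate(refs_i,
                                           delta = delta + cshift))$y_norm
    expect_equal(ys - y0, -cshift / 100, tolerance = 1e-12)
    # references normalized against themselves average to exactly 1
    yr <- normalize_activity(refs_i, refs_i)$y_norm
    expect_equal(mean(yr), 1, tolerance = 1e-12)
  }
  expect_error(normalize_activity(test1, refs[0, ]), "empty")
})

test_that("amplitude normalization is post over pre with missing handling", {
  pre <- tibble::tibble(roi = 1:3, amplitude = c(100, 100, 0))
  post <- tibble::tibble(roi = 1:3, amplitude = c(100, 150, 80))
  expect_warning(out <- normalize_amplitude(post, pre), "NA")
  expect_equal(out$ratio[1:2], c(1, 1.5))
  expect_true(is.na(out$ratio[3]))
})
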