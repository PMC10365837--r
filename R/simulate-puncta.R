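#' Simulate a two-channel puncta field with a controlled colocalized fraction
#'
#' A fraction `coloc_fraction` of puncta share centres across the two
#' channels (channel-2 copies are jittered by at most `jitter` px); the
#' remaining puncta of each channel are placed independently. Puncta are
#' Gaussian spots of width `punctum_sigma` on a flat background.
#'
#' @param n_puncta Puncta per channel.
#' @param coloc_fraction Fraction of shared centres, in `[0, 1]`.
#' @param punctum_sigma Spot width (s.d.), pixels.
#' @param field_size Image side, pixels.
#' @param amplitude Peak spot amplitude above background.
#' @param background Background level.
#' @param jitter Maximum per-axis displacement of the channel-2 copy of a
#'   shared punctum, pixels (`<= 1` keeps centres effectively shared).
#' @param min_separation Minimum centre-to-centre distance within a channel,
#'   pixels; placement warns (overcrowding) if it cannot be honoured.
#' @param noise_model,noise_sd,seed As in [transport_sim_config()].
#'
#' @return A list with `ch1`, `ch2` (matrices `[y, x]`) and `truth`, a tibble
#'   `(punctum, channel, x, y, shared, pair)` where `pair` links the two
#'   copies of a shared punctum.
#' @export
simulate_two_channel_puncta <- function(n_puncta = 60,
                                        coloc_fraction = 0.5,
                                        punctum_sigma = 1.5,
                                        field_size = 256,
                                        amplitude = 150,
                                        background = 50,
                                        jitter = 0.5,
                                        min_separation = 6,
                                        noise_model = "poisson",
                                        noise_sd = NULL,
                                        seed = 1L) {
  assert_prob(coloc_fraction, "coloc_fraction")
  set.seed(as.integer(seed))
  crowd <- n_puncta * pi * (4 * punctum_sigma)^2 / field_size^2
  if (crowd > 0.25)
    warnf("expected punctum overlap is high (area fraction %.2f): field is overcrowded",
          crowd)

  n_shared <- round(coloc_fraction * n_puncta)
  crowd_warned <- FALSE
  place <- function(n, existing = NULL) {
    out <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        p <- stats::runif(2L, 6, field_size - 5)
        all_prev <- rbind(existing, out[seq_len(i - 1L), , drop = FALSE])
        if (!is.null(all_prev) && nrow(all_prev) > 0 &&
            any((all_prev[, 1] - p[1])^2 + (all_prev[, 2] - p[2])^2 <
                min_separation^2)) next
        out[i, ] <- p; ok <- TRUE; break
      }
      if (!ok) {
        out[i, ] <- stats::runif(2L, 6, field_size - 5)
        if (!crowd_warned) {
          crowd_warned <<- TRUE
          warnf("could not honour min_separation while placing puncta (overcrowded field)")
        }
      }
    }
    out
  }

  shared <- place(n_shared)
  only1 <- place(n_puncta - n_shared, existing = shared)
  shared2 <- shared + matrix(stats::runif(2L * n_shared, -jitter, jitter),
                             ncol = 2L)
  only2 <- place(n_puncta - n_shared, existing = shared2)

  render <- function(centres) {
    img <- matrix(background, field_size, field_size)
    for (i in seq_len(nrow(centres)))
      img <- add_spot(img, centres[i, 1], centres[i, 2], amplitude,
                      punctum_sigma)
    apply_noise(img, noise_model, noise_sd)
  }

  truth <- dplyr::bind_rows(
    tibble::tibble(channel = 1L,
                   x = c(shared[, 1], only1[, 1]),
                   y = c(shared[, 2], only1[, 2]),
                   shared = rep(c(TRUE, FALSE), c(n_shared, n_puncta - n_shared)),
                   pair = c(seq_len(n_shared),
                            rep(NA_integer_, n_puncta - n_shared))),
    tibble::tibble(channel = 2L,
                   x = c(shared2[, 1], only2[, 1]),
                   y = c(shared2[, 2], only2[, 2]),
                   shared = rep(c(TRUE, FALSE), c(n_shared, n_puncta - n_shared)),
                   pair = c(seq_len(n_shared),
                            rep(NA_integer_, n_puncta - n_shared)))) |>
    dplyr::mutate(punctum = dplyr::row_number(), .before = 1L)

  list(ch1 = render(rbind(shared, only1)),
       ch2 = render(rbind(shared2, only2)),
       truth = truth)
}
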