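#' Simulate paired evoked EPSC sweeps at one interstimulus interval
#'
#' Each sweep is the sum of two inward (negative) biexponential synaptic
#' currents delivered at `t1` and `t1 + isi`, with peak magnitudes `a1` and
#' `a1 * ppr_true`, plus Gaussian current noise. Per-sweep input and series
#' resistances are recorded so the quality-control rule can be exercised; an
#' optional linear drift makes an experiment fail it.
#'
#' @param isi Interstimulus interval, ms (`> 0`). The protocol used ISIs of
#'   25, 50, 100, 250 and 500 ms.
#' @param a1 First EPSC peak amplitude, pA (`> 0`).
#' @param ppr_true True paired-pulse ratio (second/first amplitude).
#' @param rise_tau,decay_tau Biexponential time constants, ms.
#' @param noise_sd Gaussian noise s.d., pA.
#' @param n_sweeps Number of sweeps.
#' @param t1 Time of the first stimulus, ms.
#' @param sample_khz Sampling rate, kHz (10 kHz as acquired).
#' @param tail_ms Recording time kept after the second stimulus, ms.
#' @param rin,rs Baseline input/series resistance, MOhm.
#' @param resistance_drift Total fractional drift of both resistances across
#'   the sweep train (0 = stable; 0.25 = 25 percent, which must be rejected).
#' @param seed Integer seed.
#'
#' @return A tibble of class `axq_sweeps` with one row per sweep: `sweep`,
#'   `isi_ms`, `t1_ms`, `t2_ms`, `rin_mohm`, `rs_mohm`, `overlap` (TRUE when
#'   the first response has not decayed below 1 percent of `a1` at `t2`) and
#'   a list-column `trace` of tibbles `(time_ms, current_pa)`. Ground truth
#'   (`a1`, `a2`, `ppr_true`) is stored in the `truth` attribute.
#' @export
simulate_epsc_pair <- function(isi = 50,
                               a1 = 100,
                               ppr_true = 1.2,
                               rise_tau = 1,
                               decay_tau = 10,
                               noise_sd = 2,
                               n_sweeps = 20,
                               t1 = 20,
                               sample_khz = 10,
                               tail_ms = 80,
                               rin = 150,
                               rs = 15,
                               resistance_drift = 0,
                               seed = 1L) {
  if (isi <= 0) stopf("`isi` must be > 0")
  if (a1 <= 0) stopf("`a1` must be > 0")
  if (rise_tau >= decay_tau) stopf("`rise_tau` must be < `decay_tau`")
  set.seed(as.integer(seed))

  t2 <- t1 + isi
  t_end <- t2 + tail_ms
  time_ms <- seq(0, t_end, by = 1 / sample_khz)
  # Unit-peak biexponential kernel.
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  norm <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  kernel <- function(t) {
    out <- numeric(length(t))
    pos <- t >= 0
    out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / norm
    out
  }
  residual_at_t2 <- a1 * kernel(isi)
  overlap <- residual_at_t2 > 0.01 * a1

  a2 <- a1 * ppr_true
  clean <- -(a1 * kernel(time_ms - t1) + a2 * kernel(time_ms - t2))
  drift <- if (n_sweeps > 1)
    seq(0, resistance_drift, length.out = n_sweeps) else 0

  sweeps <- purrr::map_dfr(seq_len(n_sweeps), function(s) {
    trace <- clean + if (noise_sd > 0)
      stats::rnorm(length(time_ms), sd = noise_sd) else 0
    tibble::tibble(
      sweep = s, isi_ms = isi, t1_ms = t1, t2_ms = t2,
      rin_mohm = rin * (1 + drift[min(s, length(drift))]),
      rs_mohm = rs * (1 + drift[min(s, length(drift))]),
      overlap = overlap,
      trace = list(tibble::tibble(time_ms = time_ms, current_pa = trace)))
  })
  attr(sweeps, "truth") <- tibble::tibble(a1 = a1, a2 = a2,
                                          ppr_true = ppr_true,
                                          residual_at_t2 = residual_at_t2)
  class(sweeps) <- c("axq_sweeps", class(sweeps))
  sweeps
}
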