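#' Measure paired EPSC amplitudes on one sweep
#'
#' EPSCs are inward (negative) deflections; each amplitude is the magnitude
#' of the extremum within `peak_window` ms after the stimulus relative to a
#' local baseline. The first baseline is the mean current over
#' `baseline_window` ms before the first stimulus; for the second response
#' the baseline is taken immediately before the second stimulus (over
#' `local_baseline_ms`), which compensates the residual decay of the first
#' response at short interstimulus intervals. An optional exponential
#' decay-subtraction mode removes the extrapolated first response instead.
#'
#' @param trace Tibble `(time_ms, current_pa)`.
#' @param t1,t2 Stimulus times, ms.
#' @param baseline_window Pre-stimulus-1 baseline length, ms.
#' @param peak_window Post-stimulus search window, ms.
#' @param local_baseline_ms Length of the pre-stimulus-2 local baseline, ms.
#' @param subtract_decay If `TRUE`, fit a single exponential to the tail of
#'   the first response (from its peak to `t2`) and subtract its
#'   extrapolation before measuring the second amplitude.
#' @return One-row tibble `(a1_pa, a2_pa)`.
#' @export
measure_amplitude <- function(trace, t1, t2,
                              baseline_window = 5,
                              peak_window = 15,
                              local_baseline_ms = 0.5,
                              subtract_decay = FALSE) {
  tm <- trace$time_ms; cur <- trace$current_pa
  if (t2 + peak_window > max(tm))
    stopf("peak window after the second stimulus is truncated by the trace end")
  b1_idx <- tm >= (t1 - baseline_window) & tm < t1
  if (!any(b1_idx)) stopf("baseline window lies outside the trace")
  b1 <- mean(cur[b1_idx])
  w1 <- tm >= t1 & tm <= min(t1 + peak_window, t2)
  a1 <- abs(min(cur[w1]) - b1)

  if (subtract_decay) {
    pk1 <- which.min(cur * (tm >= t1 & tm <= t2))
    fit_idx <- which(tm > tm[pk1] + 1 & tm < t2)
    y <- b1 - cur[fit_idx]                       # positive decaying tail
    usable <- y > 0
    if (sum(usable) > 5L) {
      ft <- tm[fit_idx][usable]; fy <- log(y[usable])
      co <- stats::coef(stats::lm(fy ~ ft))
      decay <- exp(co[1] + co[2] * tm)
      cur2 <- cur + decay                        # remove first-response tail
      w2 <- tm >= t2 & tm <= t2 + peak_window
      a2 <- abs(min(cur2[w2]) - b1)
      return(tibble::tibble(a1_pa = a1, a2_pa = a2))
    }
  }
  b2_idx <- tm >= (t2 - local_baseline_ms) & tm < t2
  b2 <- mean(cur[b2_idx])
  w2 <- tm >= t2 & tm <= t2 + peak_window
  a2 <- abs(min(cur[w2]) - b2)
  tibble::tibble(a1_pa = a1, a2_pa = a2)
}

#' Resistance-stability quality control of a sweep train
#'
#' For each resistance type the relative variation is
#' `(max - min) / first-sweep value`; the whole experiment (cell) is rejected
#' when either input or series resistance varies by strictly more than
#' `max_variation` (20 percent by convention; exactly 20 percent is
#' accepted).
#'
#' @param sweeps An `axq_sweeps` tibble (or any tibble with `rin_mohm` and
#'   `rs_mohm` columns).
#' @param max_variation Maximum tolerated fractional variation.
#' @return List `(accepted, rin_variation, rs_variation, reason)`;
#'   `accepted` is `NA` when resistance metadata are missing.
#' @export
qc_filter <- function(sweeps, max_variation = 0.2) {
  if (!all(c("rin_mohm", "rs_mohm") %in% names(sweeps)) ||
      anyNA(sweeps$rin_mohm) || anyNA(sweeps$rs_mohm)) {
    warnf("missing resistance metadata: experiment cannot be quality-controlled")
    return(list(accepted = NA, rin_variation = NA_real_,
                rs_variation = NA_real_, reason = "missing metadata"))
  }
  variation <- function(x) (max(x) - min(x)) / x[1L]
  vin <- variation(sweeps$rin_mohm)
  vs <- variation(sweeps$rs_mohm)
  rejected <- vin > max_variation || vs > max_variation
  list(accepted = !rejected, rin_variation = vin, rs_variation = vs,
       reason = if (rejected) "resistance variation above threshold" else "ok")
}

#' Paired-pulse ratio over a sweep train at one interstimulus interval
#'
#' Each of the (typically 20) sweeps is measured individually with
#' [measure_amplitude()] and the per-sweep ratios `A2 / A1` are averaged
#' (mean of ratios); the ratio of mean amplitudes is also reported for
#' comparison — the two agree in the noise-free limit. The experiment is
#' first quality-controlled with [qc_filter()]; a rejected experiment yields
#' no ratio.
#'
#' @param sweeps An `axq_sweeps` tibble from [simulate_epsc_pair()] or built
#'   from recordings (columns `sweep`, `isi_ms`, `t1_ms`, `t2_ms`,
#'   `rin_mohm`, `rs_mohm`, list-column `trace`).
#' @param apply_qc Run the resistance QC before averaging.
#' @inheritParams measure_amplitude
#' @return One-row tibble of class `axq_ppr`: `isi_ms`, `n_sweeps`,
#'   `n_accepted`, `mean_a1_pa`, `mean_a2_pa`, `ppr_mean_of_ratios`,
#'   `ppr_ratio_of_means`, `qc_accepted`. The per-sweep table is attached as
#'   attribute `per_sweep`.
#' @export
compute_ppr <- function(sweeps, apply_qc = TRUE,
                        baseline_window = 5, peak_window = 15,
                        local_baseline_ms = 0.5, subtract_decay = FALSE) {
  sweeps <- tibble::as_tibble(sweeps)
  if (nrow(sweeps) == 0L) stopf("no sweeps supplied")
  qc <- if (apply_qc) qc_filter(sweeps) else
    list(accepted = TRUE, reason = "qc skipped")
  if (isFALSE(qc$accepted))
    stopf("experiment rejected by quality control (%s)", qc$reason)

  per <- purrr::map_dfr(seq_len(nrow(sweeps)), function(i) {
    amp <- measure_amplitude(sweeps$trace[[i]], sweeps$t1_ms[i],
                             sweeps$t2_ms[i], baseline_window, peak_window,
                             local_baseline_ms, subtract_decay)
    dplyr::mutate(amp, sweep = sweeps$sweep[i],
                  ppr = .data$a2_pa / .data$a1_pa, .before = 1L)
  })
  ok <- per$a1_pa > 0
  if (!any(ok)) stopf("no accepted sweeps with measurable first response")
  out <- tibble::tibble(
    isi_ms = sweeps$isi_ms[1L],
    n_sweeps = nrow(sweeps),
    n_accepted = sum(ok),
    mean_a1_pa = mean(per$a1_pa[ok]),
    mean_a2_pa = mean(per$a2_pa[ok]),
    ppr_mean_of_ratios = mean(per$ppr[ok]),
    ppr_ratio_of_means = mean(per$a2_pa[ok]) / mean(per$a1_pa[ok]),
    qc_accepted = isTRUE(qc$accepted))
  attr(out, "per_sweep") <- per
  class(out) <- c("axq_ppr", class(out))
  out
}
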