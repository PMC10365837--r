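#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the post hoc table of a statistical report
#'
#' @param x An `axq_stats_report`.
#' @param ... Unused.
#' @return Tibble of post hoc contrasts, or the main test as a single row
#'   when the design has no post hoc.
#' @method tidy axq_stats_report
#' @export
tidy.axq_stats_report <- function(x, ...) {
  if (!is.null(x$posthoc)) return(tibble::as_tibble(x$posthoc))
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value, stars = x$stars)
}

#' One-row summary of a statistical report
#'
#' @param x An `axq_stats_report`.
#' @param ... Unused.
#' @return One-row tibble with the design, branch, chosen test, statistic,
#'   p-value and star label.
#' @method glance axq_stats_report
#' @export
glance.axq_stats_report <- function(x, ...) {
  tibble::tibble(design = x$design, branch = x$branch, test = x$test,
                 statistic = x$statistic, p_value = x$p_value,
                 stars = x$stars)
}

#' Per-observation ROUT diagnostics
#'
#' @param x An `axq_rout` object.
#' @param ... Unused.
#' @return Tibble `(value, resid, t, p, outlier)`.
#' @method tidy axq_rout
#' @export
tidy.axq_rout <- function(x, ...) x$data

#' One-row summary of a ROUT fit
#'
#' @param x An `axq_rout` object.
#' @param ... Unused.
#' @return One-row tibble with the robust location, RSDR, Q and the number
#'   of flagged outliers.
#' @method glance axq_rout
#' @export
glance.axq_rout <- function(x, ...) {
  tibble::tibble(location = x$location, rsdr = x$rsdr, Q = x$Q,
                 n = nrow(x$data), n_outliers = sum(x$data$outlier))
}
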