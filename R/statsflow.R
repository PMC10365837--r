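#' ROUT outlier identification (robust fit + FDR)
#'
#' Identifies outliers in a single sample the way the ROUT procedure does for
#' the degenerate constant-location model: a robust location is fitted by
#' iteratively reweighted least squares with Lorentzian weights
#' `1 / (1 + (r / RSDR)^2)`, the robust scale (RSDR) is the 68.27th
#' percentile of the absolute residuals inflated by `n / (n - 1)`, residuals
#' are converted to t-like scores `|r| / RSDR` with `n - 1` degrees of
#' freedom, and outliers are flagged by a Benjamini-Hochberg step-up on the
#' two-sided tail probabilities at false-discovery rate `Q` percent.
#'
#' @param values Numeric vector (`n >= 3` for any removal to happen).
#' @param Q Target false-discovery rate, percent (default 1).
#' @return List of class `axq_rout`: `data` tibble `(value, resid, t, p,
#'   outlier)`, `clean` (values kept), `outliers` (values removed),
#'   `location`, `rsdr`, `Q`.
#' @export
rout_outliers <- function(values, Q = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) {
    warnf("ROUT needs n >= 3; no outliers removed")
    return(structure(list(
      data = tibble::tibble(value = values, resid = NA_real_, t = NA_real_,
                            p = NA_real_, outlier = FALSE),
      clean = values, outliers = numeric(0),
      location = stats::median(values), rsdr = NA_real_, Q = Q),
      class = "axq_rout"))
  }
  mu <- stats::median(values)
  rsdr <- 0
  for (iter in seq_len(100L)) {
    r <- values - mu
    rsdr <- unname(stats::quantile(abs(r), 0.6827, type = 7)) * n / (n - 1)
    if (rsdr <= 0) break
    w <- 1 / (1 + (r / rsdr)^2)
    mu_new <- sum(w * values) / sum(w)
    if (abs(mu_new - mu) < 1e-12 * max(1, rsdr)) { mu <- mu_new; break }
    mu <- mu_new
  }
  r <- values - mu
  if (rsdr <= 0) {
    # Majority of points identical: any nonzero residual is infinitely
    # surprising; constant data flags nothing.
    out <- abs(r) > 0
    tval <- ifelse(out, Inf, 0)
    pval <- ifelse(out, 0, 1)
  } else {
    tval <- abs(r) / rsdr
    pval <- 2 * stats::pt(-tval, df = n - 1)
    # Benjamini-Hochberg step-up at rate Q% on the ordered p-values.
    ord <- order(pval)
    thresh <- (Q / 100) * seq_len(n) / n
    passed <- which(pval[ord] <= thresh)
    out <- rep(FALSE, n)
    if (length(passed)) out[ord[seq_len(max(passed))]] <- TRUE
  }
  structure(list(
    data = tibble::tibble(value = values, resid = r, t = tval, p = pval,
                          outlier = out),
    clean = values[!out], outliers = values[out],
    location = mu, rsdr = rsdr, Q = Q), class = "axq_rout")
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test per group at threshold `alpha`; the workflow
#' proceeds parametrically only if every group passes. Degenerate groups
#' (all values identical) cannot be tested and force the non-parametric
#' branch with a warning.
#'
#' @param data Data frame with columns `value` and `group`.
#' @param alpha Normality threshold (default 0.05).
#' @return List `(branch, per_group)` where `branch` is `"parametric"` or
#'   `"nonparametric"` and `per_group` is a tibble `(group, n, W, p,
#'   normal)`.
#' @export
normality_gate <- function(data, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  per_group <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < 3L || n > 5000L)
        stopf("Shapiro-Wilk supports 3 <= n <= 5000 (group '%s' has n = %d)",
              key$group, n)
      if (stats::sd(g$value) == 0) {
        warnf("group '%s' is degenerate (identical values): treated as non-normal",
              key$group)
        return(tibble::tibble(group = key$group, n = n, W = NA_real_,
                              p = NA_real_, normal = FALSE))
      }
      sw <- stats::shapiro.test(g$value)
      tibble::tibble(group = key$group, n = n, W = unname(sw$statistic),
                     p = sw$p.value, normal = sw$p.value >= alpha)
    }) |>
    dplyr::bind_rows()
  list(branch = if (all(per_group$normal)) "parametric" else "nonparametric",
       per_group = per_group)
}

#' Significance stars
#'
#' `*` p<0.05, `**` p<0.01, `***` p<0.001, `****` p<0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns")
}

# Dunn's rank-based post hoc for a Kruskal-Wallis design.
dunn_posthoc <- function(value, group, adjust = "bonferroni") {
  group <- factor(group)
  N <- length(value)
  rk <- rank(value)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, group, mean)
  ni <- tapply(rk, group, length)
  lev <- levels(group)
  combs <- utils::combn(lev, 2L)
  res <- purrr::map_dfr(seq_len(ncol(combs)), function(c_) {
    g1 <- combs[1, c_]; g2 <- combs[2, c_]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni[g1] + 1 / ni[g2]))
    z <- (rbar[g1] - rbar[g2]) / se
    tibble::tibble(contrast = paste(g1, "-", g2), z = unname(z),
                   p = 2 * stats::pnorm(-abs(unname(z))))
  })
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$stars <- p_stars(res$p_adj)
  res
}

#' Run the test-selection workflow on a group table
#'
#' Applies the decision tree given the design and branch:
#' * `two_groups`: t-test (equal variances) or Mann-Whitney;
#' * `multi_group`: one-way ANOVA + Tukey post hoc, or Kruskal-Wallis +
#'   Dunn's post hoc;
#' * `two_factor` (interdependent datasets): two-way ANOVA with interaction,
#'   followed by Tukey-adjusted pairwise comparisons when more than two
#'   groups are present or Sidak-adjusted comparisons for two groups; the
#'   branch argument is ignored for this design (with a warning when
#'   non-parametric was requested).
#'
#' @param data Data frame with `value`, `group` and (for `two_factor`)
#'   `factor2` columns.
#' @param design `"two_groups"`, `"multi_group"` or `"two_factor"`.
#' @param branch `"parametric"` or `"nonparametric"` (from
#'   [normality_gate()]).
#' @return List of class `axq_stats_report`: `design`, `branch`, `test`,
#'   `statistic`, `p_value`, `stars`, `posthoc` (tibble or `NULL`),
#'   `normality`, `outlier_removal`.
#' @export
select_and_run <- function(data, design, branch) {
  data <- tibble::as_tibble(data)
  design <- match.arg(design, c("two_groups", "multi_group", "two_factor"))
  branch <- match.arg(branch, c("parametric", "nonparametric"))
  data$group <- factor(data$group)
  k <- nlevels(data$group)
  if (design == "two_groups" && k != 2L)
    stopf("design 'two_groups' requires exactly 2 groups (found %d)", k)
  if (design == "multi_group" && k < 3L)
    stopf("design 'multi_group' requires > 2 groups (found %d)", k)
  if (design == "two_factor" && !"factor2" %in% names(data))
    stopf("design 'two_factor' requires a `factor2` column")

  posthoc <- NULL
  if (design == "two_groups") {
    if (branch == "parametric") {
      ht <- stats::t.test(value ~ group, data = data, var.equal = TRUE)
      test <- "t-test"
    } else {
      ht <- stats::wilcox.test(value ~ group, data = data, exact = FALSE)
      test <- "Mann-Whitney"
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else if (design == "multi_group") {
    if (branch == "parametric") {
      fit <- stats::aov(value ~ group, data = data)
      an <- summary(fit)[[1]]
      statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      test <- "one-way ANOVA"
      tk <- stats::TukeyHSD(fit)$group
      posthoc <- tibble::tibble(contrast = rownames(tk),
                                diff = tk[, "diff"], p_adj = tk[, "p adj"],
                                stars = p_stars(tk[, "p adj"]))
    } else {
      ht <- stats::kruskal.test(value ~ group, data = data)
      statistic <- unname(ht$statistic); p <- ht$p.value
      test <- "Kruskal-Wallis"
      posthoc <- dunn_posthoc(data$value, data$group)
    }
  } else {
    if (branch == "nonparametric")
      warnf("two-factor designs are analysed by two-way ANOVA; non-parametric branch ignored")
    data$factor2 <- factor(data$factor2)
    fit <- stats::aov(value ~ group * factor2, data = data)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
    test <- "two-way ANOVA"
    adj <- if (k > 2L) "tukey" else "sidak"
    em <- emmeans::emmeans(fit, ~ group | factor2)
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = adj))
    posthoc <- tibble::tibble(
      contrast = paste(pr$contrast, "|", pr$factor2),
      estimate = pr$estimate, p_adj = pr$p.value,
      stars = p_stars(pr$p.value))
    attr(posthoc, "adjust") <- adj
  }
  structure(list(design = design, branch = branch, test = test,
                 statistic = statistic, p_value = p, stars = p_stars(p),
                 posthoc = posthoc, normality = NULL,
                 outlier_removal = NULL),
            class = "axq_stats_report")
}

#' Full statistical decision workflow
#'
#' The complete analysis path applied to every dataset: ROUT outlier removal
#' at `Q` percent per group, Shapiro-Wilk normality gate at `alpha`, then the
#' design-appropriate test and post hoc via [select_and_run()].
#'
#' @inheritParams select_and_run
#' @param Q ROUT false-discovery rate, percent.
#' @param alpha Normality threshold.
#' @return An `axq_stats_report` whose `normality` and `outlier_removal`
#'   fields record the intermediate verdicts.
#' @export
stats_workflow <- function(data, design, Q = 1, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  cleaned <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(g, key) {
      r <- rout_outliers(g$value, Q = Q)
      g$outlier <- r$data$outlier
      g$group <- key$group
      g
    }) |>
    dplyr::bind_rows()
  removed <- dplyr::filter(cleaned, .data$outlier)
  kept <- dplyr::filter(cleaned, !.data$outlier)
  gate <- normality_gate(kept, alpha = alpha)
  report <- select_and_run(kept, design, gate$branch)
  report$normality <- gate$per_group
  report$outlier_removal <- dplyr::count(removed, .data$group,
                                         name = "n_removed")
  report
}

#' @export
print.axq_stats_report <- function(x, ...) {
  cat(sprintf("Statistical report (%s, %s branch)\n", x$design, x$branch))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p_value, x$stars))
  if (!is.null(x$posthoc)) {
    cat("  Post hoc:\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}
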