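test_that("ROUT flags gross outliers and spares clean or constant data", {
  set.seed(1)
  for (s in 1:5) {
    y <- c(rnorm(100), 10)
    r <- rout_outliers(y)
    expect_true(r$data$outlier[101])
  }
  r_const <- rout_outliers(rep(3.2, 30))
  expect_equal(sum(r_const$data$outlier), 0)
  expect_warning(rout_outliers(c(1, 2)), "n >= 3")

  # false-flag rate on clean Gaussian samples stays near the target FDR
  set.seed(2)
  frac <- vapply(1:200, function(i) {
    r <- rout_outliers(rnorm(50))
    mean(r$data$outlier)
  }, numeric(1))
  expect_lte(mean(frac), 0.02)
})

test_that("ROUT flags are location/scale equivariant", {
  set.seed(3)
  y <- c(rnorm(40), 6, -7)
  base <- rout_outliers(y)$data$outlier
  expect_identical(rout_outliers(3.7 * y + 11)$data$outlier, base)
  expect_identical(rout_outliers(0.01 * y - 5)$data$outlier, base)
})

test_that("normality gate separates Gaussian from lognormal groups", {
  set.seed(4)
  gauss <- tibble::tibble(value = rnorm(200),
                          group = rep(c("a", "b"), each = 100))
  expect_equal(normality_gate(gauss)$branch, "parametric")

  skew <- tibble::tibble(value = c(rnorm(100), exp(rnorm(100, sd = 1))),
                         group = rep(c("a", "b"), each = 100))
  g <- normality_gate(skew)
  expect_equal(g$branch, "nonparametric")
  expect_false(g$per_group$normal[g$per_group$group == "b"])

  degen <- tibble::tibble(value = rep(1, 3), group = "a")
  expect_warning(gd <- normality_gate(degen), "degenerate")
  expect_equal(gd$branch, "nonparametric")
  expect_error(normality_gate(tibble::tibble(value = 1:2, group = "a")),
               "3 <= n")
})

test_that("the decision table picks the paper's test for every design", {
  set.seed(5)
  two <- tibble::tibble(value = rnorm(40), group = rep(c("a", "b"), 20))
  expect_equal(select_and_run(two, "two_groups", "parametric")$test,
               "t-test")
  expect_equal(select_and_run(two, "two_groups", "nonparametric")$test,
               "Mann-Whitney")

  multi <- tibble::tibble(value = rnorm(60),
                          group = rep(c("a", "b", "c"), 20))
  par3 <- select_and_run(multi, "multi_group", "parametric")
  expect_equal(par3$test, "one-way ANOVA")
  expect_equal(nrow(par3$posthoc), 3)
  np3 <- select_and_run(multi, "multi_group", "nonparametric")
  expect_equal(np3$test, "Kruskal-Wallis")
  expect_equal(nrow(np3$posthoc), 3)

  tf2 <- tibble::tibble(value = rnorm(40), group = rep(c("a", "b"), 20),
                        factor2 = rep(c("x", "y"), each = 20))
  r2 <- select_and_run(tf2, "two_factor", "parametric")
  expect_equal(r2$test, "two-way ANOVA")
  expect_equal(attr(r2$posthoc, "adjust"), "sidak")
  tf3 <- tibble::tibble(value = rnorm(60),
                        group = rep(c("a", "b", "c"), 20),
                        factor2 = rep(c("x", "y"), each = 30))
  expect_equal(attr(select_and_run(tf3, "two_factor",
                                   "parametric")$posthoc, "adjust"),
               "tukey")

  expect_error(select_and_run(multi, "two_groups", "parametric"),
               "exactly 2 groups")
  expect_error(select_and_run(two, "two_factor", "parametric"), "factor2")

  # identical groups -> clearly non-significant
  same <- tibble::tibble(value = rep(c(1.1, 2.3, 0.4, 1.8, 0.9), 2),
                         group = rep(c("a", "b"), each = 5))
  rs <- select_and_run(same, "two_groups", "parametric")
  expect_gt(rs$p_value, 0.9)
  expect_equal(rs$stars, "ns")
})

test_that("Dunn's post hoc matches a hand-computed example", {
  # groups (1,2), (3,4), (5,6): mean ranks 1.5, 3.5, 5.5; no ties
  d <- axonquant:::dunn_posthoc(1:6, rep(c("a", "b", "c"), each = 2))
  se <- sqrt((6 * 7 / 12) * (1 / 2 + 1 / 2))
  expect_equal(d$z[d$contrast == "a - b"], -2 / se, tolerance = 1e-12)
  expect_equal(d$z[d$contrast == "a - c"], -4 / se, tolerance = 1e-12)
  expect_equal(d$p, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)
  expect_equal(d$p_adj, pmin(1, d$p * 3), tolerance = 1e-12)
})

test_that("significance stars follow the printed convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the full workflow controls type-I error near alpha", {
  set.seed(6)
  rej <- vapply(1:300, function(i) {
    d <- tibble::tibble(value = rnorm(30), group = rep(c("a", "b"), 15))
    suppressWarnings(stats_workflow(d, "two_groups")$p_value) < 0.05
  }, logical(1))
  # slightly conservative after outlier removal is acceptable
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("tidy and glance methods expose the report", {
  set.seed(7)
  d <- tibble::tibble(value = rnorm(60), group = rep(c("a", "b", "c"), 20))
  rep <- stats_workflow(d, "multi_group")
  expect_s3_class(generics::tidy(rep), "tbl_df")
  g <- generics::glance(rep)
  expect_equal(nrow(g), 1)
  expect_true(all(c("design", "branch", "test", "p_value") %in% names(g)))
  r <- rout_outliers(c(rnorm(20), 9))
  expect_equal(nrow(generics::tidy(r)), 21)
  expect_equal(generics::glance(r)$n, 21)
})
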