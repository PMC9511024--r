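# enumeration oracle for the exact two-sided rank-sum p-value
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  u_obs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(n, m)
  r <- rank(pooled)
  us <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  mu <- m * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("exact rank-sum p-values match full enumeration", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1)  # 2 of 20 splits
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- rnorm(sample(3:6, 1))
      b <- rnorm(sample(3:6, 1))
      w <- wilcoxon_rank_sum(a, b)
      expect_true(w$exact)
      expect_equal(w$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-9)
      # and matches the reference implementation
      expect_equal(w$p_value, wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum is symmetric and handles ties and identical samples", {
  withr::with_seed(22, {
    a <- rnorm(8)
    b <- rnorm(9)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcoxon_rank_sum(b, a)$p_value, tolerance = 1e-12)
  })
  same <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(same, same)$p_value, 1)
  expect_error(wilcoxon_rank_sum(1, 1:3), "at least 2")
})

test_that("the large-sample approximation tracks the exact distribution", {
  withr::with_seed(23, {
    worst <- 0
    for (i in 1:50) {
      a <- rnorm(6)
      b <- rnorm(6)
      pe <- wilcoxon_rank_sum(a, b, method = "exact")$p_value
      pn <- wilcoxon_rank_sum(a, b, method = "normal")$p_value
      worst <- max(worst, abs(pe - pn))
    }
    expect_lt(worst, 0.01)
  })
})

test_that("ordered group test detects a planted monotone trend", {
  cfg <- tiny_config(n_per_group = c("healthy-control" = 30, "no-RT" = 30,
                                     "focal" = 30, "WBRT-high-dose" = 30),
                     seed = 61)
  rec <- simulate_cohort(cfg, timeseries = FALSE)$records
  og <- ordered_group_test(rec, "planted_scale", cfg$group_labels)
  expect_gt(og$trend$rho, 0)
  expect_lt(og$trend$p_value, 0.001)
  expect_equal(nrow(og$pairwise), 3)
})

test_that("trend p-values are uniform under permuted group labels", {
  withr::with_seed(62, {
    n <- 120
    groups <- rep(c("a", "b", "c", "d"), each = 30)
    ps <- vapply(1:200, function(i) {
      tbl <- data.frame(group = sample(groups), y = rnorm(n))
      ordered_group_test(tbl, "y", c("a", "b", "c", "d"))$trend$p_value
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  })
})

test_that("identical groups give a near-unity pairwise p", {
  tbl <- data.frame(group = rep(c("a", "b"), each = 6),
                    y = rep(c(1, 2, 3, 4, 5, 6), 2))
  og <- suppressWarnings(ordered_group_test(tbl, "y", c("a", "b")))
  expect_gte(og$pairwise$p_value[1], 0.9)
})

test_that("metric-memory correlation handles perfect, calibrated and degenerate input", {
  tbl <- data.frame(m = 1:10, isl_zscore = 2 * (1:10) - 3,
                    age_at_imaging = rep(1, 10))
  expect_equal(metric_memory_correlation(tbl, "m")$R, 1)
  expect_error(metric_memory_correlation(
    data.frame(m = rep(1, 5), isl_zscore = rnorm(5),
               age_at_imaging = rep(1, 5)), "m"), "zero variance")
  cfg <- tiny_config(n_per_group = c("healthy-control" = 50, "no-RT" = 50,
                                     "focal" = 50, "WBRT-high-dose" = 50),
                     seed = 63)
  rec <- simulate_cohort(cfg, timeseries = FALSE)$records
  res <- metric_memory_correlation(rec, "planted_composite",
                                   age_normalize = FALSE)
  expect_gte(res$R, 0.38)
  expect_lte(res$R, 0.60)
})

test_that("correlation test type-I error is calibrated at nominal alpha", {
  withr::with_seed(64, {
    hits <- vapply(1:500, function(i) {
      tbl <- data.frame(m = rnorm(200), isl_zscore = rnorm(200),
                        age_at_imaging = runif(200, 12, 25))
      metric_memory_correlation(tbl, "m",
                                age_normalize = FALSE)$p_value < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.03)
    expect_lte(mean(hits), 0.07)
  })
})

test_that("microbleed bin analysis recovers an exact quadratic", {
  cmb <- seq(0, 100, by = 2)
  tbl <- data.frame(cmb_count = cmb, m = -(cmb - 50)^2 + 7)
  res <- suppressWarnings(cmb_bin_analysis(tbl, "m", log_scale = FALSE))
  expect_equal(res$quadratic$curvature_sign, -1)
  expect_equal(res$quadratic$vertex, 50, tolerance = 1e-6)
  expect_equal(nrow(res$bin_means), 3)
  expect_error(cmb_bin_analysis(
    data.frame(cmb_count = NA_integer_, m = 1), "m"), "missing")
})

test_that("a linear burden-metric relation shows no spurious curvature", {
  withr::with_seed(65, {
    cmb <- sample(0:205, 200, replace = TRUE)
    tbl <- data.frame(cmb_count = cmb, m = 0.01 * cmb + rnorm(200))
    res <- cmb_bin_analysis(tbl, "m", log_scale = FALSE)
    ci <- res$quadratic$quad_ci
    expect_lte(ci[1], 0)
    expect_gte(ci[2], 0)
  })
})

test_that("planted parabolic burden link makes the moderate bin highest", {
  hits <- vapply(1:50, function(s) {
    cfg <- tiny_config(n_per_group = c("healthy-control" = 5, "no-RT" = 40,
                                       "focal" = 40, "WBRT-high-dose" = 40),
                       seed = 700 + s)
    rec <- simulate_cohort(cfg, timeseries = FALSE)$records
    pat <- rec[rec$group != "healthy-control", ]
    # compare the planted amplitude relative to its group baseline, which is
    # what the burden parabola modulates
    pat$rel <- pat$planted_scale /
      cfg$group_variability_scale[as.character(pat$group)]
    res <- cmb_bin_analysis(pat, "rel")
    mm <- res$bin_means$mean
    res$quadratic$curvature_sign == -1 && mm[2] > mm[1] && mm[2] > mm[3]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("risk-factor regression recovers coefficients and rejects collinearity", {
  withr::with_seed(66, {
    n <- 60
    tbl <- data.frame(age_at_rt = runif(n, 3, 20),
                      time_since_rt = runif(n, 1, 15))
    tbl$y <- 2 * tbl$age_at_rt + rnorm(n, sd = 1e-8)
    res <- risk_factor_regression(tbl, "y")
    est <- unname(res$estimate[res$term == "age_at_rt"])
    expect_equal(est, 2, tolerance = 1e-6)
    width <- with(res[res$term == "age_at_rt", ], ci_high - ci_low)
    expect_lt(width, 1e-6)
    tbl$dup <- tbl$age_at_rt
    expect_error(risk_factor_regression(tbl, "y",
                                        predictors = c("age_at_rt", "dup")),
                 "collinear")
  })
})

test_that("regression CIs cover planted coefficients at the nominal rate", {
  withr::with_seed(67, {
    cover <- matrix(FALSE, 200, 2)
    for (i in 1:200) {
      n <- 100
      tbl <- data.frame(age_at_rt = runif(n, 3, 20),
                        time_since_rt = runif(n, 1, 15))
      tbl$y <- 0.05 - 0.001 * tbl$age_at_rt - 0.001 * tbl$time_since_rt +
        rnorm(n, sd = 0.01)
      res <- risk_factor_regression(tbl, "y")
      cover[i, ] <- res$ci_low[-1] <= -0.001 & res$ci_high[-1] >= -0.001
    }
    expect_gte(mean(cover[, 1]), 0.93)
    expect_gte(mean(cover[, 2]), 0.93)
  })
})

test_that("regression residuals are orthogonal to the design", {
  withr::with_seed(68, {
    n <- 50
    tbl <- data.frame(age_at_rt = runif(n, 3, 20),
                      time_since_rt = runif(n, 1, 15))
    tbl$y <- 1 + 0.2 * tbl$age_at_rt + rnorm(n)
    fit <- lm(y ~ age_at_rt + time_since_rt, data = tbl)
    X <- model.matrix(fit)
    r <- resid(fit)
    dots <- abs(crossprod(X, r)) /
      (sqrt(colSums(X^2)) * sqrt(sum(r^2)))
    expect_lt(max(dots), 1e-6)
  })
})

test_that("metric tables join covariates, metrics and age-normalized columns", {
  rec <- tibble::tibble(subject_id = c("s1", "s2"),
                        group = factor(c("healthy-control", "no-RT")),
                        age_at_imaging = c(20, 10), isl_zscore = c(0, 1),
                        age_at_rt = c(NA, NA), time_since_rt = c(NA, NA),
                        cmb_count = c(0L, 3L))
  gm <- tibble::tibble(subject_id = c("s1", "s2"), modularity = c(0.5, 0.4),
                       efficiency = c(0.6, 0.8), n_edges = c(10L, 12L),
                       n_communities = c(3L, 2L))
  vt <- tibble::tibble(subject_id = c("s1", "s1", "s2", "s2"),
                       network = c("SN", "L-DAN", "SN", "L-DAN"),
                       component = c(1L, 2L, 1L, 2L),
                       variability = c(1, 2, 3, 4))
  mt <- build_metric_table(rec, gm, vt)
  expect_equal(mt$var_SN, c(1, 3))
  expect_equal(mt$var_L_DAN, c(2, 4))
  expect_equal(mt$modularity_agenorm, c(0.5 / 20, 0.4 / 10))
  expect_equal(mt$var_SN_agenorm, c(1 / 20, 3 / 10))
})
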