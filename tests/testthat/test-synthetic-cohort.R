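test_that("target covariance is a block matrix with the configured levels", {
  cfg <- cohort_config(
    n_per_group = c("healthy-control" = 2, "WBRT-high-dose" = 2),
    group_connectivity_offset = c("healthy-control" = 0,
                                  "WBRT-high-dose" = 0.2),
    group_variability_scale = c("healthy-control" = 1,
                                "WBRT-high-dose" = 1.5),
    n_parcels = 6, n_modules = 2,
    within_module_r = 0.6, between_module_r = 0.1)
  s <- build_target_covariance(cfg, "healthy-control")
  expect_equal(diag(s), rep(1, 6))
  same <- outer(cfg$module_assignment, cfg$module_assignment, "==")
  diag(same) <- NA
  expect_true(all(s[which(same)] == 0.6))
  expect_true(all(s[which(!same)] == 0.1))
  # additive group offset on the between-module entries
  s2 <- build_target_covariance(cfg, "WBRT-high-dose")
  expect_true(all(abs(s2[which(!same)] - 0.3) < 1e-12))
  expect_true(all(s2[which(same)] == 0.6))
})

test_that("4-parcel 2-module covariance is strictly PD by eigen oracle", {
  cfg <- cohort_config(
    n_per_group = c("healthy-control" = 1),
    group_connectivity_offset = c("healthy-control" = 0),
    group_variability_scale = c("healthy-control" = 1),
    n_parcels = 4, n_modules = 2,
    within_module_r = 0.6, between_module_r = 0.1)
  s <- build_target_covariance(cfg, "healthy-control")
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("nearest-PSD repair yields a valid correlation matrix", {
  m <- matrix(0.95, 4, 4)
  m[1, 2] <- m[2, 1] <- -0.95   # indefinite by construction
  diag(m) <- 1
  expect_lt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  r <- connvar:::nearest_psd(m)
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(r), rep(1, 4))
  expect_true(isSymmetric(r))
})

test_that("sample correlations converge to the target covariance", {
  # long, noise-only series: empirical r within 0.02 of target
  cfg <- cohort_config(
    n_per_group = c("healthy-control" = 1),
    group_connectivity_offset = c("healthy-control" = 0),
    group_variability_scale = c("healthy-control" = 1),
    n_parcels = 8, n_modules = 2, n_timepoints = 10000,
    within_module_r = 0.6, between_module_r = 0.1,
    ar_coefficient = 0, network_signal_sd = 0, seed = 5)
  sim <- simulate_timeseries(cfg, "healthy-control", seed = 5,
                             confounds = FALSE)
  target <- build_target_covariance(cfg, "healthy-control")
  emp <- cor(t(sim$ts$data))
  same <- outer(cfg$module_assignment, cfg$module_assignment, "==")
  diag(same) <- NA
  # block-mean correlations converge within 0.02; individual pairs have
  # sampling sd ~ (1 - r^2)/sqrt(T) ~ 0.01, so the per-pair bound accounts
  # for taking a maximum over all 28 pairs
  expect_lt(abs(mean(emp[which(same)]) - cfg$within_module_r), 0.02)
  expect_lt(abs(mean(emp[which(!same)]) - cfg$between_module_r), 0.02)
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("identical seeds reproduce the series bit-exactly", {
  cfg <- tiny_config(n_parcels = 10, n_modules = 2)
  a <- simulate_timeseries(cfg, "no-RT", seed = 42)
  b <- simulate_timeseries(cfg, "no-RT", seed = 42)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$confounds$motion, b$confounds$motion)
  c2 <- simulate_timeseries(cfg, "no-RT", seed = 43)
  expect_false(identical(a$ts$data, c2$ts$data))
})

test_that("doubling the variability scale doubles the network signal std", {
  base <- list(
    n_per_group = c("healthy-control" = 1),
    group_connectivity_offset = c("healthy-control" = 0),
    n_parcels = 30, n_modules = 3, n_timepoints = 10000,
    ar_coefficient = 0, network_signal_sd = 10, seed = 7)
  cfg1 <- do.call(cohort_config,
                  c(base, list(group_variability_scale =
                                 c("healthy-control" = 1))))
  cfg2 <- do.call(cohort_config,
                  c(base, list(group_variability_scale =
                                 c("healthy-control" = 2))))
  s1 <- simulate_timeseries(cfg1, "healthy-control", seed = 7,
                            confounds = FALSE)
  s2 <- simulate_timeseries(cfg2, "healthy-control", seed = 7,
                            confounds = FALSE)
  # project onto each template map; same seed means identical noise, so the
  # ratio of template-projected std reflects the planted amplitudes
  W <- cfg1$template_loadings
  for (k in seq_len(ncol(W))) {
    w <- W[, k] / sum(W[, k]^2)
    p1 <- drop(w %*% s1$ts$data)
    p2 <- drop(w %*% s2$ts$data)
    expect_equal(sd(p2) / sd(p1), 2, tolerance = 0.05)
  }
})

test_that("too-short acquisitions are rejected", {
  expect_error(cohort_config(n_timepoints = 5),
               "cannot estimate correlations")
})

test_that("zero-amplitude confounds leave the series untouched", {
  ts <- white_ts(P = 8, T_ = 60)
  spec <- list(motion_sd = 0, motion_leak = 0, spike_prob = 0,
               spike_leak = 0, drift_slope = 0, tissue_leak = 0)
  out <- inject_confounds(ts, spec, seed = 3)
  expect_identical(out$ts$data, ts$data)
  expect_length(out$confounds$spike_frames, 0)
})

test_that("spike frame counts follow the configured binomial rate", {
  ts <- white_ts(P = 4, T_ = 125)
  spec <- list(motion_sd = 0.1, motion_leak = 0, spike_prob = 0.1,
               spike_leak = 0, drift_slope = 0, tissue_leak = 0)
  counts <- vapply(1:30, function(s) {
    length(inject_confounds(ts, spec, seed = s)$confounds$spike_frames)
  }, numeric(1))
  # total spikes over 30 seeds ~ Binomial(30 * 125, 0.1); 99% interval
  total <- sum(counts)
  ci <- qbinom(c(0.005, 0.995), 30 * 125, 0.1)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("planted drift slope is recoverable from the parcel mean", {
  ts <- white_ts(P = 40, T_ = 200, tr = 2, sd = 0.05, seed = 9)
  spec <- list(motion_sd = 0, motion_leak = 0, spike_prob = 0,
               spike_leak = 0, drift_slope = 0.01, tissue_leak = 0)
  out <- inject_confounds(ts, spec, seed = 11)
  tsec <- (seq_len(200) - 1) * 2
  pm <- colMeans(out$ts$data) - colMeans(ts$data)
  # remove the cosine component the generator documents, leaving the line
  slope <- coef(lm(pm ~ tsec + cos(2 * pi * tsec / max(tsec))))[["tsec"]]
  expect_equal(slope, 0.01, tolerance = 0.1 * 0.01)
})

test_that("cohort honors group sizes, ordering and record invariants", {
  cfg <- tiny_config(n_per_group = c("healthy-control" = 19, "no-RT" = 4,
                                     "WVRT" = 5, "focal" = 2,
                                     "WBRT-low-dose" = 4,
                                     "WBRT-high-dose" = 4))
  co <- simulate_cohort(cfg, timeseries = FALSE)
  expect_equal(nrow(co$records), 38L)
  expect_equal(as.vector(table(co$records$group)[cfg$group_labels]),
               unname(cfg$n_per_group))
  expect_identical(levels(co$records$group), cfg$group_labels)
  with_rt <- !is.na(co$records$age_at_rt)
  expect_true(all(co$records$age_at_rt[with_rt] <=
                    co$records$age_at_imaging[with_rt]))
  expect_true(is.integer(co$records$cmb_count) ||
                is.numeric(co$records$cmb_count))
})

test_that("memory z-score correlation lands near the configured target", {
  cfg <- tiny_config(n_per_group = c("healthy-control" = 50, "no-RT" = 50,
                                     "focal" = 50, "WBRT-high-dose" = 50),
                     seed = 31)
  co <- simulate_cohort(cfg, timeseries = FALSE)
  r <- cor(co$records$planted_composite, co$records$isl_zscore)
  expect_gte(r, 0.38)
  expect_lte(r, 0.60)
})

test_that("the planted microbleed link is parabolic with a mid-burden peak", {
  hits <- vapply(1:20, function(s) {
    cfg <- tiny_config(n_per_group = c("healthy-control" = 10, "no-RT" = 30,
                                       "focal" = 30, "WBRT-high-dose" = 30),
                       seed = 400 + s)
    rec <- simulate_cohort(cfg, timeseries = FALSE)$records
    pat <- rec[rec$group != "healthy-control" & !is.na(rec$cmb_count), ]
    # normalize out the group effect to isolate the planted burden bump
    rel <- pat$planted_scale /
      cfg$group_variability_scale[as.character(pat$group)]
    bin <- cut(pat$cmb_count, c(-Inf, 2, 90, Inf),
               labels = c("low", "mid", "high"))
    mm <- tapply(rel, bin, mean)
    mm[["mid"]] > mm[["low"]] && mm[["mid"]] > mm[["high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cohort generation is reproducible and writes readable files", {
  cfg <- tiny_config(n_per_group = c("healthy-control" = 2, "no-RT" = 2),
                     n_parcels = 8, n_modules = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$timeseries[[1]]$data, b$timeseries[[1]]$data)
  dir <- withr::local_tempdir()
  write_cohort(a, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  rt <- read_parcel_ts(file.path(dir, "sub-001_bold.tsv"))
  expect_equal(rt$data, a$timeseries[[1]]$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rt$sampling_interval, cfg$sampling_interval)
})
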