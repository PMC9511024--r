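#' Target spatial covariance (correlation) matrix for one subject
#'
#' Builds the planted parcel x parcel correlation matrix: `within_module_r`
#' inside planted modules, `between_module_r` plus the subject group's
#' connectivity offset between modules, unit diagonal. Entries are clipped to
#' (-1, 1); if clipping (or an extreme parameter choice) breaks positive
#' semi-definiteness, the nearest-PSD repair (eigenvalue clipping at 1e-8 and
#' rescaling back to a correlation matrix) is applied.
#'
#' @param config a [cohort_config()].
#' @param subject one subject record (a list or one-row data frame with at
#'   least a `group` entry), or a group label string.
#' @return symmetric positive semi-definite correlation matrix.
#' @export
build_target_covariance <- function(config, subject) {
  group <- if (is.character(subject)) subject else as.character(subject$group)
  if (!group %in% config$group_labels) {
    stop(sprintf("unknown group label '%s'", group))
  }
  offset <- config$group_connectivity_offset[[group]]
  mod <- config$module_assignment
  if (length(mod) != config$n_parcels) {
    stop("module_assignment must cover all parcels")
  }
  same <- outer(mod, mod, "==")
  sigma <- matrix(config$between_module_r + offset,
                  config$n_parcels, config$n_parcels)
  sigma[same] <- config$within_module_r
  sigma <- pmin(pmax(sigma, -0.99), 0.99)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) sigma <- nearest_psd(sigma)
  sigma
}

# Nearest-PSD shortcut: clip negative eigenvalues to 1e-8, re-symmetrize and
# rescale to unit diagonal. Hard error (reporting the offending eigenvalue)
# if the repaired matrix is still indefinite.
nearest_psd <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  check <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (check < -eps) {
    stop(sprintf("covariance not PSD after repair (eigenvalue %.3e)", check))
  }
  out
}

# Standardized super-Gaussian smooth series used as a planted network time
# course: AR(1)-smoothed Gaussian noise pushed through x|x| (positive excess
# kurtosis, as spatial/temporal ICA assumes for recoverable sources).
rsupergauss <- function(n, smooth = 0.8) {
  burn <- 100L
  g <- as.numeric(stats::filter(stats::rnorm(n + burn), smooth,
                                method = "recursive"))[-seq_len(burn)]
  s <- g * abs(g)
  (s - mean(s)) / stats::sd(s)
}

#' Simulate one subject's parcellated BOLD time series
#'
#' Draws a Gaussian series with the subject's target spatial covariance and
#' lag-1 temporal autocorrelation `ar_coefficient` (stationary AR(1) with
#' spatially correlated innovations), adds the planted canonical-network
#' signals (super-Gaussian time courses entering through the template
#' loadings, scaled by the subject's variability amplitude), and optionally
#' injects confounds via [inject_confounds()].
#'
#' @param config a [cohort_config()].
#' @param subject a subject record (needs `group`; optional `subject_id` and
#'   `planted_scale`, the realized amplitude multiplier -- defaults to the
#'   group's variability scale), or a group label string.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param confounds logical; add motion/drift/tissue confounds.
#' @return a list with `ts` (a [parcel_ts()]) and `confounds` (a
#'   `confound_table`, or `NULL` when `confounds = FALSE`).
#' @export
simulate_timeseries <- function(config, subject, seed = config$seed,
                                confounds = TRUE) {
  if (config$n_timepoints < 10L) {
    stop("n_timepoints < 10: cannot estimate correlations meaningfully")
  }
  if (is.character(subject)) {
    subject <- list(subject_id = subject, group = subject)
  }
  group <- as.character(subject$group)
  scale <- if (!is.null(subject$planted_scale) && is.finite(subject$planted_scale)) {
    subject$planted_scale
  } else {
    config$group_variability_scale[[group]]
  }
  sid <- if (!is.null(subject$subject_id)) subject$subject_id else group
  sigma <- build_target_covariance(config, group)
  P <- config$n_parcels
  T_ <- config$n_timepoints
  phi <- config$ar_coefficient
  withr::with_seed(seed, {
    L <- t(chol(sigma + diag(1e-10, P)))
    E <- L %*% matrix(stats::rnorm(P * T_), P, T_)
    X <- matrix(0, P, T_)
    X[, 1] <- E[, 1]
    if (T_ > 1L) {
      s <- sqrt(1 - phi^2)
      for (t in 2:T_) X[, t] <- phi * X[, t - 1] + s * E[, t]
    }
    W <- config$template_loadings
    amp <- config$network_signal_sd * scale
    S <- t(vapply(seq_len(ncol(W)), function(k) rsupergauss(T_),
                  numeric(T_)))
    X <- X + W %*% (amp * S)
    ts <- parcel_ts(X, sampling_interval = config$sampling_interval,
                    subject_id = sid,
                    parcel_labels = sprintf("parcel_%03d", seq_len(P)))
    conf <- NULL
    if (confounds) {
      injected <- inject_confounds(ts, config$confound_spec,
                                   seed = seed + 1L)
      ts <- injected$ts
      conf <- injected$confounds
    }
    list(ts = ts, confounds = conf)
  })
}

#' Inject confound structure into a parcel time series
#'
#' Adds (i) linear plus low-frequency cosine drift (slope `drift_slope` signal
#' units per second, identical in every parcel so the parcel-mean trend slope
#' equals the configured slope), (ii) 12 motion regressor channels (6
#' rigid-body random-walk parameters plus their first derivatives) partially
#' leaked into parcels through a random rank-3 mixing matrix, (iii) 15
#' white-matter and 5 CSF tissue noise channels, also leaked at rank 3, whose
#' first two channels carry the drift basis (as anatomical noise components do
#' for scanner drift), and (iv) spike frames whose simulated translation jump
#' exceeds 2 mm, occurring independently per frame with probability
#' `spike_prob` and leaking a large artifact into all parcels. The returned
#' `confound_table` records the ground truth.
#'
#' All-zero amplitudes leave the series exactly unchanged.
#'
#' @param ts a [parcel_ts()].
#' @param spec confound specification list (see [cohort_config()]).
#' @param seed integer seed.
#' @return list with `ts` (confounded series) and `confounds` (class
#'   `confound_table`: `motion` T x 12, `tissue` T x 20, `spike_frames`,
#'   `drift`, `outlier_flags`).
#' @export
inject_confounds <- function(ts, spec, seed = 1L) {
  stopifnot(inherits(ts, "parcel_ts"))
  amps <- c(spec$motion_sd, spec$motion_leak, spec$spike_prob,
            spec$spike_leak, spec$drift_slope, spec$tissue_leak)
  if (any(amps < 0)) stop("confound amplitudes must be >= 0")
  P <- n_parcels(ts)
  T_ <- n_timepoints(ts)
  tsec <- (seq_len(T_) - 1) * ts$sampling_interval
  withr::with_seed(seed, {
    # 6 rigid-body parameters as random walks (translations in mm)
    M6 <- vapply(seq_len(6L), function(j) cumsum(stats::rnorm(T_, sd = spec$motion_sd)),
                 numeric(T_))
    colnames(M6) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    # spike frames: single-frame translation excursions > 2 mm
    spike <- which(stats::runif(T_) < spec$spike_prob)
    if (length(spike)) {
      jumps <- stats::runif(length(spike), 2.5, 5) *
        sample(c(-1, 1), length(spike), replace = TRUE)
      M6[spike, "trans_x"] <- M6[spike, "trans_x"] + jumps
    }
    D6 <- rbind(0, diff(M6))
    colnames(D6) <- paste0("d_", colnames(M6))
    motion <- cbind(M6, D6)

    # drift: linear + one full cosine cycle (no net trend contribution),
    # added equally to all parcels so the parcel-mean slope is the config one
    drift <- spec$drift_slope * tsec +
      0.25 * spec$drift_slope * max(tsec) * cos(2 * pi * tsec / max(tsec))

    # tissue channels: first two carry the drift basis, the rest AR(1) noise
    tissue <- vapply(seq_len(20L), function(j) {
      as.numeric(stats::filter(stats::rnorm(T_), 0.5, method = "recursive"))
    }, numeric(T_))
    tissue[, 1] <- tsec
    tissue[, 2] <- cos(2 * pi * tsec / max(tsec))
    tissue <- scale(tissue)
    colnames(tissue) <- c(paste0("wm_", 1:15), paste0("csf_", 1:5))

    X <- ts$data
    X <- X + matrix(drift, P, T_, byrow = TRUE)
    if (spec$motion_leak > 0) {
      Mstd <- apply(motion, 2, function(v) {
        s <- stats::sd(v)
        if (s > 0) (v - mean(v)) / s else v * 0
      })
      mix <- (Mstd %*% matrix(stats::rnorm(12 * 3), 12, 3) %*%
                matrix(stats::rnorm(3 * P), 3, P)) / sqrt(3 * 12)
      X <- X + spec$motion_leak * t(mix)
    }
    if (spec$tissue_leak > 0) {
      mix <- (tissue %*% matrix(stats::rnorm(20 * 3), 20, 3) %*%
                matrix(stats::rnorm(3 * P), 3, P)) / sqrt(3 * 20)
      X <- X + spec$tissue_leak * t(mix)
    }
    if (spec$spike_leak > 0 && length(spike)) {
      X[, spike] <- X[, spike] +
        spec$spike_leak * matrix(stats::rnorm(P * length(spike)), P)
    }
    flags <- rep(FALSE, T_)
    flags[spike] <- TRUE
    conf <- structure(
      list(motion = motion, tissue = tissue,
           spike_frames = spike, drift = drift, outlier_flags = flags),
      class = "confound_table"
    )
    list(ts = ts_with_data(ts, X), confounds = conf)
  })
}

#' @export
print.confound_table <- function(x, ...) {
  cat(sprintf("<confound_table> %d frames, %d motion + %d tissue regressors, %d spike frames\n",
              nrow(x$motion), ncol(x$motion), ncol(x$tissue),
              length(x$spike_frames)))
  invisible(x)
}

# parabolic modulation of the variability amplitude by microbleed burden:
# quadratic in log1p(count), peaking at `vertex`, clipped to +/- amplitude
cmb_bump <- function(cmb, quad) {
  x <- log1p(cmb)
  b <- quad$amplitude * (1 - ((x - quad$vertex) / quad$halfwidth)^2)
  pmin(pmax(b, -quad$amplitude), quad$amplitude)
}

# draw a patient's microbleed count: mixture over low (0-2), moderate (4-47)
# and very high (92-205) burden strata
draw_cmb <- function(n) {
  stratum <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  counts <- integer(n)
  counts[stratum == 1L] <- sample(0:2, sum(stratum == 1L), replace = TRUE)
  counts[stratum == 2L] <- sample(4:47, sum(stratum == 2L), replace = TRUE)
  counts[stratum == 3L] <- sample(92:205, sum(stratum == 3L), replace = TRUE)
  counts
}

#' Simulate a full cohort
#'
#' Generates subject records (group, ages, RT dose/timing, microbleed count,
#' memory z-score) and, optionally, the per-subject confounded BOLD series.
#' Group sizes are honored exactly and the configured group ordering is
#' preserved. The memory (ISL) z-score is a linear combination of the
#' subject's standardized planted effect composite and noise, calibrated so
#' the cohort-level Pearson correlation approaches
#' `covariate_model$isl_target_r`; the planted variability amplitude is
#' modulated by the configured parabola in the microbleed count so downstream
#' burden-bin analyses see the planted parabolic link.
#'
#' Ground-truth generator quantities are kept in `planted_*` columns of the
#' records table.
#'
#' @param config a [cohort_config()].
#' @param timeseries generate BOLD series and confounds (set `FALSE` for
#'   covariate-only cohorts, which is much faster).
#' @return list of class `cohort`: `records` (tibble), `timeseries` (list of
#'   [parcel_ts()] or `NULL`), `confounds` (list of `confound_table` or
#'   `NULL`), `config`.
#' @export
simulate_cohort <- function(config, timeseries = TRUE) {
  groups <- config$group_labels
  n <- config$n_per_group
  total <- sum(n)
  withr::with_seed(config$seed, {
    group <- factor(rep(groups, times = n), levels = groups)
    irradiated <- !group %in% c("healthy-control", "no-RT")
    age_im <- round(stats::runif(total, 12, 25), 1)
    time_since_rt <- ifelse(irradiated,
                            pmin(round(stats::runif(total, 1, 15), 1),
                                 age_im - 3), NA_real_)
    age_rt <- ifelse(irradiated, round(age_im - time_since_rt, 1), NA_real_)
    dose <- rep(NA_real_, total)
    dose[group == "WVRT"] <- round(stats::runif(sum(group == "WVRT"), 30, 45), 1)
    dose[group == "focal"] <- 59.4
    dose[group == "WBRT-low-dose"] <-
      round(stats::runif(sum(group == "WBRT-low-dose"), 23, 36), 1)
    dose[group == "WBRT-high-dose"] <-
      round(stats::runif(sum(group == "WBRT-high-dose"), 54, 60), 1)

    patient <- group != "healthy-control"
    cmb <- integer(total)
    cmb[patient] <- draw_cmb(sum(patient))
    cmb_missing <- patient & stats::runif(total) < config$covariate_model$cmb_missing_prob
    cmb_out <- ifelse(cmb_missing, NA_integer_, cmb)

    base_scale <- config$group_variability_scale[as.character(group)] *
      exp(stats::rnorm(total, sd = config$subject_scale_sd))
    bump <- ifelse(patient, cmb_bump(cmb, config$covariate_model$cmb_quadratic), 0)
    planted_scale <- base_scale * (1 + bump)
    planted_offset <- config$group_connectivity_offset[as.character(group)]

    # composite of planted effects driving the memory score
    comp <- as.numeric(scale(planted_scale))
    r <- config$covariate_model$isl_target_r
    isl <- r * comp + sqrt(1 - r^2) * stats::rnorm(total)

    records <- tibble::tibble(
      subject_id = sprintf("sub-%03d", seq_len(total)),
      group = group,
      age_at_imaging = age_im,
      age_at_rt = age_rt,
      time_since_rt = time_since_rt,
      rt_dose_max = dose,
      cmb_count = cmb_out,
      isl_zscore = round(isl, 3),
      planted_scale = planted_scale,
      planted_offset = unname(planted_offset),
      planted_composite = comp
    )
    stopifnot(all(is.na(records$age_at_rt) |
                    records$age_at_rt <= records$age_at_imaging))

    ts_list <- NULL
    conf_list <- NULL
    if (timeseries) {
      subj_seeds <- sample.int(.Machine$integer.max - 2L, total)
      sims <- lapply(seq_len(total), function(i) {
        simulate_timeseries(config, as.list(records[i, ]),
                            seed = subj_seeds[i], confounds = TRUE)
      })
      ts_list <- lapply(sims, `[[`, "ts")
      conf_list <- lapply(sims, `[[`, "confounds")
      names(ts_list) <- names(conf_list) <- records$subject_id
    }
    structure(list(records = records, timeseries = ts_list,
                   confounds = conf_list, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s)%s\n", nrow(x$records),
              paste(sprintf("%s: %d", names(x$config$n_per_group),
                            x$config$n_per_group), collapse = ", "),
              if (is.null(x$timeseries)) ", covariates only" else ""))
  invisible(x)
}

#' Write a cohort to disk as plain-text tables
#'
#' Per-subject time-series TSVs, confound TSVs (one regressor per column plus
#' the ground-truth outlier flags), a cohort metadata CSV and the
#' configuration as JSON.
#'
#' @param cohort a [simulate_cohort()] result with time series.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- cohort$records
  utils::write.csv(rec, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$template_loadings <- NULL
  cfg$parcel_coords_mm <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$timeseries)) {
    for (sid in rec$subject_id) {
      write_parcel_ts(cohort$timeseries[[sid]],
                      file.path(dir, paste0(sid, "_bold.tsv")))
      conf <- cohort$confounds[[sid]]
      df <- data.frame(conf$motion, conf$tissue,
                       outlier_flag = as.integer(conf$outlier_flags),
                       check.names = FALSE)
      utils::write.table(df, file.path(dir, paste0(sid, "_confounds.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
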