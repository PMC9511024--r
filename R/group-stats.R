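#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison with midrank ties. The p-value is exact (by
#' enumeration of rank assignments) when the combined sample size is at most
#' 12 and there are no ties. Larger tie-free samples use a
#' continuity-corrected normal approximation refined by the Edgeworth
#' kurtosis term with the closed-form excess kurtosis of the Mann-Whitney
#' statistic, `-(6/5) (m^2 + n^2 + mn + m + n) / (mn(m + n + 1))`, which
#' keeps the worst-case two-sided discrepancy from the exact distribution
#' well below 0.01 even at m = n = 6. With ties, the standard tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param method `"auto"` (the rule above), `"exact"` or `"normal"`.
#' @return list with `statistic` (Mann-Whitney U of the first sample),
#'   `p_value`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample must have at least 2 observations")
  }
  m <- length(a)
  n <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(method,
                  auto = (m + n <= 12L) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) {
    stop("exact p-value is not defined with ties")
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        1 - stats::pwilcox(U - 1, m, n)))
  } else if (!ties) {
    mu <- m * n / 2
    s2 <- m * n * (m + n + 1) / 12
    g2 <- -(6 / 5) * (m^2 + n^2 + m * n + m + n) / (m * n * (m + n + 1))
    F_edge <- function(u) {
      z <- (u + 0.5 - mu) / sqrt(s2)
      # the kurtosis term can overshoot [0, 1] in the far tails; clamp
      min(max(stats::pnorm(z) -
                stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z), 0), 1)
    }
    p <- min(1, max(2 * min(F_edge(U), 1 - F_edge(U - 1)), 2e-16))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                         correct = TRUE)
    )
    p <- wt$p.value
  }
  list(statistic = U, p_value = p, exact = exact)
}

#' Collapse fine exposure groups into the four-level ordering
#'
#' Maps the six generator labels onto the coarse analysis ordering
#' healthy controls < no RT < focal/WVRT < WBRT, used to keep groups
#' adequately sized.
#'
#' @param group factor or character vector of fine group labels.
#' @return factor with levels `healthy-control`, `no-RT`, `focal/WVRT`,
#'   `WBRT` in that order.
#' @export
collapse_groups4 <- function(group) {
  g <- as.character(group)
  out <- ifelse(g %in% c("WVRT", "focal"), "focal/WVRT",
                ifelse(g %in% c("WBRT-low-dose", "WBRT-high-dose"), "WBRT", g))
  factor(out, levels = c("healthy-control", "no-RT", "focal/WVRT", "WBRT"))
}

#' Ordered group comparison along an exposure ladder
#'
#' Pairwise Wilcoxon rank-sum tests between consecutive groups of the stated
#' ordering, plus a trend statistic: the Spearman rank correlation of the
#' metric against the ordinal group index (two-sided asymptotic p). Groups
#' with fewer than 2 members skip their pairwise tests with a warning.
#'
#' @param metric_table data frame with a group column and the metric column.
#' @param metric name of the metric column.
#' @param ordering character vector of group labels, low to high exposure.
#' @param group_col name of the group column (default `"group"`).
#' @return list with `pairwise` (tibble: group_low, group_high, statistic,
#'   p_value) and `trend` (list: rho, p_value, n).
#' @export
ordered_group_test <- function(metric_table, metric, ordering,
                               group_col = "group") {
  g <- as.character(metric_table[[group_col]])
  if (!all(ordering %in% g)) {
    stop("every ordering label must be present in the table")
  }
  y <- metric_table[[metric]]
  keep <- g %in% ordering & !is.na(y)
  g <- g[keep]
  y <- y[keep]
  pairs <- list()
  for (i in seq_len(length(ordering) - 1L)) {
    lo <- ordering[i]
    hi <- ordering[i + 1L]
    if (sum(g == lo) < 2L || sum(g == hi) < 2L) {
      warning(sprintf("group pair %s vs %s skipped: fewer than 2 members",
                      lo, hi))
      next
    }
    wt <- wilcoxon_rank_sum(y[g == lo], y[g == hi])
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      group_low = lo, group_high = hi,
      statistic = wt$statistic, p_value = wt$p_value)
  }
  idx <- match(g, ordering)
  ct <- suppressWarnings(
    stats::cor.test(y, idx, method = "spearman", exact = FALSE)
  )
  list(pairwise = dplyr::bind_rows(pairs),
       trend = list(rho = unname(ct$estimate), p_value = ct$p.value,
                    n = length(y)))
}

#' Correlation between an age-normalized metric and memory performance
#'
#' Pearson correlation (two-sided t-based p) between a metric and the memory
#' z-score, pairwise-complete. Metrics are taken age-normalized (divided by
#' age at imaging) by default, matching how memory z-scores are age-normed.
#'
#' @param metric_table data frame with the metric, the score and
#'   `age_at_imaging`.
#' @param metric metric column name.
#' @param score score column name (default `isl_zscore`).
#' @param age_normalize divide the metric by `age_at_imaging` first.
#' @return list with `R`, `p_value`, `n`.
#' @export
metric_memory_correlation <- function(metric_table, metric,
                                      score = "isl_zscore",
                                      age_normalize = TRUE) {
  x <- metric_table[[metric]]
  if (age_normalize) {
    if (!"age_at_imaging" %in% names(metric_table)) {
      stop("age_at_imaging required for age normalization")
    }
    x <- x / metric_table[["age_at_imaging"]]
  }
  y <- metric_table[[score]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Microbleed-burden bins
#'
#' Default edges reproduce the low (0-2), moderate (3-90, occupied 4-47) and
#' very high (>= 91) burden groups; edges are configurable since the original
#' grouping was derived from the distribution of the data.
#'
#' @param breaks increasing numeric cut points (right-closed, first bin from
#'   0).
#' @param labels bin labels.
#' @return object of class `cmb_bins`.
#' @export
cmb_bins <- function(breaks = c(2, 90), labels = c("low", "moderate",
                                                   "very-high")) {
  if (length(labels) != length(breaks) + 1L) {
    stop("need one more label than break")
  }
  structure(list(breaks = c(-Inf, breaks, Inf), labels = labels),
            class = "cmb_bins")
}

#' Microbleed-burden bin analysis with quadratic trend
#'
#' Assigns each subject with a non-missing microbleed count to a burden bin,
#' reports per-bin metric means and counts, and fits a least-squares
#' quadratic of the metric on the count (on the log1p scale by default,
#' matching the wide dynamic range of counts), reporting the curvature sign,
#' the vertex and the 95% CI of the quadratic coefficient.
#'
#' @param metric_table data frame with `cmb_count` and the metric.
#' @param metric metric column name.
#' @param bins a [cmb_bins()].
#' @param log_scale fit the quadratic in log1p(count) rather than the raw
#'   count.
#' @return list with `bin_means` (tibble: bin, n, mean), `quadratic` (list:
#'   coefficients, curvature_sign, vertex, quad_ci, p_value), `n_used`,
#'   `n_missing`.
#' @export
cmb_bin_analysis <- function(metric_table, metric, bins = cmb_bins(),
                             log_scale = TRUE) {
  cmb <- metric_table[["cmb_count"]]
  y <- metric_table[[metric]]
  keep <- !is.na(cmb) & !is.na(y)
  if (!any(keep)) stop("all microbleed counts are missing")
  cmb <- cmb[keep]
  y <- y[keep]
  bin <- cut(cmb, breaks = bins$breaks, labels = bins$labels, right = TRUE)
  bm <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, y = y), .data$bin,
                    .drop = FALSE),
    n = sum(!is.na(.data$y)), mean = mean(.data$y), .groups = "drop")
  x <- if (log_scale) log1p(cmb) else cmb
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  ci <- stats::confint(fit)["I(x^2)", ]
  pq <- summary(fit)$coefficients["I(x^2)", "Pr(>|t|)"]
  vertex_x <- -cf[["x"]] / (2 * cf[["I(x^2)"]])
  vertex <- if (log_scale) expm1(vertex_x) else vertex_x
  list(bin_means = bm,
       quadratic = list(coefficients = cf,
                        curvature_sign = sign(cf[["I(x^2)"]]),
                        vertex = vertex, quad_ci = unname(ci),
                        p_value = pq),
       n_used = length(y), n_missing = sum(!keep))
}

#' Risk-factor regression
#'
#' Ordinary least squares of an (age-normalized) imaging metric or the memory
#' z-score on the clinical risk factors for post-RT cognitive decline (age
#' during RT and time since RT), over irradiated subjects (for whom the
#' predictors are defined). Reports per-predictor coefficients, normal-theory
#' 95% confidence intervals and two-sided p-values. Errors on a collinear
#' design (condition number > 1e8).
#'
#' @param metric_table data frame with the outcome and predictor columns.
#' @param outcome outcome column name.
#' @param predictors predictor column names (default `age_at_rt`,
#'   `time_since_rt`).
#' @return tibble: `term`, `estimate`, `ci_low`, `ci_high`, `p_value`, with
#'   attribute `n` (subjects used, listwise complete).
#' @export
risk_factor_regression <- function(metric_table, outcome,
                                   predictors = c("age_at_rt",
                                                  "time_since_rt")) {
  cols <- c(outcome, predictors)
  if (!all(cols %in% names(metric_table))) stop("missing columns")
  d <- metric_table[stats::complete.cases(metric_table[, cols]), cols]
  if (nrow(d) < length(predictors) + 2L) {
    stop("too few complete cases for regression")
  }
  X <- cbind(1, as.matrix(d[, predictors]))
  sv <- svd(scale(X, center = FALSE,
                  scale = apply(abs(X), 2, max)))$d
  if (max(sv) / min(sv) > 1e8) {
    stop("collinear predictors: condition number exceeds 1e8")
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p_value = sm[, "Pr(>|t|)"]
  )
  attr(out, "n") <- nrow(d)
  out
}

#' Join covariates with computed imaging metrics
#'
#' One row per subject: the clinical covariates joined with modularity,
#' efficiency and per-network variability, plus age-normalized versions
#' (metric / age at imaging) of every imaging metric.
#'
#' @param records subject records (from [simulate_cohort()] or read from
#'   disk).
#' @param graph_metrics tibble from [cohort_graph_metrics()].
#' @param variability tibble from [variability_table()] (long; spread to one
#'   column per network, multiple components per network averaged).
#' @return tibble of class `metric_table`.
#' @export
build_metric_table <- function(records, graph_metrics, variability = NULL) {
  out <- dplyr::left_join(tibble::as_tibble(records), graph_metrics,
                          by = "subject_id")
  metric_cols <- c("modularity", "efficiency")
  if (!is.null(variability) && nrow(variability) > 0L) {
    wide <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(variability, .data$subject_id, .data$network),
        variability = mean(.data$variability), .groups = "drop"),
      names_from = "network", values_from = "variability",
      names_prefix = "var_")
    names(wide) <- gsub("-", "_", names(wide))
    out <- dplyr::left_join(out, wide, by = "subject_id")
    metric_cols <- c(metric_cols, setdiff(names(wide), "subject_id"))
  }
  for (mc in metric_cols) {
    out[[paste0(mc, "_agenorm")]] <- out[[mc]] / out[["age_at_imaging"]]
  }
  class(out) <- c("metric_table", class(out))
  out
}
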