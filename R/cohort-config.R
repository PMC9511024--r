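#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a 132-parcel,
#' 125-timepoint, TR = 4 s acquisition; planted modular covariance;
#' group-ordered hyperconnectivity and network-variability effects across the
#' exposure ladder (healthy controls through high-dose whole-brain RT);
#' motion/drift/tissue confound structure; and clinical covariates (memory
#' z-score linked to the planted effects, microbleed counts with a quadratic
#' link to variability).
#'
#' Group-level parameters (`n_per_group`, `group_connectivity_offset`,
#' `group_variability_scale`) are named vectors sharing the same names; the
#' ordering of `names(n_per_group)` is the exposure ordering and is preserved
#' in all outputs. Defaults mirror the studied cohort: 19 healthy controls and
#' 19 patients (4 non-irradiated, 5 whole-ventricular RT, 2 supratentorial
#' focal RT, 4 low-dose and 4 high-dose whole-brain RT), with connectivity
#' offsets and variability scales monotone in that ordering.
#'
#' @param n_per_group named integer vector of subjects per group; the name
#'   order defines the exposure ordering.
#' @param n_parcels number of atlas parcels (default 132).
#' @param n_timepoints number of BOLD timepoints (default 125).
#' @param sampling_interval TR in seconds (default 4).
#' @param n_modules number of planted covariance modules (communities).
#' @param within_module_r,between_module_r target Pearson correlations inside /
#'   between planted modules; must satisfy `0 <= between < within < 1`.
#' @param group_connectivity_offset named numeric vector, additive shift on the
#'   between-module correlation per group (the hyperconnectivity effect).
#' @param group_variability_scale named numeric vector, multiplier on the
#'   planted network-signal amplitude per group.
#' @param ar_coefficient lag-1 autocorrelation of the spatially correlated
#'   noise (per parcel).
#' @param network_signal_sd baseline standard deviation of each planted
#'   canonical-network time course, before group scaling.
#' @param subject_scale_sd lognormal sd of the per-subject amplitude jitter
#'   around the group variability scale.
#' @param module_assignment optional integer vector (parcel -> module id,
#'   1-based); defaults to contiguous equal blocks.
#' @param template_loadings optional parcels x 4 matrix of canonical-network
#'   weights (columns SN, FPN, L-DAN, R-DAN); defaults to smooth disjoint-peak
#'   bumps over the parcel axis.
#' @param parcel_spacing_mm spacing of the synthetic 1-D parcel coordinates,
#'   used by parcel-space smoothing.
#' @param confound_spec list with `motion_sd` (mm, random-walk step),
#'   `motion_leak` (amplitude of motion leakage into parcels), `spike_prob`
#'   (per-frame probability of a > 2 mm displacement spike), `spike_leak`
#'   (parcel artifact amplitude at spike frames), `drift_slope` (signal units
#'   per second of linear drift), `tissue_leak` (amplitude of tissue-noise
#'   leakage).
#' @param covariate_model list with `isl_target_r` (target Pearson correlation
#'   between the planted effect composite and the memory z-score),
#'   `cmb_quadratic` (list `amplitude`, `vertex`, `halfwidth` of the parabola
#'   in log1p(CMB count) modulating the variability amplitude) and
#'   `cmb_missing_prob` (probability a patient's CMB count is missing,
#'   emulating unusable susceptibility-weighted scans).
#' @param seed integer seed; every random draw in the generator is
#'   reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c("healthy-control" = 19, "no-RT" = 4,
                                          "WVRT" = 5, "focal" = 2,
                                          "WBRT-low-dose" = 4,
                                          "WBRT-high-dose" = 4),
                          n_parcels = 132, n_timepoints = 125,
                          sampling_interval = 4, n_modules = 6,
                          within_module_r = 0.6, between_module_r = 0.2,
                          group_connectivity_offset =
                            c("healthy-control" = 0, "no-RT" = 0.04,
                              "WVRT" = 0.06, "focal" = 0.08,
                              "WBRT-low-dose" = 0.10, "WBRT-high-dose" = 0.12),
                          group_variability_scale =
                            c("healthy-control" = 1.0, "no-RT" = 1.25,
                              "WVRT" = 1.35, "focal" = 1.45,
                              "WBRT-low-dose" = 1.55, "WBRT-high-dose" = 1.70),
                          ar_coefficient = 0.3, network_signal_sd = 1.0,
                          subject_scale_sd = 0.1,
                          module_assignment = NULL, template_loadings = NULL,
                          parcel_spacing_mm = 4,
                          confound_spec = list(motion_sd = 0.1,
                                               motion_leak = 0.3,
                                               spike_prob = 0.02,
                                               spike_leak = 3,
                                               drift_slope = 0.002,
                                               tissue_leak = 0.2),
                          covariate_model = list(
                            isl_target_r = 0.5,
                            cmb_quadratic = list(amplitude = 0.25,
                                                 vertex = log1p(20),
                                                 halfwidth = 1.6),
                            cmb_missing_prob = 0.1),
                          seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(groups == "")) {
    stop("n_per_group must be a fully named vector")
  }
  if (anyDuplicated(groups)) stop("duplicated group labels")
  for (nm in c("group_connectivity_offset", "group_variability_scale")) {
    v <- get(nm)
    if (!all(groups %in% names(v))) {
      stop(sprintf("%s must be named for every group label", nm))
    }
  }
  group_connectivity_offset <- group_connectivity_offset[groups]
  group_variability_scale <- group_variability_scale[groups]
  if (!(between_module_r >= 0 && between_module_r < within_module_r &&
        within_module_r < 1)) {
    stop("need 0 <= between_module_r < within_module_r < 1")
  }
  if (n_timepoints < 10L) {
    stop("n_timepoints < 10: cannot estimate correlations meaningfully")
  }
  if (abs(ar_coefficient) >= 1) stop("ar_coefficient must be in (-1, 1)")
  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_modules), n_parcels))
  }
  module_assignment <- as.integer(module_assignment)
  if (length(module_assignment) != n_parcels) {
    stop("module_assignment must cover all parcels")
  }
  if (is.null(template_loadings)) {
    template_loadings <- default_templates(n_parcels)
  }
  template_loadings <- as.matrix(template_loadings)
  if (nrow(template_loadings) != n_parcels) {
    stop("template_loadings must have one row per parcel")
  }
  structure(
    list(n_per_group = n_per_group, group_labels = groups,
         n_parcels = as.integer(n_parcels),
         n_timepoints = as.integer(n_timepoints),
         sampling_interval = sampling_interval,
         n_modules = as.integer(max(module_assignment)),
         within_module_r = within_module_r,
         between_module_r = between_module_r,
         group_connectivity_offset = group_connectivity_offset,
         group_variability_scale = group_variability_scale,
         ar_coefficient = ar_coefficient,
         network_signal_sd = network_signal_sd,
         subject_scale_sd = subject_scale_sd,
         module_assignment = module_assignment,
         template_loadings = template_loadings,
         parcel_coords_mm = matrix((seq_len(n_parcels) - 1) * parcel_spacing_mm,
                                   ncol = 1),
         confound_spec = confound_spec,
         covariate_model = covariate_model,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d subjects in %d groups; %d parcels x ",
                     "%d timepoints, TR = %g s, %d modules\n"),
              sum(x$n_per_group), length(x$group_labels), x$n_parcels,
              x$n_timepoints, x$sampling_interval, x$n_modules))
  invisible(x)
}

# Smooth disjoint-peak parcel-weight maps standing in for the canonical
# salience (SN), frontoparietal (FPN) and left/right dorsal attention
# (L-DAN / R-DAN) network templates. Peaks at fixed fractions of the parcel
# axis, Gaussian falloff, max weight 1, small weights zeroed for sparsity.
default_templates <- function(n_parcels) {
  centers <- c(SN = 0.12, FPN = 0.38, `L-DAN` = 0.64, `R-DAN` = 0.88)
  width <- n_parcels / 18
  i <- seq_len(n_parcels)
  w <- vapply(centers, function(cf) {
    v <- exp(-(i - cf * n_parcels)^2 / (2 * width^2))
    v[v < 0.01] <- 0
    v / max(v)
  }, numeric(n_parcels))
  rownames(w) <- sprintf("parcel_%03d", i)
  w
}

#' Canonical-network spatial templates for a cohort configuration
#'
#' Returns the parcels x networks template weight matrix. With
#' `split_dan = TRUE` (default) a combined `DAN` column (sum of the left and
#' right maps, renormalized) is appended, so that low-model-order ICA runs in
#' which the dorsal attention network appears as a single component can still
#' be matched.
#'
#' @param config a [cohort_config()].
#' @param split_dan append the combined DAN template.
#' @return numeric matrix, parcels x templates.
#' @export
network_templates <- function(config, split_dan = TRUE) {
  w <- config$template_loadings
  if (split_dan && all(c("L-DAN", "R-DAN") %in% colnames(w))) {
    dan <- w[, "L-DAN"] + w[, "R-DAN"]
    w <- cbind(w, DAN = dan / max(dan))
  }
  w
}

#' Map template labels to network families
#'
#' `L-DAN`, `R-DAN` and `DAN` all belong to the `DAN` family; other labels are
#' their own family. Used when correlating variability across ICA model orders
#' in which the dorsal attention network may or may not split into hemispheric
#' subnetworks.
#'
#' @param labels character vector of network labels.
#' @return character vector of family names.
#' @export
network_family <- function(labels) {
  ifelse(labels %in% c("DAN", "L-DAN", "R-DAN"), "DAN", labels)
}
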