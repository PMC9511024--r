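#' Reproducibility sweep of the network-variability pipeline
#'
#' Re-runs the full variability pipeline (parcel-space smoothing, bandpass
#' filtering, group ICA, template matching, backprojection, standard
#' deviation) over every combination of bandpass band, smoothing kernel and
#' ICA model order, on identical input data. Confound regression, which does
#' not depend on the swept settings, is applied once up front when the cohort
#' carries confound tables.
#'
#' @param cohort a [simulate_cohort()] result with time series (or any list
#'   with `timeseries`, optional `confounds`, and `config`).
#' @param bands list of length-2 band edges in Hz.
#' @param fwhms numeric vector of smoothing FWHMs in mm.
#' @param components integer vector of ICA model orders.
#' @param seed integer seed (one ICA seed per setting, derived
#'   deterministically).
#' @param floor template-matching floor.
#' @return tibble of class `sweep_result` with one row per subject x matched
#'   network x setting: `subject_id`, `network`, `band_low`, `band_high`,
#'   `fwhm`, `n_components`, `variability`.
#' @export
reproducibility_sweep <- function(cohort,
                                  bands = list(c(0.008, 0.09),
                                               c(0.008, 0.06),
                                               c(0.016, 0.09)),
                                  fwhms = c(0, 4, 8),
                                  components = c(20, 40),
                                  seed = 1L, floor = 0.3) {
  config <- cohort$config
  ts_list <- cohort$timeseries
  if (is.null(ts_list)) stop("cohort carries no time series")
  if (!is.null(cohort$confounds)) {
    ts_list <- lapply(names(ts_list), function(sid) {
      regress_confounds(ts_list[[sid]], cohort$confounds[[sid]])$ts
    })
    names(ts_list) <- names(cohort$timeseries)
  }
  templates <- network_templates(config, split_dan = TRUE)
  grid <- expand.grid(band = seq_along(bands), fwhm = fwhms,
                      n_components = components)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    band <- bands[[grid$band[i]]]
    fwhm <- grid$fwhm[i]
    ncomp <- grid$n_components[i]
    prepped <- lapply(ts_list, function(ts) {
      ts <- smooth_parcels(ts, fwhm, config$parcel_coords_mm)
      suppressWarnings(bandpass(ts, band[1], band[2]))
    })
    dec <- run_group_ica(prepped, n_components = ncomp,
                         seed = seed + 1000L * i)
    dec <- match_templates(dec, templates, floor = floor)
    vt <- variability_table(dec, prepped)
    if (nrow(vt) == 0L) return(NULL)
    vt$band_low <- band[1]
    vt$band_high <- band[2]
    vt$fwhm <- fwhm
    vt$n_components <- ncomp
    vt
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Cross-setting correlations of network variability
#'
#' For every pair of distinct sweep settings and every pair of network labels
#' within the same family (so a combined DAN at 20 components can be compared
#' with the hemispheric L-DAN / R-DAN at 40), computes the Pearson
#' correlation of per-subject variability across subjects. Multiple
#' components matched to the same label within a setting are averaged per
#' subject first.
#'
#' @param sweep a [reproducibility_sweep()] result.
#' @param min_n minimum paired subjects for a correlation (default 5).
#' @return tibble with the two settings' parameters, the two labels, `r` and
#'   `n`.
#' @export
sweep_correlations <- function(sweep, min_n = 5L) {
  agg <- dplyr::summarise(
    dplyr::group_by(sweep, .data$subject_id, .data$network, .data$band_low,
                    .data$band_high, .data$fwhm, .data$n_components),
    variability = mean(.data$variability), .groups = "drop"
  )
  agg$family <- network_family(agg$network)
  agg$setting <- paste(agg$band_low, agg$band_high, agg$fwhm,
                       agg$n_components, sep = "|")
  settings <- unique(agg[, c("setting", "band_low", "band_high", "fwhm",
                             "n_components")])
  out <- list()
  for (i in seq_len(nrow(settings))) {
    for (j in seq_len(nrow(settings))) {
      if (j <= i) next
      a <- agg[agg$setting == settings$setting[i], ]
      b <- agg[agg$setting == settings$setting[j], ]
      fams <- intersect(unique(a$family), unique(b$family))
      for (fam in fams) {
        af <- a[a$family == fam, ]
        bf <- b[b$family == fam, ]
        for (la in unique(af$network)) {
          for (lb in unique(bf$network)) {
            m <- merge(af[af$network == la, c("subject_id", "variability")],
                       bf[bf$network == lb, c("subject_id", "variability")],
                       by = "subject_id")
            if (nrow(m) < min_n) next
            out[[length(out) + 1L]] <- tibble::tibble(
              band_low_1 = settings$band_low[i],
              band_high_1 = settings$band_high[i],
              fwhm_1 = settings$fwhm[i],
              n_components_1 = settings$n_components[i],
              network_1 = la,
              band_low_2 = settings$band_low[j],
              band_high_2 = settings$band_high[j],
              fwhm_2 = settings$fwhm[j],
              n_components_2 = settings$n_components[j],
              network_2 = lb,
              r = stats::cor(m$variability.x, m$variability.y),
              n = nrow(m)
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Band-direction comparison with fixed spatial maps
#'
#' Isolates the effect of the bandpass choice on network variability: the
#' group ICA decomposition is estimated once on the wide-band data, its
#' template-matched maps are held fixed, and the subject-specific time
#' courses are backprojected from the data filtered at each band. Because the
#' narrow passband is contained in the wide one, the narrow-band variability
#' of the same component on the same data is bounded by the wide-band value
#' up to estimation noise; this function reports the two means and the
#' per-subject direction rate. (Re-estimating the ICA per band, as the
#' reproducibility sweep does, additionally changes the spatial maps and so
#' mixes filtering effects with decomposition differences.)
#'
#' @param cohort a cohort with time series (confounds regressed out here when
#'   present).
#' @param band_wide,band_narrow length-2 band edges in Hz; the narrow band
#'   should be contained in the wide band.
#' @param n_components ICA model order for the reference decomposition.
#' @param seed integer seed.
#' @param floor template-matching floor.
#' @return list with `mean_wide`, `mean_narrow`, `frac_narrow_lower` (share
#'   of subject x network values lower under the narrow band), `n`.
#' @export
band_direction_comparison <- function(cohort, band_wide = c(0.008, 0.09),
                                      band_narrow = c(0.008, 0.06),
                                      n_components = 20L, seed = 1L,
                                      floor = 0.3) {
  ts_list <- cohort$timeseries
  if (is.null(ts_list)) stop("cohort carries no time series")
  if (!is.null(cohort$confounds)) {
    ts_list <- lapply(names(ts_list), function(sid) {
      regress_confounds(ts_list[[sid]], cohort$confounds[[sid]])$ts
    })
    names(ts_list) <- names(cohort$timeseries)
  }
  wide <- lapply(ts_list, function(ts) {
    suppressWarnings(bandpass(ts, band_wide[1], band_wide[2]))
  })
  narrow <- lapply(ts_list, function(ts) {
    suppressWarnings(bandpass(ts, band_narrow[1], band_narrow[2]))
  })
  dec <- run_group_ica(wide, n_components = n_components, seed = seed)
  dec <- match_templates(dec, network_templates(cohort$config),
                         floor = floor)
  vw <- variability_table(dec, wide)
  vn <- variability_table(dec, narrow)
  j <- merge(vw, vn, by = c("subject_id", "network", "component"))
  list(mean_wide = mean(j$variability.x),
       mean_narrow = mean(j$variability.y),
       frac_narrow_lower = mean(j$variability.y < j$variability.x),
       n = nrow(j))
}

#' Per-subject family-mean variability for one sweep setting
#'
#' Convenience accessor: averages variability over all components of one
#' network family, per subject, within a single setting.
#'
#' @param sweep a [reproducibility_sweep()] result.
#' @param family network family name (e.g. `"DAN"`).
#' @param n_components,fwhm,band optional filters; each defaults to all.
#' @return tibble `subject_id`, `variability`.
#' @export
family_variability <- function(sweep, family, n_components = NULL,
                               fwhm = NULL, band = NULL) {
  x <- sweep[network_family(sweep$network) == family, ]
  if (!is.null(n_components)) x <- x[x$n_components == n_components, ]
  if (!is.null(fwhm)) x <- x[x$fwhm == fwhm, ]
  if (!is.null(band)) {
    x <- x[x$band_low == band[1] & x$band_high == band[2], ]
  }
  dplyr::summarise(dplyr::group_by(x, .data$subject_id),
                   variability = mean(.data$variability), .groups = "drop")
}
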