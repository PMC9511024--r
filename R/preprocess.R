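#' Detect outlier frames from motion parameters
#'
#' Flags frames whose frame-to-frame composite translation (Euclidean norm of
#' the first difference of the x/y/z translations, mm) exceeds the threshold.
#' If more than `max_outliers` frames qualify, only the `max_outliers` largest
#' excursions are kept and a truncation warning is raised.
#'
#' @param motion matrix or data frame of motion parameters with at least 6
#'   columns; translations are taken from columns named `trans_x`, `trans_y`,
#'   `trans_z` when present, otherwise the first three columns.
#' @param threshold_mm composite translation threshold (default 2 mm).
#' @param max_outliers cap on the number of flagged frames (default 30).
#' @return logical vector of per-frame outlier flags.
#' @export
detect_outlier_frames <- function(motion, threshold_mm = 2,
                                  max_outliers = 30L) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6L) {
    stop("motion table needs >= 6 columns (translations unidentifiable)")
  }
  trans_cols <- c("trans_x", "trans_y", "trans_z")
  tr <- if (all(trans_cols %in% colnames(motion))) {
    motion[, trans_cols, drop = FALSE]
  } else {
    motion[, 1:3, drop = FALSE]
  }
  composite <- c(0, sqrt(rowSums(diff(tr)^2)))
  flags <- composite > threshold_mm
  if (sum(flags) > max_outliers) {
    warning(sprintf("%d frames exceed %g mm; keeping the %d largest",
                    sum(flags), threshold_mm, max_outliers))
    keep <- order(composite, decreasing = TRUE)[seq_len(max_outliers)]
    flags <- rep(FALSE, length(flags))
    flags[keep] <- TRUE
  }
  flags
}

#' Regress confounds out of a parcel time series
#'
#' Ordinary-least-squares residualization of every parcel against an
#' intercept, the 12 motion regressors, the tissue (white-matter + CSF) noise
#' components and one indicator column per flagged outlier frame
#' (spike regression). Degrees of freedom remaining
#' (`timepoints - rank(design)`) are recorded and a minimum of `min_dof` is
#' enforced, erroring out otherwise.
#'
#' @param ts a [parcel_ts()].
#' @param confounds a `confound_table` (from [inject_confounds()] or read from
#'   disk) or a plain numeric matrix of regressors (one column each).
#' @param outlier_flags logical per-frame flags; defaults to
#'   [detect_outlier_frames()] on the motion parameters when a
#'   `confound_table` is given, else none.
#' @param min_dof minimum residual degrees of freedom (default 30).
#' @return list with `ts` (residual series) and `report` (class
#'   `denoise_report`: `dof_remaining`, `n_outliers`, `regressors_used`,
#'   `band`, `normality_stat`, `normality_pass`).
#' @export
regress_confounds <- function(ts, confounds, outlier_flags = NULL,
                              min_dof = 30L) {
  stopifnot(inherits(ts, "parcel_ts"))
  T_ <- n_timepoints(ts)
  if (inherits(confounds, "confound_table")) {
    reg <- cbind(confounds$motion, confounds$tissue)
    if (is.null(outlier_flags)) {
      outlier_flags <- detect_outlier_frames(confounds$motion)
    }
  } else {
    reg <- as.matrix(confounds)
    if (is.null(outlier_flags)) outlier_flags <- rep(FALSE, T_)
  }
  if (nrow(reg) != T_) stop("confound rows must equal timepoints")
  if (length(outlier_flags) != T_) {
    stop("outlier_flags length must equal timepoints")
  }
  design <- cbind(intercept = 1, reg)
  if (any(outlier_flags)) {
    ind <- vapply(which(outlier_flags), function(t) {
      v <- numeric(T_); v[t] <- 1; v
    }, numeric(T_))
    colnames(ind) <- sprintf("outlier_%03d", which(outlier_flags))
    design <- cbind(design, ind)
  }
  qrd <- qr(design)
  dof <- T_ - qrd$rank
  if (dof < min_dof) {
    stop(sprintf("insufficient degrees of freedom: %d remaining, need >= %d",
                 dof, min_dof))
  }
  resid <- t(qr.resid(qrd, t(ts$data)))
  report <- structure(
    list(dof_remaining = dof, n_outliers = sum(outlier_flags),
         regressors_used = ncol(design), band = c(NA_real_, NA_real_),
         normality_stat = NA_real_, normality_pass = NA),
    class = "denoise_report"
  )
  list(ts = ts_with_data(ts, resid), report = report)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("<denoise_report> dof = %g, %d outliers, %d regressors, band = [%g, %g] Hz\n",
              x$dof_remaining, x$n_outliers, x$regressors_used,
              x$band[1], x$band[2]))
  invisible(x)
}

#' Write a denoise report as JSON
#' @param report a `denoise_report`.
#' @param path output path.
#' @export
write_denoise_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Zero-phase bandpass filter
#'
#' Order-4 Butterworth filter applied forward-backward (zero phase) per
#' parcel, with reflective padding to suppress edge transients. A high edge at
#' or above the Nyquist frequency (`1 / (2 * TR)`) is clamped to
#' 0.99 * Nyquist with a warning -- at TR = 4 s the conventional 0.01-0.25 Hz
#' band exceeds the 0.125 Hz Nyquist limit and is effectively a high-pass.
#' A low edge of 0 yields a pure low-pass.
#'
#' @param ts a [parcel_ts()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz`.
#' @param order Butterworth order (default 4).
#' @return filtered [parcel_ts()].
#' @export
bandpass <- function(ts, low_hz, high_hz, order = 4L) {
  stopifnot(inherits(ts, "parcel_ts"))
  nyq <- 1 / (2 * ts$sampling_interval)
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("need 0 <= low_hz < high_hz")
  }
  if (low_hz >= nyq) {
    stop(sprintf("low edge %g Hz is at or above Nyquist (%g Hz)", low_hz, nyq))
  }
  if (high_hz > nyq) {
    warning(sprintf("high edge %g Hz exceeds Nyquist (%g Hz); clamping to %g Hz",
                    high_hz, nyq, 0.99 * nyq))
    high_hz <- 0.99 * nyq
  }
  flt <- if (low_hz <= 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  T_ <- n_timepoints(ts)
  # pad past the low-edge settling time so filtfilt transients stay outside
  pad <- min(T_ - 1L,
             max(50L, ceiling(2 / (max(low_hz, 1e-3) * ts$sampling_interval))))
  filt_one <- function(x) {
    x <- x - mean(x)  # DC is outside any passband; removing it up front
    xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
            2 * x[T_] - rev(x[T_ - seq_len(pad)]))
    y <- signal::filtfilt(flt, xp)
    y[pad + seq_len(T_)]
  }
  out <- t(apply(ts$data, 1, filt_one))
  ts_with_data(ts, out)
}

#' Gaussian spatial smoothing of a 3D/4D volume
#'
#' Separable Gaussian convolution with the stated full width at half maximum,
#' applied along the three spatial axes (and independently per volume of a 4D
#' array). Kernels are truncated at 4 standard deviations and normalized to
#' unit sum, so total image mass is conserved for interior structure. A FWHM
#' of 0 returns the input bit-identically.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm full width at half maximum in mm (conventionally 0, 4 or 8).
#' @param voxel_mm voxel size in mm: a scalar for isotropic voxels or a
#'   length-3 vector. Anisotropic voxels require `sigma_vox` to be given
#'   explicitly, otherwise an error is raised.
#' @param sigma_vox optional per-axis Gaussian sd in voxel units (length 3),
#'   overriding the FWHM/voxel computation.
#' @return smoothed array, same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_mm = 1, sigma_vox = NULL) {
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L)) stop("volume must be a 3D or 4D array")
  if (fwhm_mm == 0 && is.null(sigma_vox)) return(volume)
  if (is.null(sigma_vox)) {
    voxel_mm <- rep_len(voxel_mm, 3L)
    if (length(unique(voxel_mm)) > 1L) {
      stop("anisotropic voxels: give per-axis sigma_vox explicitly")
    }
    sigma_vox <- rep(fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm[1], 3L)
  }
  sigma_vox <- rep_len(sigma_vox, 3L)
  kernels <- lapply(sigma_vox, function(s) {
    if (s <= 0) return(1)
    r <- ceiling(4 * s)
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  })
  smooth3 <- function(a) {
    d <- dim(a)
    for (ax in 1:3) {
      k <- kernels[[ax]]
      if (length(k) == 1L) next
      a <- aperm(a, c(ax, setdiff(1:3, ax)))
      da <- dim(a)
      m <- matrix(a, da[1], da[2] * da[3])
      r <- (length(k) - 1L) / 2L
      mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
      out <- matrix(0, da[1], ncol(m))
      for (j in seq_along(k)) {
        out <- out + k[j] * mp[(j - 1L) + seq_len(da[1]), , drop = FALSE]
      }
      a <- array(out, da)
      a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
    }
    a
  }
  if (nd == 3L) return(smooth3(volume))
  out <- volume
  for (v in seq_len(dim(volume)[4])) {
    out[, , , v] <- smooth3(volume[, , , v, drop = TRUE])
  }
  out
}

#' Parcel-space analog of volumetric smoothing
#'
#' Gaussian-weighted averaging of parcel signals over inter-parcel distances
#' (row-normalized weights), standing in for voxelwise smoothing when only
#' parcellated data exist -- as in the reproducibility sweep over smoothing
#' kernels. A FWHM of 0 is the identity.
#'
#' @param ts a [parcel_ts()].
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param coords_mm parcels x k matrix of parcel coordinates in mm.
#' @return smoothed [parcel_ts()].
#' @export
smooth_parcels <- function(ts, fwhm_mm, coords_mm) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (fwhm_mm == 0) return(ts)
  coords_mm <- as.matrix(coords_mm)
  if (nrow(coords_mm) != n_parcels(ts)) {
    stop("coords_mm must have one row per parcel")
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(coords_mm))^2
  W <- exp(-d2 / (2 * sigma^2))
  W <- W / rowSums(W)
  ts_with_data(ts, W %*% ts$data)
}

#' Normality check on a connectivity distribution
#'
#' Denoising adequacy check: computes the skewness and excess kurtosis of the
#' Fisher-z off-diagonal connectivity values and passes when |skewness| < 0.5
#' and |excess kurtosis| < 1.0 (conventional cutoffs). A Pearson-r matrix is
#' Fisher-transformed first (values clipped just inside +/-1). Degenerate
#' (zero-variance) distributions fail.
#'
#' @param matrix a `conn_matrix` (Pearson or Fisher-z) or plain symmetric
#'   numeric matrix of correlations.
#' @param max_abs_skew,max_abs_kurtosis pass thresholds.
#' @return list with `skewness`, `kurtosis`, `normality_stat`
#'   (max of the two magnitudes) and `normality_pass`.
#' @export
check_connectivity_normality <- function(matrix, max_abs_skew = 0.5,
                                         max_abs_kurtosis = 1.0) {
  if (inherits(matrix, "conn_matrix")) {
    vals <- matrix$values
    kind <- matrix$kind
  } else {
    vals <- as.matrix(matrix)
    kind <- "pearson-r"
  }
  if (!isSymmetric(unname(vals), tol = 1e-8)) {
    stop("connectivity matrix must be symmetric")
  }
  z <- vals[upper.tri(vals)]
  if (kind == "pearson-r") z <- atanh(pmin(pmax(z, -0.9999), 0.9999))
  if (stats::sd(z) == 0) {
    return(list(skewness = NA_real_, kurtosis = NA_real_,
                normality_stat = Inf, normality_pass = FALSE,
                degenerate = TRUE))
  }
  sk <- e1071::skewness(z)
  ku <- e1071::kurtosis(z)
  list(skewness = sk, kurtosis = ku,
       normality_stat = max(abs(sk), abs(ku)),
       normality_pass = abs(sk) < max_abs_skew && abs(ku) < max_abs_kurtosis,
       degenerate = FALSE)
}

#' Standard denoising chain for one subject
#'
#' Scrub (outlier detection from motion), regress (confounds + spike
#' indicators), then bandpass filter -- the order used throughout the
#' analyses.
#'
#' @param ts a [parcel_ts()].
#' @param confounds a `confound_table`.
#' @param band length-2 band edges in Hz (default 0.01-0.25, clamped at
#'   Nyquist as in [bandpass()]).
#' @param min_dof minimum residual degrees of freedom.
#' @return list with `ts` (denoised) and `report` (band recorded).
#' @export
preprocess_subject <- function(ts, confounds, band = c(0.01, 0.25),
                               min_dof = 30L) {
  flags <- detect_outlier_frames(confounds$motion)
  reg <- regress_confounds(ts, confounds, outlier_flags = flags,
                           min_dof = min_dof)
  out <- suppressWarnings(bandpass(reg$ts, band[1], band[2]))
  nyq <- 1 / (2 * ts$sampling_interval)
  reg$report$band <- c(band[1], min(band[2], 0.99 * nyq))
  list(ts = out, report = reg$report)
}
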