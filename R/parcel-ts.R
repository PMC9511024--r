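#' Parcellated BOLD time series
#'
#' Container for one subject's parcels x timepoints BOLD matrix with its
#' sampling interval (TR, seconds) and parcel labels. All downstream stages
#' (denoising, connectivity, ICA) consume this object.
#'
#' @param data numeric matrix, parcels in rows, timepoints in columns.
#' @param sampling_interval repetition time in seconds.
#' @param subject_id subject identifier.
#' @param parcel_labels character vector, one label per parcel. Defaults to
#'   `parcel_001`, `parcel_002`, ...
#' @return an object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, sampling_interval, subject_id = "subject",
                      parcel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop("time-series data contains missing or non-finite values")
  }
  if (nrow(data) < 2L) stop("need at least 2 parcels")
  if (ncol(data) < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be a positive number of seconds")
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- sprintf("parcel_%03d", seq_len(nrow(data)))
  }
  if (length(parcel_labels) != nrow(data)) {
    stop("parcel_labels length must equal the number of parcels")
  }
  rownames(data) <- parcel_labels
  structure(
    list(subject_id = as.character(subject_id), data = data,
         sampling_interval = sampling_interval,
         parcel_labels = as.character(parcel_labels)),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %s: %d parcels x %d timepoints, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_interval))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

n_timepoints <- function(ts) ncol(ts$data)
n_parcels <- function(ts) nrow(ts$data)

# replace the data matrix, keeping metadata
ts_with_data <- function(ts, data) {
  ts$data <- data
  rownames(ts$data) <- ts$parcel_labels
  ts
}

#' Write / read a parcel time series as TSV
#'
#' Parcels are rows; the header is the timepoint index. The sampling interval
#' is stored in a `# TR=<seconds>` comment on the first line.
#'
#' @param ts a [parcel_ts()].
#' @param path output file path.
#' @export
write_parcel_ts <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR=%.10g subject=%s", ts$sampling_interval, ts$subject_id), con)
  df <- data.frame(parcel = ts$parcel_labels, ts$data, check.names = FALSE)
  colnames(df) <- c("parcel", sprintf("t%03d", seq_len(ncol(ts$data))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_ts
#' @param path input file path.
#' @export
read_parcel_ts <- function(path) {
  header <- readLines(path, n = 1L)
  tr <- as.numeric(sub("^# TR=([0-9.eE+-]+).*$", "\\1", header))
  sid <- sub("^.*subject=(\\S+).*$", "\\1", header)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  parcel_ts(as.matrix(df[, -1, drop = FALSE]), sampling_interval = tr,
            subject_id = sid, parcel_labels = df$parcel)
}
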