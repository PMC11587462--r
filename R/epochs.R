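#' Epoched EEG container
#'
#' Light-weight container for epoched EEG: a numeric array
#' `epoch x channel x time` in microvolts, a uniform time axis in seconds
#' relative to stimulus onset, the sampling rate, channel names, and the
#' electrode layout. Two state flags record whether the data have been
#' average-referenced and baseline-corrected.
#'
#' @param data numeric array, `epoch x channel x time`, microvolts.
#' @param sfreq sampling frequency in Hz.
#' @param times numeric time axis in seconds (length `dim(data)[3]`),
#'   strictly increasing with step `1/sfreq`.
#' @param channels channel names (length `dim(data)[2]`).
#' @param layout optional electrode layout data.frame (`channel`, `x`, `y`).
#' @param baselined,avg_ref state flags.
#' @return an object of class `pg_epochs`.
#' @export
pg_epochs <- function(data, sfreq, times, channels, layout = NULL,
                      baselined = FALSE, avg_ref = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(channels) != dim(data)[2]) stop("channel count mismatch")
  if (length(times) != dim(data)[3]) stop("time axis length mismatch")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / sfreq)) > 1e-6 / sfreq) {
    stop("time axis must be strictly increasing with uniform step 1/sfreq")
  }
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, sfreq = sfreq, times = times,
                 channels = channels, layout = layout,
                 baselined = baselined, avg_ref = avg_ref),
            class = "pg_epochs")
}

#' @export
print.pg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pg_epochs> %d epochs x %d channels x %d samples @ %g Hz, %.3f..%.3f s\n",
    d[1], d[2], d[3], x$sfreq, x$times[1], x$times[length(x$times)]))
  cat(sprintf("  average-referenced: %s, baseline-corrected: %s\n",
              x$avg_ref, x$baselined))
  invisible(x)
}

#' @export
dim.pg_epochs <- function(x) dim(x$data)

n_epochs <- function(epochs) dim(epochs$data)[1]

subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs
}

#' Binned dependent-variable container
#'
#' Participant-level averages of usable epochs in one of the four binning
#' schemes used for the DC-shift analyses: a 5-D array
#' `participant x bin x condition x channel x time` plus contributing epoch
#' counts per cell.
#'
#' @param data 5-D numeric array `participant x bin x condition x channel x time`.
#' @param scheme one of `"onsets_2_8"`, `"partitions"`, `"onset_pairs"`,
#'   `"partition_by_onset_pair"`.
#' @param participants participant identifiers (first dimension).
#' @param bins bin labels (second dimension, partition-major for the
#'   nine-bin scheme).
#' @param conditions condition labels (third dimension).
#' @param channels,times,sfreq signal metadata carried over from the epochs.
#' @param counts integer array `participant x bin x condition` of
#'   contributing epochs (0 marks a missing cell).
#' @return an object of class `pg_binned`.
#' @export
pg_binned <- function(data, scheme, participants, bins, conditions,
                      channels, times, sfreq, counts = NULL) {
  stopifnot(length(dim(data)) == 5)
  if (is.null(counts)) {
    counts <- array(1L, dim = dim(data)[1:3])
  }
  structure(list(data = data, scheme = scheme,
                 participants = participants, bins = bins,
                 conditions = conditions, channels = channels,
                 times = times, sfreq = sfreq, counts = counts),
            class = "pg_binned")
}

#' @export
print.pg_binned <- function(x, ...) {
  cat(sprintf(
    "<pg_binned> scheme '%s': %d participants x %d bins x %s x %d channels x %d samples\n",
    x$scheme, length(x$participants), length(x$bins),
    paste(x$conditions, collapse = "/"), length(x$channels),
    length(x$times)))
  invisible(x)
}

#' Restrict a binned dataset to a time window
#'
#' @param binned a `pg_binned` object.
#' @param window `c(start, end)` in seconds (inclusive).
#' @return the cropped `pg_binned`.
#' @export
crop_window <- function(binned, window) {
  keep <- binned$times >= window[1] & binned$times <= window[2]
  if (!any(keep)) stop("analysis window contains no samples")
  binned$data <- binned$data[, , , , keep, drop = FALSE]
  binned$times <- binned$times[keep]
  binned
}

# Flatten one condition of a pg_binned to the observation-by-sample matrix
# used by the mass-univariate fit. Rows are ordered bin-major with
# participants fastest (all participants of bin 1, then bin 2, ...); columns
# are ordered time-major with channels fastest, matching a
# `matrix(nrow = n_channels)` view of each map.
binned_row_matrix <- function(binned, condition = binned$conditions[1]) {
  ci <- match(condition, binned$conditions)
  if (is.na(ci)) stop("condition '", condition, "' not present")
  arr <- binned$data[, , ci, , , drop = FALSE]
  np <- length(binned$participants); nb <- length(binned$bins)
  nc <- length(binned$channels); nt <- length(binned$times)
  dim(arr) <- c(np, nb, nc, nt)
  arr <- aperm(arr, c(1, 2, 3, 4))       # already (p, b, ch, t)
  dim(arr) <- c(np * nb, nc * nt)
  rows <- data.frame(
    participant = rep(binned$participants, times = nb),
    bin = rep(binned$bins, each = np),
    stringsAsFactors = FALSE)
  list(Y = arr, rows = rows, n_channels = nc, n_times = nt,
       channels = binned$channels, times = binned$times)
}
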