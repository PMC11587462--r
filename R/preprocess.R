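#' Zero-phase Hann-windowed FIR band-pass filter
#'
#' Filters every epoch and channel with a linear-phase windowed-sinc FIR
#' band-pass (Hann window), applied by centred convolution with reflection
#' padding, so the net filter is zero-phase. The kernel is the difference of
#' two unit-DC-gain windowed-sinc low-pass kernels, which makes the DC gain
#' of the band-pass exactly zero regardless of kernel length.
#'
#' The kernel length is chosen from the narrower of the two transition
#' bandwidths (`~3.3 * sfreq / tb` taps, the usual Hann-window rule) and is
#' capped at the epoch length; at that cap the low-edge transition widens
#' rather than the filter failing. Default transition bandwidths follow
#' common windowed-FIR practice for slow-wave EEG work: the low edge uses a
#' transition equal to the edge frequency itself and the high edge uses
#' 7.5 Hz, leaving the sustained (DC-shift) band untouched.
#'
#' @param epochs a [pg_epochs] object.
#' @param low,high band edges in Hz, `0 < low < high < sfreq/2`.
#' @param trans_bandwidth `c(low_tb, high_tb)` transition bandwidths in Hz.
#' @return the filtered [pg_epochs].
#' @export
bandpass_filter <- function(epochs, low = 0.1, high = 30,
                            trans_bandwidth = c(low, 7.5)) {
  sf <- epochs$sfreq
  if (!(low > 0 && low < high && high < sf / 2)) {
    stop("band edges must satisfy 0 < low < high < sfreq/2")
  }
  n_t <- dim(epochs$data)[3]
  h <- fir_bandpass_kernel(sf, low, high, trans_bandwidth, max_len = n_t)
  m <- (length(h) - 1L) / 2L
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_t)
  for (j in seq_len(ncol(flat))) {
    flat[, j] <- fir_apply(flat[, j], h, m)
  }
  epochs$data <- aperm(array(flat, dim = c(n_t, d[1], d[2])), c(2, 3, 1))
  dimnames(epochs$data) <- list(NULL, epochs$channels, NULL)
  epochs
}

# windowed-sinc band-pass kernel (odd length, symmetric, zero DC gain)
fir_bandpass_kernel <- function(sfreq, low, high, trans_bandwidth, max_len) {
  tb <- min(trans_bandwidth)
  if (tb <= 0) stop("transition bandwidths must be positive")
  L <- ceiling(3.3 * sfreq / tb)
  L <- min(L, max_len)
  if (L %% 2 == 0) L <- L - 1L
  if (L < 7) L <- 7L
  k <- seq_len(L) - 1L - (L - 1L) / 2
  win <- as.numeric(signal::hanning(L))
  lp <- function(fc) {
    x <- 2 * fc / sfreq * sinc(2 * fc / sfreq * k) * win
    x / sum(x)                     # unit gain at DC
  }
  lp(high) - lp(low)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# centred convolution with single reflection padding (no edge duplication)
fir_apply <- function(x, h, m) {
  n <- length(x)
  pad <- min(m, n - 1L)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(pad + m + 1):(pad + m + n)]
}

#' Decimate epochs
#'
#' Keeps every `factor`-th sample starting from the first, dividing the
#' sampling rate by `factor`. Anti-alias filtering is the caller's
#' responsibility; running [bandpass_filter()] with a 30 Hz high edge before
#' decimating to >= 64 Hz satisfies it.
#'
#' @param epochs a [pg_epochs] object.
#' @param factor integer decimation factor (>= 1).
#' @return the decimated [pg_epochs].
#' @export
decimate_epochs <- function(epochs, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("decimation factor must be >= 1")
  if (factor == 1) return(epochs)
  keep <- seq(1, dim(epochs$data)[3], by = factor)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times <- epochs$times[keep]
  epochs$sfreq <- epochs$sfreq / factor
  epochs
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' standard average reference. Idempotent.
#'
#' @param epochs a [pg_epochs] object with at least two channels.
#' @return the re-referenced [pg_epochs] (`avg_ref` flag set).
#' @export
rereference_average <- function(epochs) {
  if (dim(epochs$data)[2] < 2) stop("average reference needs >= 2 channels")
  mu <- apply(epochs$data, c(1, 3), mean)        # epoch x time
  epochs$data <- epochs$data - aperm(
    array(mu, dim = c(dim(epochs$data)[1], dim(epochs$data)[3],
                      dim(epochs$data)[2])), c(1, 3, 2))
  epochs$avg_ref <- TRUE
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' window from the whole series.
#'
#' @param epochs a [pg_epochs] object.
#' @param window `c(start, end)` seconds; default the -200..0 ms
#'   pre-stimulus window.
#' @return the corrected [pg_epochs] (`baselined` flag set).
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  mu <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(mu, dim = dim(epochs$data))
  epochs$baselined <- TRUE
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Flags every epoch containing any sample beyond `±limit` microvolts on any
#' channel. Epoch data are left in place; the returned `keep` vector and log
#' let the caller propagate usability into the trial table with
#' [apply_rejections()].
#'
#' @param epochs a [pg_epochs] object.
#' @param limit rejection threshold in microvolts (> 0); default 100.
#' @return list with `keep` (logical per epoch), and `log` (data.frame:
#'   epoch, channel of the extremum, extremum value).
#' @export
reject_threshold <- function(epochs, limit = 100) {
  if (limit <= 0) stop("limit must be positive")
  absmax <- apply(abs(epochs$data), 1, max)
  bad <- which(absmax > limit)
  log <- data.frame(epoch = integer(0), channel = character(0),
                    extremum = numeric(0), stringsAsFactors = FALSE)
  if (length(bad)) {
    log <- do.call(rbind, lapply(bad, function(e) {
      sl <- epochs$data[e, , , drop = TRUE]
      if (is.null(dim(sl))) sl <- matrix(sl, nrow = 1)
      i <- which.max(abs(sl))
      ch <- ((i - 1) %% nrow(sl)) + 1
      data.frame(epoch = e, channel = epochs$channels[ch],
                 extremum = sl[i], stringsAsFactors = FALSE)
    }))
  }
  keep <- rep(TRUE, n_epochs(epochs))
  keep[bad] <- FALSE
  list(keep = keep, log = log)
}

#' Propagate rejections into the trial table
#'
#' @param trial_table trial table with an `epoch` index column.
#' @param keep logical vector over epochs from [reject_threshold()].
#' @return trial table with updated `usable` flags.
#' @export
apply_rejections <- function(trial_table, keep) {
  trial_table$usable <- trial_table$usable & keep[trial_table$epoch]
  trial_table
}

#' Participant inclusion by usable-trial fraction
#'
#' A participant is kept iff the usable fraction of epochs is at least
#' `min_fraction` for every stimulus condition. The boundary is inclusive: a
#' participant at exactly the minimum fraction is retained.
#'
#' @param trial_table trial table with `usable` flags populated.
#' @param min_fraction required usable proportion per condition, default 0.2.
#' @return sorted vector of retained participant ids.
#' @export
include_participants <- function(trial_table, min_fraction = 0.2) {
  if (nrow(trial_table) == 0) stop("empty trial table")
  frac <- stats::aggregate(usable ~ participant + stimulus,
                           data = trial_table, FUN = mean)
  ok <- stats::aggregate(usable ~ participant, data = frac,
                         FUN = function(u) all(u >= min_fraction))
  sort(ok$participant[ok$usable])
}

scheme_bins <- function(scheme, n_partitions = 3) {
  switch(scheme,
    onsets_2_8 = "onsets_2_8",
    partitions = paste0("P", seq_len(n_partitions)),
    onset_pairs = c("O23", "O45", "O67"),
    partition_by_onset_pair = as.vector(t(outer(
      paste0("P", seq_len(n_partitions)), c("O23", "O45", "O67"),
      paste, sep = "_"))),
    stop("unknown binning scheme '", scheme, "'"))
}

# bin label for each trial-table row under a scheme; NA = contributes nowhere.
# Onsets 1 and 9 are excluded everywhere (surprise / too-infrequent); onset 8
# enters only the schemes that pool onsets 2-8.
scheme_bin_of <- function(scheme, onset, partition) {
  pair_lab <- c(NA, "O23", "O23", "O45", "O45", "O67", "O67", NA, NA)[onset]
  switch(scheme,
    onsets_2_8 = ifelse(onset >= 2 & onset <= 8, "onsets_2_8", NA),
    partitions = ifelse(onset >= 2 & onset <= 8,
                        paste0("P", partition), NA),
    onset_pairs = pair_lab,
    partition_by_onset_pair = ifelse(is.na(pair_lab), NA,
                                     paste0("P", partition, "_", pair_lab)),
    stop("unknown binning scheme '", scheme, "'"))
}

#' Average usable epochs into analysis bins
#'
#' Builds one of the four dependent-variable datasets: per participant,
#' condition, and bin, the arithmetic mean over usable epochs whose onset
#' index belongs to the bin. Onset 1 (surprise) and onset 9 (too infrequent)
#' contribute to no scheme; onset 8 contributes to the onsets-2-8 and
#' partition schemes but to no onset-pair bin. Cells with zero usable epochs
#' are `NA` with count 0.
#'
#' @param epochs preprocessed [pg_epochs].
#' @param trial_table trial table aligned with the epochs (`epoch` column).
#' @param scheme `"onsets_2_8"`, `"partitions"`, `"onset_pairs"`, or
#'   `"partition_by_onset_pair"`.
#' @param participants participants to include (default: all present).
#' @return a [pg_binned] object with conditions thin/medium/thick.
#' @export
bin_average <- function(epochs, trial_table, scheme,
                        participants = sort(unique(trial_table$participant))) {
  bins <- scheme_bins(scheme)
  if (!all(participants %in% trial_table$participant)) {
    stop("participant absent from the trial table")
  }
  nch <- length(epochs$channels); nt <- length(epochs$times)
  np <- length(participants); nb <- length(bins)
  conds <- stimulus_levels
  dat <- array(NA_real_, dim = c(np, nb, length(conds), nch, nt))
  counts <- array(0L, dim = c(np, nb, length(conds)))
  tt <- trial_table[trial_table$usable &
                      trial_table$participant %in% participants, ]
  tt$binlab <- scheme_bin_of(scheme, tt$onset, tt$partition)
  tt <- tt[!is.na(tt$binlab), ]
  if (nrow(tt)) {
    grp <- interaction(match(tt$participant, participants),
                       match(tt$binlab, bins),
                       match(tt$stimulus, conds), drop = TRUE)
    for (g in levels(grp)) {
      rows <- tt[grp == g, ]
      p <- match(rows$participant[1], participants)
      b <- match(rows$binlab[1], bins)
      cc <- match(rows$stimulus[1], conds)
      sl <- epochs$data[rows$epoch, , , drop = FALSE]
      dat[p, b, cc, , ] <- colMeans(sl, dims = 1)
      counts[p, b, cc] <- nrow(rows)
    }
  }
  pg_binned(dat, scheme, participants, bins, conds,
            epochs$channels, epochs$times, epochs$sfreq, counts)
}

#' Drop participants with missing cells
#'
#' Removes participants with any zero-count (missing) cell among the
#' scheme's required participant x bin x condition cells, mirroring the
#' per-analysis inclusion counts of multi-scheme studies.
#'
#' @param binned a [pg_binned] object.
#' @return the filtered [pg_binned].
#' @export
drop_incomplete <- function(binned) {
  ok <- apply(binned$counts > 0, 1, all)
  binned$data <- binned$data[ok, , , , , drop = FALSE]
  binned$counts <- binned$counts[ok, , , drop = FALSE]
  binned$participants <- binned$participants[ok]
  binned
}

#' Pattern Glare Index
#'
#' The PGI contrast `medium - (thick + thin) / 2`, computed elementwise over
#' channel x time for every participant and bin. Values beyond zero in
#' either direction index responses to the aggravating medium grating more
#' extreme than the control midpoint, the operational signature of
#' hyper-excitation.
#'
#' @param binned a [pg_binned] with all three stimulus conditions.
#' @return a [pg_binned] with the single derived condition `"PGI"`.
#' @export
compute_pgi <- function(binned) {
  need <- c("thin", "medium", "thick")
  idx <- match(need, binned$conditions)
  if (anyNA(idx)) stop("missing condition: ",
                       paste(need[is.na(idx)], collapse = ", "))
  if (any(binned$counts[, , idx] == 0)) {
    stop("missing condition cell; run drop_incomplete() first")
  }
  pgi <- binned$data[, , idx[2], , , drop = FALSE] -
    (binned$data[, , idx[1], , , drop = FALSE] +
       binned$data[, , idx[3], , , drop = FALSE]) / 2
  cnt <- array(apply(binned$counts[, , idx, drop = FALSE], c(1, 2), min),
               dim = c(dim(binned$counts)[1:2], 1L))
  pg_binned(pgi, binned$scheme, binned$participants, binned$bins, "PGI",
            binned$channels, binned$times, binned$sfreq, cnt)
}
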