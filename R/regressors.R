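#' Design regressor container
#'
#' One value per observation row of a binned dataset. Rows are ordered
#' bin-major with participants fastest (for the nine-bin scheme, bins are
#' partition-major then onset-pair), matching [pg_binned] exactly.
#'
#' @param values numeric vector, one per row.
#' @param rows data.frame with `participant` and `bin` in row order.
#' @param factor factor name (e.g. `"discomfort"`, `"intercept"`).
#' @param granularity `"none"`, `"onset_pairs"`, `"partitions"`, or
#'   `"both"`.
#' @param direction character; per-granularity change direction
#'   (`"increase"`, `"decrease"`, or `"none"`).
#' @param orthogonalized,centred state flags.
#' @return object of class `pg_regressor`.
#' @export
design_regressor <- function(values, rows, factor, granularity = "none",
                             direction = "none", orthogonalized = FALSE,
                             centred = FALSE) {
  stopifnot(length(values) == nrow(rows))
  structure(list(values = as.numeric(values), rows = rows, factor = factor,
                 granularity = granularity, direction = direction,
                 orthogonalized = orthogonalized, centred = centred),
            class = "pg_regressor")
}

#' @export
print.pg_regressor <- function(x, ...) {
  cat(sprintf(
    "<pg_regressor> %s (%s %s), %d rows, centred=%s, orthogonalized=%s\n",
    x$factor, x$granularity, paste(x$direction, collapse = "/"),
    length(x$values), x$centred, x$orthogonalized))
  invisible(x)
}

regressor_rows <- function(participants, bins) {
  data.frame(participant = rep(participants, times = length(bins)),
             bin = rep(bins, each = length(participants)),
             stringsAsFactors = FALSE)
}

#' Intercept regressor
#'
#' All-ones regressor testing the across-participant mean: with mean-centred
#' covariates, its slope is the grand mean of the PGI, so inference on it is
#' a one-sample test of the PGI against zero (implemented directly with
#' sign-flip permutation rather than through a duplicated-zero two-sample
#' construction, to which it is mathematically equivalent).
#'
#' @param rows row index data.frame (`participant`, `bin`), or a
#'   [pg_binned] whose rows to use.
#' @return a `pg_regressor`.
#' @export
intercept_regressor <- function(rows) {
  if (inherits(rows, "pg_binned")) {
    rows <- regressor_rows(rows$participants, rows$bins)
  }
  if (nrow(rows) < 2) stop("need at least 2 rows")
  design_regressor(rep(1, nrow(rows)), rows, "intercept")
}

#' Plain factor regressor
#'
#' Mean-centred factor scores tiled across the bins of the target scheme
#' (for the single-bin onsets-2-8 scheme this is the classic one-number-per-
#' participant covariate).
#'
#' @param scores named numeric vector of factor scores (names = participant
#'   ids, in the binned participant order).
#' @param bins bin labels of the target scheme (default single bin).
#' @param factor factor name for the metadata.
#' @return a centred `pg_regressor`.
#' @export
factor_regressor <- function(scores, bins = "onsets_2_8",
                             factor = "factor") {
  v <- rep(as.numeric(scores), times = length(bins))
  v <- v - mean(v)
  design_regressor(v, regressor_rows(names(scores), bins), factor,
                   centred = TRUE)
}

#' Exponential change pattern
#'
#' Per-bin weights of the habituation / sensitisation model: a decrease is
#' `w_k = exp(-rate * (k - 1))`, `k = 1..n_bins`; an increase is the same
#' sequence reversed. Weights are strictly monotone and positive.
#'
#' @param n_bins number of bins (>= 2).
#' @param direction `"decrease"` or `"increase"`.
#' @param rate exponential rate per bin step (> 0), default 1.
#' @return list of class `pg_change_pattern` with `weights`, `rate`,
#'   `direction`.
#' @export
exponential_weights <- function(n_bins, direction = c("decrease", "increase"),
                                rate = 1) {
  direction <- match.arg(direction)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (rate <= 0) stop("rate must be > 0")
  w <- exp(-rate * (seq_len(n_bins) - 1))
  if (direction == "increase") w <- rev(w)
  structure(list(weights = w, rate = rate, direction = direction),
            class = "pg_change_pattern")
}

shift_nonnegative <- function(scores) {
  if (length(unique(scores)) == 1) {
    warning("all factor scores equal: interaction regressor reduces to ",
            "the pure change pattern")
  }
  scores - min(scores)
}

#' Two-way factor-by-change interaction regressor
#'
#' Construction: (1) shift the factor scores to be non-negative by
#' subtracting their minimum; (2) tile the shifted scores once per bin;
#' (3) multiply each bin's copy by the bin's exponential change weight;
#' (4) mean-centre the full vector. Row order is bin-major, participants
#' fastest.
#'
#' @param scores named factor scores (names = participant ids).
#' @param pattern a `pg_change_pattern` over the target bins.
#' @param bins bin labels (defaults to `P1..Pn` partitions, or `O23/O45/O67`
#'   when `granularity = "onset_pairs"`).
#' @param factor factor name.
#' @param granularity `"partitions"` or `"onset_pairs"`.
#' @return a centred `pg_regressor`.
#' @export
two_way_regressor <- function(scores, pattern, bins = NULL,
                              factor = "discomfort",
                              granularity = c("partitions", "onset_pairs")) {
  granularity <- match.arg(granularity)
  nb <- length(pattern$weights)
  if (is.null(bins)) {
    bins <- if (granularity == "partitions") paste0("P", seq_len(nb))
            else c("O23", "O45", "O67")[seq_len(nb)]
  }
  stopifnot(length(bins) == nb)
  s <- shift_nonnegative(as.numeric(scores))
  v <- as.vector(outer(s, pattern$weights))    # participants fastest
  v <- v - mean(v)
  design_regressor(v, regressor_rows(names(scores), bins), factor,
                   granularity, pattern$direction, centred = TRUE)
}

#' Three-way factor-by-onset-change-by-partition-change regressor
#'
#' The shifted factor scores are tiled over the three onset-pairs and
#' multiplied by the onset-pair change weights; that nine-participant-block
#' vector is tiled over the three partitions and multiplied by the partition
#' change weights; the result is mean-centred. For one participant the 3x3
#' cell grid is the outer product of the two weight vectors scaled by the
#' shifted score. Bins are ordered partition-major then onset-pair, matching
#' the partition-by-onset-pair binning.
#'
#' @param scores named factor scores.
#' @param onset_pattern,partition_pattern length-3 `pg_change_pattern`s.
#' @param factor factor name.
#' @return a centred `pg_regressor` over 9 bins.
#' @export
three_way_regressor <- function(scores, onset_pattern, partition_pattern,
                                factor = "discomfort") {
  stopifnot(length(onset_pattern$weights) == 3,
            length(partition_pattern$weights) == 3)
  s <- shift_nonnegative(as.numeric(scores))
  bins <- scheme_bins("partition_by_onset_pair")
  w <- as.vector(t(outer(partition_pattern$weights,
                         onset_pattern$weights)))  # partition-major bins
  v <- as.vector(outer(s, w))
  v <- v - mean(v)
  design_regressor(v, regressor_rows(names(scores), bins), factor, "both",
                   c(onset_pattern$direction, partition_pattern$direction),
                   centred = TRUE)
}

#' Orthogonalise a set of regressors
#'
#' Gram-Schmidt in the fixed factor order (visual stress, headache,
#' discomfort): the first regressor is unchanged and every later one has its
#' projections onto the earlier ones removed. Since projection removal among
#' mean-centred vectors preserves centring, outputs stay centred; they are
#' re-centred to guard against floating-point drift and the invariant is
#' asserted.
#'
#' @param regressors ordered list of `pg_regressor`s sharing one row index.
#' @return list of orthogonalised `pg_regressor`s.
#' @export
orthogonalize_design <- function(regressors) {
  rows <- regressors[[1]]$rows
  for (r in regressors) {
    if (!identical(r$rows, rows)) stop("regressor row indices differ")
  }
  vals <- gram_schmidt(lapply(regressors, `[[`, "values"))
  for (i in seq_along(regressors)) {
    v <- vals[[i]]
    if (regressors[[i]]$centred) {
      stopifnot(abs(mean(v)) < 1e-8 * max(sqrt(mean(v^2)), 1))
      v <- v - mean(v)
    }
    regressors[[i]]$values <- v
    regressors[[i]]$orthogonalized <- TRUE
  }
  regressors
}
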