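#' In-experiment discomfort index
#'
#' Per participant, the mean discomfort rating for the medium stimulus minus
#' the mean over the pooled thin and thick ratings, across all blocks.
#' Participants who found the aggravating medium grating more uncomfortable
#' than the controls score positive. Ratings are pooled (not averaged per
#' stimulus first), which is equivalent when trial counts are balanced and
#' more robust when they are not.
#'
#' @param trial_table trial table with `participant`, `stimulus`, `trial`,
#'   `partition`, `rating` columns (one row per onset is fine; ratings are
#'   collapsed to one per trial first).
#' @return data.frame with `participant` and `discomfort_index`.
#' @export
discomfort_index <- function(trial_table) {
  tt <- unique(trial_table[, c("participant", "stimulus", "partition",
                               "trial", "rating")])
  out <- lapply(split(tt, tt$participant), function(d) {
    if (!all(stimulus_levels %in% d$stimulus)) {
      stop("participant ", d$participant[1],
           " is missing ratings for a stimulus type")
    }
    med <- d$rating[d$stimulus == "medium"]
    ctl <- d$rating[d$stimulus %in% c("thin", "thick")]
    data.frame(participant = d$participant[1],
               discomfort_index = mean(med) - mean(ctl))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant), , drop = FALSE]
}

#' Standardise behavioural measures
#'
#' Z-scores every measure column (sample SD, `n - 1` denominator). The
#' questionnaire totals have very different ranges, so standardisation is
#' required before factoring.
#'
#' @param measures data.frame; a `participant` column, if present, is passed
#'   through untouched.
#' @return the standardised data.frame.
#' @export
standardize_measures <- function(measures) {
  out <- measures
  for (nm in setdiff(names(measures), "participant")) {
    x <- measures[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("measure '", nm, "' has zero variance and cannot be standardised")
    }
    out[[nm]] <- (x - mean(x)) / s
  }
  out
}

#' Extract rotated factors from standardised measures
#'
#' Principal-component factor extraction on the measure correlation matrix,
#' varimax rotation (started from the identity, hence deterministic), and
#' regression (Thomson) factor scores. The eigenvalue sequence of the
#' correlation matrix is returned for scree inspection; the number of
#' factors is fixed by the caller rather than detected automatically.
#' Loading columns are sign-fixed so the largest-magnitude loading in each
#' column is positive, and ordered by explained variance.
#'
#' @param z_table standardised measures ([standardize_measures()] output).
#' @param k number of factors (default 3).
#' @return list of class `pg_factors`: `scores` (participant x k, mean 0),
#'   `loadings` (measure x k), `eigenvalues`, `rotation_converged`.
#' @export
extract_factors <- function(z_table, k = 3) {
  X <- as.matrix(z_table[, setdiff(names(z_table), "participant")])
  if (nrow(X) <= ncol(X)) stop("need more participants than measures")
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  L0 <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  # Kaiser-normalised varimax, guarding zero-communality rows
  h <- sqrt(rowSums(L0^2))
  hs <- ifelse(h > 1e-12, h, 1)
  rot <- stats::varimax(L0 / hs, normalize = FALSE, eps = 1e-8)
  L <- (L0 / hs) %*% rot$rotmat * hs
  # deterministic sign and order conventions
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("F", seq_len(k))
  scores <- X %*% MASS::ginv(R) %*% L  # regression / Thomson scores
                                       # (ginv tolerates the singular R of
                                       #  noise-free block structures)
  scores <- sweep(scores, 2, colMeans(scores))
  colnames(scores) <- colnames(L)
  structure(list(scores = scores, loadings = L, eigenvalues = e$values,
                 rotation_converged = TRUE),
            class = "pg_factors")
}

#' Label factors by their dominant measure block
#'
#' Assigns the labels visual stress, headache, and discomfort to the three
#' rotated factors by greedy best match on the mean absolute loading of each
#' label's measure block (visual stress: CHi and VDS; headache: frequency,
#' intensity, duration, aura; discomfort: the in-experiment discomfort
#' index). Errors if an assignment is ambiguous.
#'
#' @param loadings measure x factor loading matrix with the measure names of
#'   [simulate_behavioral()] plus `discomfort_index` as row names.
#' @param groups optional named list overriding the label -> measures map.
#' @return named character vector: factor column name -> label.
#' @export
label_factors <- function(loadings, groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      visual_stress = c("chi", "vds"),
      headache = c("headache_frequency", "headache_intensity",
                   "headache_duration", "sensory_aura"),
      discomfort = "discomfort_index")
  }
  if (ncol(loadings) != length(groups)) {
    stop("need as many factors as labels")
  }
  score <- sapply(groups, function(ms) {
    ms <- intersect(ms, rownames(loadings))
    if (!length(ms)) stop("no loading rows for a label's measure block")
    colMeans(abs(loadings[ms, , drop = FALSE]))
  })                                    # factor x label
  labels <- stats::setNames(rep(NA_character_, ncol(loadings)),
                            colnames(loadings))
  for (step in seq_along(groups)) {
    best <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1) {
      stop("ambiguous factor labelling: tied loadings for ",
           paste(colnames(score)[unique(best[, 2])], collapse = " and "))
    }
    labels[rownames(score)[best[1]]] <- colnames(score)[best[2]]
    score[best[1], ] <- NA
    score[, best[2]] <- NA
  }
  labels
}

#' Gram-Schmidt orthogonalisation
#'
#' Sequentially removes from each vector its projections onto all earlier
#' (already orthogonalised) vectors. The first vector is returned unchanged
#' and no normalisation is applied, so earlier vectors keep their scale and
#' later vectors become the residuals after regressing out the earlier ones.
#'
#' @param vectors a list of equal-length numeric vectors, or a matrix whose
#'   columns are the vectors, in the orthogonalisation order.
#' @param tol relative tolerance below which a residual counts as collinear.
#' @return a list of orthogonalised vectors (same order).
#' @export
gram_schmidt <- function(vectors, tol = 1e-12) {
  if (is.matrix(vectors)) {
    vectors <- lapply(seq_len(ncol(vectors)), function(j) vectors[, j])
  }
  n <- length(vectors[[1]])
  if (any(vapply(vectors, length, 1L) != n)) {
    stop("vectors must have equal length")
  }
  if (sqrt(sum(vectors[[1]]^2)) == 0) stop("first vector is zero")
  out <- vectors
  for (i in seq_along(out)) {
    v <- out[[i]]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        u <- out[[j]]
        v <- v - (sum(u * v) / sum(u * u)) * u
      }
    }
    if (sqrt(sum(v^2)) < tol * max(sqrt(sum(vectors[[i]]^2)), 1)) {
      stop("vector ", i, " is numerically collinear with its predecessors")
    }
    out[[i]] <- v
  }
  out
}
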