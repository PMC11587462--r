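#' Channel adjacency graph from electrode positions
#'
#' Two channels are neighbours iff their Euclidean layout distance is at
#' most `distance_threshold`. Spatial clustering of channel x time samples
#' requires this neighbourhood structure.
#'
#' @param layout electrode layout (`channel`, `x`, `y`).
#' @param distance_threshold layout-distance threshold.
#' @return list of class `pg_adjacency`: symmetric logical `matrix` (no
#'   self-loops), per-channel `neighbors` index list, `mean_degree`.
#' @export
build_adjacency <- function(layout, distance_threshold) {
  if (nrow(layout) < 2) stop("need >= 2 channels")
  if (anyDuplicated(layout[, c("x", "y")])) {
    stop("channel positions must be distinct")
  }
  D <- as.matrix(stats::dist(layout[, c("x", "y")]))
  A <- D <= distance_threshold
  diag(A) <- FALSE
  dimnames(A) <- list(layout$channel, layout$channel)
  if (!any(A)) warning("adjacency threshold yields an edgeless graph")
  structure(list(matrix = A,
                 neighbors = lapply(seq_len(nrow(A)), function(i) which(A[i, ])),
                 mean_degree = mean(rowSums(A))),
            class = "pg_adjacency")
}

t_cap <- 1e6   # cap for degenerate zero-residual fits

#' Samplewise regression t-map
#'
#' Fits, independently at every channel x time sample, an ordinary
#' least-squares model of the observations on `[1, regressor]` and returns
#' the slope t-statistic; for the intercept regressor the statistic is the
#' one-sample t of the mean against zero. Degenerate zero-residual fits are
#' capped at `1e6` (sign kept) and flagged.
#'
#' @param binned a [pg_binned] holding the PGI (single condition).
#' @param regressor a `pg_regressor` row-aligned with `binned`.
#' @return list of class `pg_statmap`: `t` (channel x time matrix), `df`,
#'   `n_rows`, `n_participants`, `capped`, `channels`, `times`, regressor
#'   metadata.
#' @export
samplewise_stat <- function(binned, regressor) {
  rm <- binned_row_matrix(binned)
  check_alignment(rm$rows, regressor)
  Y <- rm$Y
  n <- nrow(Y)
  if (regressor$factor == "intercept") {
    df <- n - 1L
    if (df < 1) stop("fewer rows than model parameters")
    m <- colMeans(Y)
    v <- (colSums(Y^2) - n * m^2) / df
    tval <- m / sqrt(pmax(v, 0) / n)
  } else {
    df <- n - 2L
    if (df < 1) stop("fewer rows than model parameters")
    x <- regressor$values - mean(regressor$values)
    sxx <- sum(x^2)
    if (sxx == 0) stop("regressor is constant")
    Yc <- sweep(Y, 2, colMeans(Y))
    sxy <- as.vector(crossprod(Yc, x))
    syy <- colSums(Yc^2)
    denom <- sxx * syy - sxy^2
    tval <- sxy * sqrt(df) / sqrt(pmax(denom, 0))
  }
  capped <- !is.finite(tval) | abs(tval) > t_cap
  tval[is.nan(tval)] <- 0
  tval[tval == Inf] <- t_cap
  tval[tval == -Inf] <- -t_cap
  tval <- pmin(pmax(tval, -t_cap), t_cap)
  tmat <- matrix(tval, nrow = rm$n_channels)
  dimnames(tmat) <- list(rm$channels, NULL)
  structure(list(t = tmat, df = df, n_rows = n,
                 n_participants = length(binned$participants),
                 capped = any(capped),
                 channels = rm$channels, times = rm$times,
                 regressor = regressor$factor,
                 granularity = regressor$granularity,
                 direction = regressor$direction),
            class = "pg_statmap")
}

check_alignment <- function(rows, regressor) {
  if (!identical(nrow(rows), nrow(regressor$rows)) ||
      !identical(as.character(rows$participant),
                 as.character(regressor$rows$participant)) ||
      !identical(as.character(rows$bin), as.character(regressor$rows$bin))) {
    stop("regressor rows are not aligned with the binned data rows")
  }
  invisible(TRUE)
}

# connected components of suprathreshold samples under spatial adjacency at
# equal time plus temporal succession at equal channel; returns a list of
# integer sample-index vectors (column-major index into the ch x time map)
connected_components <- function(supra, nch, nt, neighbors) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  inset <- logical(nch * nt)
  inset[idx] <- TRUE
  visited <- logical(nch * nt)
  comps <- list()
  stack <- integer(length(idx))
  for (s0 in idx) {
    if (visited[s0]) next
    top <- 1L
    stack[1L] <- s0
    visited[s0] <- TRUE
    members <- integer(0)
    while (top > 0L) {
      s <- stack[top]; top <- top - 1L
      members <- c(members, s)
      ch <- ((s - 1L) %% nch) + 1L
      tt <- ((s - 1L) %/% nch) + 1L
      nb <- neighbors[[ch]] + (tt - 1L) * nch
      if (tt > 1L) nb <- c(nb, s - nch)
      if (tt < nt) nb <- c(nb, s + nch)
      for (q in nb) {
        if (inset[q] && !visited[q]) {
          visited[q] <- TRUE
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# maximum |sum of t| over clusters of one tail; 0 when no sample is
# suprathreshold. tvec is the flattened ch-fastest t map.
max_cluster_mass <- function(tvec, tcrit, nch, nt, neighbors, tail) {
  supra <- if (tail > 0) tvec > tcrit else tvec < -tcrit
  comps <- connected_components(supra, nch, nt, neighbors)
  if (!length(comps)) return(0)
  max(vapply(comps, function(m) abs(sum(tvec[m])), 0))
}

#' Form suprathreshold clusters
#'
#' Thresholds the t-map at the Student-t quantile of the per-tail forming
#' probability and groups suprathreshold samples into connected components
#' under channel adjacency (same timepoint) plus temporal succession (same
#' channel). Cluster mass is the sum of member t-values; clusters are sorted
#' by decreasing `|mass|`.
#'
#' @param stat_map a `pg_statmap`.
#' @param adjacency a `pg_adjacency` over the map's channels.
#' @param forming_alpha per-tail tail probability of the forming threshold
#'   (default 0.025).
#' @param tail `+1` (positive) or `-1` (negative).
#' @return list of clusters; each has `members` (data.frame channel, time,
#'   t), `member_index` (column-major sample indices), `mass`, `tail`,
#'   `n_samples`, `time_range`.
#' @export
form_clusters <- function(stat_map, adjacency, forming_alpha = 0.025,
                          tail = 1) {
  stopifnot(tail %in% c(-1, 1))
  tcrit <- stats::qt(1 - forming_alpha, df = stat_map$df)
  nch <- nrow(stat_map$t); nt <- ncol(stat_map$t)
  tvec <- as.vector(stat_map$t)
  supra <- if (tail > 0) tvec > tcrit else tvec < -tcrit
  comps <- connected_components(supra, nch, nt, adjacency$neighbors)
  clusters <- lapply(comps, function(m) {
    ch <- ((m - 1L) %% nch) + 1L
    tt <- ((m - 1L) %/% nch) + 1L
    list(members = data.frame(channel = stat_map$channels[ch],
                              time = stat_map$times[tt],
                              t = tvec[m], stringsAsFactors = FALSE),
         member_index = m,
         mass = sum(tvec[m]), tail = tail, n_samples = length(m),
         time_range = range(stat_map$times[tt]))
  })
  clusters[order(vapply(clusters, function(cl) abs(cl$mass), 0),
                 decreasing = TRUE)]
}

all_sign_matrix <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation null distributions of the maximum cluster mass
#'
#' Monte-Carlo (or exhaustive) permutation null of the per-tail maximum
#' cluster `|mass|`. Two exchangeability schemes: `sign_flip` multiplies
#' each participant's whole PGI block (all bins, channels, times) by +-1,
#' appropriate for the intercept / one-sample analysis; `participant_shuffle`
#' permutes whole participant row-blocks of the regressor, keeping each
#' participant's within-bin pattern attached, appropriate for
#' between-participant covariates.
#'
#' @param binned a [pg_binned] (PGI).
#' @param regressor aligned `pg_regressor`.
#' @param adjacency `pg_adjacency`.
#' @param n_perm number of random permutations (warns below 100).
#' @param scheme `"sign_flip"` or `"participant_shuffle"`; default picked
#'   from the regressor (intercept -> sign_flip).
#' @param seed integer RNG seed.
#' @param forming_alpha per-tail forming threshold probability.
#' @param exhaustive enumerate all distinct permutations instead of
#'   sampling (sign flips: `2^n`; shuffles: `n!`, small n only).
#' @return list of class `pg_perm_null`: `pos`, `neg` (max-|mass| vectors),
#'   `n_perm`, `scheme`, `exhaustive`.
#' @export
permutation_null <- function(binned, regressor, adjacency, n_perm = 10000,
                             scheme = NULL, seed = 1L,
                             forming_alpha = 0.025, exhaustive = FALSE) {
  if (is.null(scheme)) {
    scheme <- if (regressor$factor == "intercept") "sign_flip"
              else "participant_shuffle"
  }
  scheme <- match.arg(scheme, c("sign_flip", "participant_shuffle"))
  rm <- binned_row_matrix(binned)
  check_alignment(rm$rows, regressor)
  Y <- rm$Y
  n <- nrow(Y)
  np <- length(binned$participants)
  part_of_row <- match(rm$rows$participant, binned$participants)
  nch <- rm$n_channels; nt <- rm$n_times
  nb <- length(binned$bins)

  if (exhaustive) {
    P <- if (scheme == "sign_flip") all_sign_matrix(np) else {
      if (np > 8) stop("exhaustive shuffle limited to 8 participants")
      all_permutations(np)
    }
    n_perm <- nrow(P)
  } else {
    if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
    set.seed(seed)
    P <- if (scheme == "sign_flip") {
      matrix(sample(c(-1, 1), n_perm * np, replace = TRUE), n_perm, np)
    } else {
      t(replicate(n_perm, sample.int(np)))
    }
  }

  intercept <- regressor$factor == "intercept"
  if (intercept) {
    df <- n - 1L
    ss <- colSums(Y^2)
  } else {
    df <- n - 2L
    x <- regressor$values - mean(regressor$values)
    sxx <- sum(x^2)
    Yc <- sweep(Y, 2, colMeans(Y))
    syy <- colSums(Yc^2)
    # row-level gather for participant permutation pi:
    # x_perm[row(b,p)] = x[row(b, pi(p))]
    row_of <- matrix(seq_len(n), np, nb)   # [participant, bin] -> row
  }
  tcrit <- stats::qt(1 - forming_alpha, df = df)

  pos <- numeric(n_perm); neg <- numeric(n_perm)
  chunk <- 256L
  for (start in seq(1L, n_perm, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n_perm)
    if (intercept) {
      Srow <- P[ii, part_of_row, drop = FALSE]
      M <- (Srow %*% Y) / n
      V <- sweep(-n * M^2, 2, ss, `+`) / df
      Tm <- M / sqrt(pmax(V, 0) / n)
    } else {
      Xp <- t(apply(P[ii, , drop = FALSE], 1, function(pp) {
        x[as.vector(row_of[pp, ])]
      }))
      if (length(ii) == 1) Xp <- matrix(Xp, nrow = 1)
      Sxy <- Xp %*% Yc
      denom <- sxx * matrix(syy, length(ii), ncol(Y), byrow = TRUE) - Sxy^2
      Tm <- Sxy * sqrt(df) / sqrt(pmax(denom, 0))
    }
    Tm[is.nan(Tm)] <- 0
    Tm[Tm > t_cap] <- t_cap
    Tm[Tm < -t_cap] <- -t_cap
    for (r in seq_along(ii)) {
      tv <- Tm[r, ]
      pos[ii[r]] <- max_cluster_mass(tv, tcrit, nch, nt,
                                     adjacency$neighbors, 1)
      neg[ii[r]] <- max_cluster_mass(tv, tcrit, nch, nt,
                                     adjacency$neighbors, -1)
    }
  }
  structure(list(pos = pos, neg = neg, n_perm = n_perm, scheme = scheme,
                 exhaustive = exhaustive, forming_alpha = forming_alpha),
            class = "pg_perm_null")
}

#' Monte-Carlo cluster p-values
#'
#' For each cluster, `p = (b + 1) / (m + 1)` where `b` is the number of
#' permutations whose max `|mass|` on the cluster's tail reaches the
#' cluster's `|mass|` (so p is never exactly zero). For exhaustive nulls the
#' identity permutation is already enumerated and `p = b / m` is the exact
#' permutation p-value.
#'
#' @param clusters cluster list from [form_clusters()].
#' @param null a `pg_perm_null`.
#' @param alpha per-tail significance level for the `significant` flag.
#' @return the clusters, each gaining `p_value` and `significant`.
#' @export
cluster_pvalues <- function(clusters, null, alpha = 0.05) {
  lapply(clusters, function(cl) {
    dist <- if (cl$tail > 0) null$pos else null$neg
    # tolerance so a permutation recomputing the observed statistic (e.g. the
    # identity sign assignment in an exhaustive null) counts as reaching it
    tol <- 1e-8 * (1 + abs(cl$mass))
    b <- sum(dist >= abs(cl$mass) - tol)
    cl$p_value <- if (null$exhaustive) b / null$n_perm
                  else (b + 1) / (null$n_perm + 1)
    cl$significant <- cl$p_value <= alpha
    cl
  })
}

#' Cluster effect sizes at the peak sample
#'
#' At the cluster's peak sample (maximum `|t|`):
#' `r = sign(t) * sqrt(t^2 / (t^2 + df))`, one-sample
#' `d = t / sqrt(n_participants)`, and regression `d = 2 t / sqrt(df)`.
#' Both d conventions are computed and labelled.
#'
#' @param cluster one cluster from [form_clusters()].
#' @param n_participants participant count of the analysis.
#' @param df model degrees of freedom.
#' @return the cluster, gaining `peak_time`, `peak_t`, `r`, `d_one_sample`,
#'   `d_regression`.
#' @export
effect_sizes <- function(cluster, n_participants, df) {
  if (df <= 0) stop("df must be positive")
  if (!length(cluster$member_index)) stop("empty cluster")
  i <- which.max(abs(cluster$members$t))
  tv <- cluster$members$t[i]
  cluster$peak_time <- cluster$members$time[i]
  cluster$peak_t <- tv
  cluster$r <- sign(tv) * sqrt(tv^2 / (tv^2 + df))
  cluster$d_one_sample <- tv / sqrt(n_participants)
  cluster$d_regression <- 2 * tv / sqrt(df)
  cluster
}

#' Peak electrode of a cluster
#'
#' The electrode with the most member timepoints in the cluster (the largest
#' temporal extent of the effect); ties are broken by larger summed `|t|`,
#' then by channel-name order.
#'
#' @param cluster one cluster from [form_clusters()].
#' @return the electrode name.
#' @export
select_peak_electrode <- function(cluster) {
  if (!length(cluster$member_index)) stop("empty cluster")
  m <- cluster$members
  agg <- stats::aggregate(cbind(count = rep(1, nrow(m)), abst = abs(m$t)),
                          by = list(channel = m$channel), FUN = sum)
  agg <- agg[order(-agg$count, -agg$abst, agg$channel), ]
  agg$channel[1]
}

#' Run a mass-univariate cluster-permutation analysis set
#'
#' For every named regressor: restrict the PGI to the analysis window
#' (default 0.5--3.0 s, the sustained DC-shift period), compute the
#' samplewise t-map, form clusters on both tails at the forming threshold,
#' build the permutation null (sign flips for the intercept, whole-
#' participant block shuffles for covariates), attach Monte-Carlo p-values,
#' effect sizes, and peak electrodes.
#'
#' @param pgi_binned a [pg_binned] holding the PGI.
#' @param regressors named list of aligned `pg_regressor`s.
#' @param adjacency `pg_adjacency` over the data channels.
#' @param window analysis window in seconds.
#' @param forming_alpha per-tail forming threshold probability.
#' @param alpha per-tail cluster significance level.
#' @param n_perm permutations per analysis.
#' @param seed integer seed; each analysis uses `seed + its index`.
#' @param exhaustive enumerate all permutations (small n only).
#' @return list of class `pg_mua` keyed by regressor name; each element has
#'   `stat_map`, `clusters` (with p-values, effect sizes, peak electrodes),
#'   and `null`.
#' @export
run_mua <- function(pgi_binned, regressors, adjacency,
                    window = c(0.5, 3), forming_alpha = 0.025,
                    alpha = 0.05, n_perm = 10000, seed = 1L,
                    exhaustive = FALSE) {
  cropped <- crop_window(pgi_binned, window)
  if (is.null(names(regressors))) {
    names(regressors) <- paste0("analysis", seq_along(regressors))
  }
  out <- list()
  for (i in seq_along(regressors)) {
    reg <- regressors[[i]]
    sm <- samplewise_stat(cropped, reg)
    clusters <- c(form_clusters(sm, adjacency, forming_alpha, 1),
                  form_clusters(sm, adjacency, forming_alpha, -1))
    null <- permutation_null(cropped, reg, adjacency, n_perm = n_perm,
                             seed = seed + i, forming_alpha = forming_alpha,
                             exhaustive = exhaustive)
    clusters <- cluster_pvalues(clusters, null, alpha)
    clusters <- lapply(clusters, function(cl) {
      cl <- effect_sizes(cl, sm$n_participants, sm$df)
      cl$peak_channel <- select_peak_electrode(cl)
      cl
    })
    out[[names(regressors)[i]]] <-
      list(stat_map = sm, clusters = clusters, null = null,
           alpha = alpha, window = window)
  }
  structure(out, class = "pg_mua")
}
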