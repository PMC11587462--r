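#' Median split of factor scores
#'
#' Splits participants into low and high groups at the median; participants
#' exactly at the median go to the low group (a fixed, documented rule so
#' splits are deterministic).
#'
#' @param scores named numeric vector of factor scores.
#' @return list with `low`, `high` (participant names), `median`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 participants")
  if (length(unique(scores)) == 1) stop("all scores identical: no split")
  med <- stats::median(scores)
  list(low = names(scores)[scores <= med],
       high = names(scores)[scores > med],
       median = med)
}

#' Percentile-bootstrap confidence bands for a grand average
#'
#' Participants are resampled with replacement; one resample drives every
#' condition within a bootstrap iteration, preserving the cross-condition
#' correlation the PGI depends on. Bands are the per-timepoint
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the surrogate
#' grand averages.
#'
#' @param x participant x time matrix, or participant x condition x time
#'   array.
#' @param n_boot bootstrap iterations (default 5000; warns below 100).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @return for a matrix: list `mean`, `lower`, `upper` (time vectors); for
#'   an array: the same per condition (lists of vectors).
#' @export
bootstrap_ci <- function(x, n_boot = 5000, level = 0.95, seed = 1L) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable bands")
  is_arr <- length(dim(x)) == 3
  n <- dim(x)[1]
  if (n < 2) stop("need >= 2 participants")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  band_of <- function(mat) {     # participant x time
    W <- matrix(0, n_boot, n)
    for (b in seq_len(n_boot)) {
      tb <- tabulate(idx[b, ], nbins = n)
      W[b, ] <- tb / n
    }
    G <- W %*% mat               # surrogate grand averages
    q <- apply(G, 2, stats::quantile, probs = probs, names = FALSE)
    list(mean = colMeans(mat), lower = q[1, ], upper = q[2, ])
  }
  if (!is_arr) return(band_of(x))
  out <- lapply(seq_len(dim(x)[2]), function(ci) band_of(x[, ci, ]))
  names(out) <- dimnames(x)[[2]]
  out
}

#' Cluster summary table
#'
#' One row per cluster per tail across all analyses of a [run_mua()] result,
#' with p-value, peak electrode and time, effect sizes, and temporal extent.
#' Rows with p below the reporting cutoff (default 0.1, keeping borderline
#' effects visible) are retained, sorted by p ascending within analysis.
#'
#' @param results a `pg_mua` bundle.
#' @param p_cutoff reporting cutoff on the cluster p-value.
#' @return data.frame (possibly empty, with headers).
#' @export
cluster_table <- function(results, p_cutoff = 0.1) {
  rows <- list()
  for (an in names(results)) {
    res <- results[[an]]
    for (cl in res$clusters) {
      if (cl$p_value >= p_cutoff) next
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = an, regressor = res$stat_map$regressor,
        scheme = res$stat_map$granularity, tail = cl$tail,
        p_value = cl$p_value, significant = cl$significant,
        mass = cl$mass, n_samples = cl$n_samples,
        peak_electrode = cl$peak_channel, peak_time = cl$peak_time,
        peak_t = cl$peak_t, r = cl$r,
        d_one_sample = cl$d_one_sample, d_regression = cl$d_regression,
        time_start = cl$time_range[1], time_end = cl$time_range[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(analysis = character(0), regressor = character(0),
                      scheme = character(0), tail = integer(0),
                      p_value = numeric(0), significant = logical(0),
                      mass = numeric(0), n_samples = integer(0),
                      peak_electrode = character(0), peak_time = numeric(0),
                      peak_t = numeric(0), r = numeric(0),
                      d_one_sample = numeric(0), d_regression = numeric(0),
                      time_start = numeric(0), time_end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$analysis, tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Grand-average series with bootstrap bands at one electrode
#'
#' Across-participant mean time series (with percentile-bootstrap CI bands)
#' for each condition and bin of a binned dataset at one electrode,
#' optionally restricted to a participant subset (e.g. a median-split
#' group).
#'
#' @param binned a [pg_binned] (stimulus conditions or PGI).
#' @param channel electrode name.
#' @param participants subset of participants (default all).
#' @param n_boot,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return long data.frame: condition, bin, time, mean, lower, upper.
#' @export
grand_average <- function(binned, channel, participants = binned$participants,
                          n_boot = 5000, level = 0.95, seed = 1L) {
  ch <- match(channel, binned$channels)
  if (is.na(ch)) stop("channel '", channel, "' not present")
  ps <- match(participants, binned$participants)
  if (anyNA(ps)) stop("unknown participant in subset")
  out <- list()
  for (ci in seq_along(binned$conditions)) {
    for (bi in seq_along(binned$bins)) {
      mat <- binned$data[ps, bi, ci, ch, , drop = FALSE]
      dim(mat) <- c(length(ps), length(binned$times))
      bb <- bootstrap_ci(mat, n_boot = n_boot, level = level, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        condition = binned$conditions[ci], bin = binned$bins[bi],
        time = binned$times, mean = bb$mean, lower = bb$lower,
        upper = bb$upper, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export analysis products
#'
#' Writes, per analysis: the t-map (long channel x time), the cluster-member
#' mask, grand-average series with CI bands at the top cluster's peak
#' electrode (split into low/high groups for factor analyses), and the
#' pooled cluster table. Delimited text files are the canonical, numerically
#' testable surface; figures (t-map heatmap, grand-average bands) are a thin
#' rendering layer over the same tables.
#'
#' @param results a `pg_mua` bundle.
#' @param binned_sets named list of [pg_binned] objects keyed like
#'   `results`, used for the grand averages (typically the per-condition
#'   binned data of each analysis' scheme).
#' @param out_dir output directory (created if needed).
#' @param groups optional named list of participant subsets (e.g.
#'   median-split `low` / `high`); `NULL` exports ungrouped averages.
#' @param n_boot,level,seed bootstrap parameters for the bands.
#' @param figures also render PNG figures.
#' @return invisible character vector of written file paths.
#' @export
export_products <- function(results, binned_sets, out_dir, groups = NULL,
                            n_boot = 1000, level = 0.95, seed = 1L,
                            figures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tab <- cluster_table(results)
  paths <- c(paths, write_tsv(fmt_num(tab),
                              file.path(out_dir, "cluster_table.tsv")))
  for (an in names(results)) {
    res <- results[[an]]
    sm <- res$stat_map
    tmap <- data.frame(
      channel = rep(sm$channels, times = length(sm$times)),
      time = rep(sm$times, each = length(sm$channels)),
      t = as.vector(sm$t), stringsAsFactors = FALSE)
    paths <- c(paths, write_tsv(fmt_num(tmap),
                                file.path(out_dir, paste0("tmap_", an, ".tsv"))))
    mask <- do.call(rbind, lapply(seq_along(res$clusters), function(i) {
      cl <- res$clusters[[i]]
      data.frame(cluster = i, tail = cl$tail, p_value = cl$p_value,
                 cl$members, stringsAsFactors = FALSE)
    }))
    if (is.null(mask)) {
      mask <- data.frame(cluster = integer(0), tail = integer(0),
                         p_value = numeric(0), channel = character(0),
                         time = numeric(0), t = numeric(0))
    }
    paths <- c(paths, write_tsv(fmt_num(mask),
                                file.path(out_dir, paste0("mask_", an, ".tsv"))))
    binned <- binned_sets[[an]]
    if (!is.null(binned) && length(res$clusters)) {
      peak <- res$clusters[[1]]$peak_channel
      grp <- if (sm$regressor == "intercept" || is.null(groups)) {
        list(all = binned$participants)
      } else groups
      for (g in names(grp)) {
        keep <- intersect(as.character(grp[[g]]),
                          as.character(binned$participants))
        if (length(keep) < 2) next
        ga <- grand_average(binned, peak, keep, n_boot = n_boot,
                            level = level, seed = seed)
        paths <- c(paths, write_tsv(
          fmt_num(ga),
          file.path(out_dir, paste0("grandavg_", an, "_", g, ".tsv"))))
        if (figures) {
          paths <- c(paths, render_grandavg_figure(
            ga, file.path(out_dir, paste0("grandavg_", an, "_", g, ".png")),
            sprintf("%s (%s) at %s", an, g, peak)))
        }
      }
    }
    if (figures) {
      paths <- c(paths, render_tmap_figure(
        sm, file.path(out_dir, paste0("tmap_", an, ".png")), an))
    }
  }
  invisible(paths)
}

# round-trip-stable fixed formatting for deterministic delimited outputs
fmt_num <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}

render_grandavg_figure <- function(ga, path, title) {
  p <- ggplot2::ggplot(ga, ggplot2::aes(x = time, y = mean,
                                        colour = bin,
                                        fill = bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower,
                                      ymax = upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)", title = title) +
    ggplot2::theme_minimal()
  suppressMessages(ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 96))
  path
}

render_tmap_figure <- function(sm, path, title) {
  df <- data.frame(channel = factor(rep(sm$channels,
                                        times = length(sm$times)),
                                    levels = rev(sm$channels)),
                   time = rep(sm$times, each = length(sm$channels)),
                   t = as.vector(sm$t))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = channel,
                                        fill = t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (s)", y = NULL, title = title) +
    ggplot2::theme_minimal()
  suppressMessages(ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 96))
  path
}
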