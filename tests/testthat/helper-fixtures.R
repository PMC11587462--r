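# Small, fast study configurations used across the suite. Sizes are chosen
# so every statistical property under test is identifiable at desk scale.

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_participants = 4L,
    channel_layout = default_layout(4),
    sfreq = 20,
    epoch_window = c(-0.2, 3.5),
    trials_per_stimulus_per_partition = 2L,
    onsets_prob = c("7" = 1),
    dc_amplitude = 0,
    dc_window = c(0.5, 3),
    lambda_partition = 1,
    lambda_onset = 1,
    factor_effect_gain = 0,
    noise_sd = 0,
    ar_coefficient = 0.3,
    spatial_corr_length = 0.3,
    seed = 42L), list(...))
  do.call(simulation_config, args)
}

# single-channel-bump topography helpers
delta_topography <- function(layout, channel) {
  w <- stats::setNames(rep(0, nrow(layout)), layout$channel)
  w[channel] <- 1
  w
}

# a regular n x n grid layout with spacing h, for adjacency tests
grid_layout <- function(n, h = 0.2) {
  g <- expand.grid(ix = seq_len(n), iy = seq_len(n))
  data.frame(channel = sprintf("G%02d", seq_len(n * n)),
             x = (g$ix - (n + 1) / 2) * h,
             y = (g$iy - (n + 1) / 2) * h,
             stringsAsFactors = FALSE)
}

# wrap a participant x channel x time array as a single-bin PGI dataset
as_pgi_binned <- function(arr, times, sfreq, channels = NULL) {
  np <- dim(arr)[1]; nch <- dim(arr)[2]; nt <- dim(arr)[3]
  if (is.null(channels)) channels <- sprintf("G%02d", seq_len(nch))
  dat <- array(arr, dim = c(np, 1, 1, nch, nt))
  pg_binned(dat, "onsets_2_8", seq_len(np), "onsets_2_8", "PGI",
            channels, times, sfreq)
}

# build a pg_statmap directly from a t matrix (channel x time)
as_statmap <- function(tmat, df, n_participants = df + 1,
                       times = seq_len(ncol(tmat)),
                       channels = rownames(tmat)) {
  if (is.null(channels)) channels <- sprintf("G%02d", seq_len(nrow(tmat)))
  dimnames(tmat) <- list(channels, NULL)
  structure(list(t = tmat, df = df, n_rows = n_participants,
                 n_participants = n_participants, capped = FALSE,
                 channels = channels, times = times,
                 regressor = "test", granularity = "none",
                 direction = "none"),
            class = "pg_statmap")
}

# independent flood-fill oracle for spatiotemporal clustering, via igraph
oracle_clusters <- function(tmat, tcrit, layout_adj, tail) {
  nch <- nrow(tmat); nt <- ncol(tmat)
  supra <- if (tail > 0) tmat > tcrit else tmat < -tcrit
  nodes <- which(supra)          # column-major, channel fastest
  if (!length(nodes)) return(list())
  edges <- c()
  for (a in nodes) {
    ca <- (a - 1) %% nch + 1; ta <- (a - 1) %/% nch + 1
    for (b in nodes) {
      if (b <= a) next
      cb <- (b - 1) %% nch + 1; tb <- (b - 1) %/% nch + 1
      spatial <- ta == tb && layout_adj[ca, cb]
      temporal <- ca == cb && abs(ta - tb) == 1
      if (spatial || temporal) edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n = nch * nt, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  comps <- split(seq_len(nch * nt), comp$membership)
  comps <- lapply(comps, function(m) sort(intersect(m, nodes)))
  comps[vapply(comps, length, 1L) > 0]
}
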