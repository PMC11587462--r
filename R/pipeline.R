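#' Default end-to-end pipeline configuration
#'
#' A nested list (YAML round-trippable, see [read_config()]) holding every
#' knob of [run_all()]: the simulation design, preprocessing choices, the
#' analysis window and permutation parameters, the exponential change rates,
#' and the reporting bootstrap. Defaults mirror the study design the
#' simulator emulates; `n_perm` and `n_boot` are sized for a desk-scale run
#' and can be raised (e.g. 10000 permutations, escalating to 25000 for
#' p-values near the significance threshold, and 5000 bootstrap draws) for
#' production use.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    simulation = list(
      n_participants = 38, n_channels = 32, sfreq = 512,
      epoch_window = c(-0.2, 4), n_partitions = 3,
      trials_per_stimulus_per_partition = 6,
      onsets_prob = c("7" = 0.4, "8" = 0.4, "9" = 0.2),
      dc_amplitude = 2, dc_window = c(0.5, 3),
      lambda_partition = 1, lambda_onset = 1,
      factor_effect_gain = 1, noise_sd = 10, ar_coefficient = 0.9,
      spatial_corr_length = 0.4, artifact_rate = 0,
      artifact_amplitude = 150),
    preprocessing = list(
      filter = TRUE, filter_low = 0.1, filter_high = 30,
      reject_limit = 100, include_min_fraction = 0.2),
    analysis = list(
      window = c(0.5, 3), forming_alpha = 0.025, alpha = 0.05,
      n_perm = 1000, n_perm_escalated = 2500, escalate_band = c(0.03, 0.07),
      lambda = 1, orthogonalize = TRUE, adjacency_threshold = 0.45),
    reporting = list(n_boot = 1000, level = 0.95, figures = FALSE))
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return for `read_config`, the configuration list merged over
#'   [default_config()] defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulates a pattern-glare study, preprocesses it (band-pass, average
#' reference, baseline correction, threshold rejection, participant
#' inclusion), derives the behavioural factor scores (discomfort index,
#' standardisation, varimax factoring, labelling), builds the analysis set
#' -- the intercept and discomfort analyses on the averaged-onsets data plus
#' the discomfort-by-decrease / increase interactions at both time
#' granularities and the three-way interaction, Gram-Schmidt orthogonalised
#' across factors in the order visual stress, headache, discomfort -- runs
#' the cluster-permutation mass-univariate analyses, and exports delimited
#' products. Fully deterministic for a fixed seed.
#'
#' @param config configuration list (see [default_config()]).
#' @param seed integer master seed; overrides the simulation seed and
#'   derives every downstream seed.
#' @param out_dir output directory for delimited products (and figures if
#'   configured); `NULL` skips export.
#' @return list with `simulation`, `factors`, `included`, `binned`, `pgi`,
#'   `regressors`, `results`, `products`.
#' @export
run_all <- function(config = default_config(), seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  simcfg <- config$simulation
  sim_config <- simulation_config(
    n_participants = simcfg$n_participants,
    channel_layout = default_layout(simcfg$n_channels),
    sfreq = simcfg$sfreq, epoch_window = as.numeric(simcfg$epoch_window),
    n_partitions = simcfg$n_partitions,
    trials_per_stimulus_per_partition =
      simcfg$trials_per_stimulus_per_partition,
    onsets_prob = unlist(simcfg$onsets_prob),
    dc_amplitude = simcfg$dc_amplitude,
    dc_window = as.numeric(simcfg$dc_window),
    lambda_partition = simcfg$lambda_partition,
    lambda_onset = simcfg$lambda_onset,
    factor_effect_gain = simcfg$factor_effect_gain,
    noise_sd = simcfg$noise_sd, ar_coefficient = simcfg$ar_coefficient,
    spatial_corr_length = simcfg$spatial_corr_length,
    artifact_rate = simcfg$artifact_rate,
    artifact_amplitude = simcfg$artifact_amplitude,
    seed = seed)
  sim <- simulate_epochs(sim_config)
  epochs <- sim$epochs
  pp <- config$preprocessing
  if (isTRUE(pp$filter)) {
    epochs <- bandpass_filter(epochs, pp$filter_low, pp$filter_high)
  }
  epochs <- rereference_average(epochs)
  epochs <- baseline_correct(epochs)
  rej <- reject_threshold(epochs, pp$reject_limit)
  trials <- apply_rejections(sim$trials, rej$keep)
  included <- include_participants(trials, pp$include_min_fraction)

  # behavioural factors
  behav <- simulate_behavioral(sim_config, sim$truth, trial_table = trials)
  zb <- standardize_measures(behav)
  fact <- extract_factors(zb, k = 3)
  labels <- label_factors(fact$loadings)
  scores <- fact$scores
  colnames(scores) <- labels[colnames(scores)]

  an <- config$analysis
  lam <- an$lambda
  results <- list()
  binned_sets <- list()
  regressors_used <- list()
  groups <- NULL

  specs <- list(
    intercept = list(scheme = "onsets_2_8", type = "intercept"),
    discomfort = list(scheme = "onsets_2_8", type = "factor"),
    discomfort_by_decrease_partitions =
      list(scheme = "partitions", type = "two_way", direction = "decrease"),
    discomfort_by_increase_partitions =
      list(scheme = "partitions", type = "two_way", direction = "increase"),
    discomfort_by_decrease_onsets =
      list(scheme = "onset_pairs", type = "two_way", direction = "decrease"),
    discomfort_by_increase_partitions_by_decrease_onsets =
      list(scheme = "partition_by_onset_pair", type = "three_way",
           partition_direction = "increase", onset_direction = "decrease"))

  for (nm in names(specs)) {
    sp <- specs[[nm]]
    binned <- bin_average(epochs, trials, sp$scheme, included)
    binned <- drop_incomplete(binned)
    pgi <- compute_pgi(binned)
    keep <- match(binned$participants, seq_len(sim_config$n_participants))
    fscores <- function(f) {
      stats::setNames(scores[keep, f], as.character(binned$participants))
    }
    reg <- switch(sp$type,
      intercept = intercept_regressor(pgi),
      factor = {
        regs <- lapply(c("visual_stress", "headache", "discomfort"),
                       function(f) factor_regressor(fscores(f),
                                                    pgi$bins, f))
        if (isTRUE(an$orthogonalize)) regs <- orthogonalize_design(regs)
        regs[[3]]
      },
      two_way = {
        pat <- exponential_weights(length(pgi$bins), sp$direction, lam)
        gran <- if (sp$scheme == "partitions") "partitions" else "onset_pairs"
        regs <- lapply(c("visual_stress", "headache", "discomfort"),
                       function(f) two_way_regressor(fscores(f), pat,
                                                     bins = pgi$bins,
                                                     factor = f,
                                                     granularity = gran))
        if (isTRUE(an$orthogonalize)) regs <- orthogonalize_design(regs)
        regs[[3]]
      },
      three_way = {
        op <- exponential_weights(3, sp$onset_direction, lam)
        pp2 <- exponential_weights(3, sp$partition_direction, lam)
        regs <- lapply(c("visual_stress", "headache", "discomfort"),
                       function(f) three_way_regressor(fscores(f), op, pp2,
                                                       factor = f))
        if (isTRUE(an$orthogonalize)) regs <- orthogonalize_design(regs)
        regs[[3]]
      })
    adjacency <- build_adjacency(sim_config$channel_layout,
                                 an$adjacency_threshold)
    res <- run_mua(pgi, stats::setNames(list(reg), nm), adjacency,
                   window = as.numeric(an$window),
                   forming_alpha = an$forming_alpha, alpha = an$alpha,
                   n_perm = an$n_perm, seed = seed + match(nm, names(specs)))
    # escalate the permutation count when a p-value sits near the
    # significance threshold, for a more accurate Monte-Carlo estimate
    ps <- vapply(res[[nm]]$clusters, `[[`, 0, "p_value")
    band <- as.numeric(an$escalate_band)
    if (!is.null(an$n_perm_escalated) && an$n_perm_escalated > an$n_perm &&
        length(ps) && any(ps >= band[1] & ps <= band[2])) {
      res <- run_mua(pgi, stats::setNames(list(reg), nm), adjacency,
                     window = as.numeric(an$window),
                     forming_alpha = an$forming_alpha, alpha = an$alpha,
                     n_perm = an$n_perm_escalated,
                     seed = seed + match(nm, names(specs)))
    }
    results[[nm]] <- res[[nm]]
    binned_sets[[nm]] <- crop_window(binned, as.numeric(an$window))
    regressors_used[[nm]] <- reg
    if (is.null(groups) && sp$type != "intercept") {
      ms <- median_split(fscores("discomfort"))
      groups <- list(low = ms$low, high = ms$high)
    }
  }
  class(results) <- "pg_mua"

  products <- NULL
  if (!is.null(out_dir)) {
    rep_cfg <- config$reporting
    products <- export_products(results, binned_sets, out_dir,
                                groups = groups, n_boot = rep_cfg$n_boot,
                                level = rep_cfg$level, seed = seed,
                                figures = isTRUE(rep_cfg$figures))
  }
  list(simulation = sim, factors = list(scores = scores,
                                        loadings = fact$loadings,
                                        eigenvalues = fact$eigenvalues,
                                        labels = labels),
       included = included, regressors = regressors_used,
       results = results, binned = binned_sets, products = products)
}
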