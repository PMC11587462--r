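#' Simulation configuration
#'
#' Bundles every parameter of the synthetic pattern-glare study generator.
#' Defaults reproduce the design of the EEG study the package analyses:
#' 38 participants, three blocks (partitions) of six trials per stimulus type
#' (thin / medium / thick gratings), each trial a train of 7--9 three-second
#' onsets, epochs of -200 ms to 4000 ms at 512 Hz, and a sustained positive
#' DC-shift to the medium stimulus over a right-posterior scalp region during
#' 0.5--3.0 s. The injected medium-stimulus amplitude for participant `p` in
#' partition `j` and onset-pair `i` is
#'
#'   `A = dc_amplitude + factor_effect_gain * discomfort_p *
#'        exp(-lambda_partition * (j - 1)) * exp(+lambda_onset * (i - 1))`
#'
#' scaled by the per-channel effect topography; thin and thick epochs carry
#' no injected effect. Noise is stationary Gaussian, AR(1) in time with
#' spatial covariance `exp(-distance / spatial_corr_length)`.
#'
#' @param n_participants number of participants.
#' @param channel_layout electrode layout (`default_layout()` format).
#' @param sfreq sampling rate, Hz.
#' @param epoch_window `c(start, end)` of the epoch in seconds relative to
#'   stimulus onset (start must be negative: a pre-stimulus baseline exists).
#' @param n_partitions number of experimental blocks.
#' @param trials_per_stimulus_per_partition trials per stimulus per block.
#' @param onsets_prob named probability vector over the number of onsets per
#'   trial (names are onset counts); must sum to 1.
#' @param dc_amplitude microvolts of the medium-stimulus DC shift common to
#'   all participants.
#' @param effect_topography per-channel weights in `[0, 1]`; `NULL` uses a
#'   raised-cosine bump of radius 0.3 centred on the right-posterior
#'   electrode `B16`.
#' @param dc_window `c(start, end)` seconds over which the effect is
#'   injected (within the epoch, after onset).
#' @param lambda_partition habituation rate across partitions (>= 0).
#' @param lambda_onset sensitisation rate across onset-pairs (>= 0).
#' @param factor_effect_gain microvolts of effect per unit discomfort factor
#'   score.
#' @param noise_sd marginal noise standard deviation, microvolts.
#' @param ar_coefficient temporal AR(1) coefficient in `[0, 1)`.
#' @param spatial_corr_length spatial correlation length in layout units.
#' @param artifact_rate probability that an epoch receives a rectangular
#'   artifact spike (0 disables; used to exercise threshold rejection).
#' @param artifact_amplitude absolute spike amplitude, microvolts.
#' @param rating_gain latent discomfort-rating gain (rating units per unit
#'   discomfort factor score, medium stimulus only).
#' @param rating_noise_sd latent rating noise SD per trial.
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return a validated list of class `pg_sim_config`.
#' @export
simulation_config <- function(n_participants = 38,
                              channel_layout = default_layout(32),
                              sfreq = 512,
                              epoch_window = c(-0.2, 4),
                              n_partitions = 3,
                              trials_per_stimulus_per_partition = 6,
                              onsets_prob = c("7" = 0.4, "8" = 0.4, "9" = 0.2),
                              dc_amplitude = 2,
                              effect_topography = NULL,
                              dc_window = c(0.5, 3),
                              lambda_partition = 1,
                              lambda_onset = 1,
                              factor_effect_gain = 1,
                              noise_sd = 10,
                              ar_coefficient = 0.9,
                              spatial_corr_length = 0.4,
                              artifact_rate = 0,
                              artifact_amplitude = 150,
                              rating_gain = 0.8,
                              rating_noise_sd = 0.6,
                              seed = 1L) {
  if (n_participants < 1) stop("n_participants must be positive")
  if (nrow(channel_layout) < 1) stop("channel layout is empty")
  if (!(epoch_window[1] < 0 && 0 < dc_window[1] && dc_window[1] < dc_window[2] &&
        dc_window[2] <= epoch_window[2])) {
    stop("require epoch start < 0 < dc start < dc end <= epoch end")
  }
  if (abs(sum(onsets_prob) - 1) > 1e-9) stop("onsets_prob must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must be in [0, 1)")
  }
  if (lambda_partition < 0 || lambda_onset < 0) stop("rates must be >= 0")
  if (is.null(effect_topography)) {
    center <- if ("B16" %in% channel_layout$channel) "B16" else
      channel_layout$channel[which.max(channel_layout$x - channel_layout$y)]
    effect_topography <- raised_cosine_topography(channel_layout, center, 0.3)
  }
  if (length(effect_topography) != nrow(channel_layout)) {
    stop("effect_topography length must match layout")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    channel_layout = channel_layout, sfreq = sfreq,
    epoch_window = epoch_window, n_partitions = as.integer(n_partitions),
    trials_per_stimulus_per_partition =
      as.integer(trials_per_stimulus_per_partition),
    onsets_prob = onsets_prob, dc_amplitude = dc_amplitude,
    effect_topography = effect_topography, dc_window = dc_window,
    lambda_partition = lambda_partition, lambda_onset = lambda_onset,
    factor_effect_gain = factor_effect_gain, noise_sd = noise_sd,
    ar_coefficient = ar_coefficient,
    spatial_corr_length = spatial_corr_length,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    rating_gain = rating_gain, rating_noise_sd = rating_noise_sd,
    seed = as.integer(seed)), class = "pg_sim_config")
}

stimulus_levels <- c("thin", "medium", "thick")

# onset-pair index used by the sensitisation law: pairs {2,3}, {4,5}, {6,7}
# map to 1..3; onset 1 is clamped to pair 1 and onsets 8/9 continue at pair 3
# (they sit beyond the last analysed pair).
onset_pair_index <- function(onset) pmin(pmax(onset %/% 2L, 1L), 3L)

# trial structure + latent ratings for every participant; one row per onset
sim_trial_table <- function(config, discomfort) {
  n_onset_choices <- as.integer(names(config$onsets_prob))
  rows <- list()
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    for (part in seq_len(config$n_partitions)) {
      for (stim in stimulus_levels) {
        for (tr in seq_len(config$trials_per_stimulus_per_partition)) {
          n_on <- n_onset_choices[sample.int(length(n_onset_choices), 1,
                                             prob = config$onsets_prob)]
          base <- if (stim == "medium") 2.5 else 2.0
          latent <- base +
            (stim == "medium") * config$rating_gain * discomfort[p] +
            stats::rnorm(1, 0, config$rating_noise_sd)
          rating <- as.integer(pmin(pmax(round(latent), 1), 5))
          k <- k + 1L
          rows[[k]] <- data.frame(
            participant = p, stimulus = stim, partition = part,
            trial = tr, onset = seq_len(n_on), rating = rating,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$usable <- TRUE
  tab$epoch <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Simulate an epoched pattern-glare EEG study
#'
#' Generates the full study: per-participant factor scores (visual stress,
#' headache, discomfort; independent standard normals), the trial table with
#' per-trial discomfort ratings, epoched EEG with the configured
#' medium-stimulus DC-shift effect, and the ground truth needed for recovery
#' testing.
#'
#' @param config a `pg_sim_config` from [simulation_config()].
#' @return a list with elements `epochs` ([pg_epochs]), `trials` (one row per
#'   epoch: participant, stimulus, partition, trial, onset, rating, usable,
#'   epoch index), and `truth` (factor scores, `effect_support` channel x
#'   time mask, `bin_amplitudes` 3 x 3 exponential modulation grid,
#'   `amplitudes` participant x partition x pair injected microvolts, and the
#'   artifact ledger).
#' @export
simulate_epochs <- function(config) {
  stopifnot(inherits(config, "pg_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  scores <- matrix(stats::rnorm(n * 3), n, 3,
                   dimnames = list(NULL,
                                   c("visual_stress", "headache", "discomfort")))
  trials <- sim_trial_table(config, scores[, "discomfort"])
  nep <- nrow(trials)
  layout <- config$channel_layout
  nch <- nrow(layout)
  n_t <- round((config$epoch_window[2] - config$epoch_window[1]) *
                 config$sfreq) + 1L
  times <- config$epoch_window[1] + (seq_len(n_t) - 1) / config$sfreq

  # --- noise: AR(1) in time, exp(-d/l) across channels, separable ----------
  data <- array(0, dim = c(nep, nch, n_t))
  if (config$noise_sd > 0) {
    a <- config$ar_coefficient
    innov_sd <- config$noise_sd * sqrt(1 - a^2)
    X <- array(stats::rnorm(nch * n_t * nep), dim = c(nch, n_t, nep))
    X[, 1, ] <- X[, 1, ] * config$noise_sd
    if (n_t > 1) {
      for (t in 2:n_t) {
        X[, t, ] <- a * X[, t - 1, ] + innov_sd * X[, t, ]
      }
    }
    if (nch > 1) {
      D <- as.matrix(stats::dist(layout[, c("x", "y")]))
      Cs <- exp(-D / config$spatial_corr_length)
      L <- chol(Cs + diag(1e-10, nch))
      dim(X) <- c(nch, n_t * nep)
      X <- crossprod(L, X)          # t(L) %*% X gives cov Cs across channels
      dim(X) <- c(nch, n_t, nep)
    }
    data <- aperm(X, c(3, 1, 2))
  }

  # --- injected medium-stimulus effect -------------------------------------
  tmask <- times >= config$dc_window[1] & times <= config$dc_window[2]
  w <- config$effect_topography
  pair_mod <- exp(config$lambda_onset * (0:2))
  part_mod <- exp(-config$lambda_partition *
                    (seq_len(config$n_partitions) - 1))
  bin_amplitudes <- outer(part_mod, pair_mod)   # partition x pair modulation
  dimnames(bin_amplitudes) <- list(paste0("P", seq_along(part_mod)),
                                   c("O23", "O45", "O67"))
  amplitudes <- array(
    config$dc_amplitude + config$factor_effect_gain *
      rep(scores[, "discomfort"], times = length(bin_amplitudes)) *
      rep(as.vector(bin_amplitudes), each = n),
    dim = c(n, nrow(bin_amplitudes), ncol(bin_amplitudes)),
    dimnames = c(list(NULL), dimnames(bin_amplitudes)))
  med <- which(trials$stimulus == "medium")
  if (length(med) && any(tmask) && any(w > 0)) {
    amp_e <- amplitudes[cbind(trials$participant[med],
                              trials$partition[med],
                              onset_pair_index(trials$onset[med]))]
    sig <- outer(amp_e, w)                      # epoch x channel
    data[med, , tmask] <- data[med, , tmask, drop = FALSE] +
      array(rep(sig, times = sum(tmask)),
            dim = c(length(med), nch, sum(tmask)))
  }

  # --- optional rectangular artifact spikes --------------------------------
  artifact_epochs <- integer(0)
  if (config$artifact_rate > 0) {
    hit <- which(stats::runif(nep) < config$artifact_rate)
    for (e in hit) {
      ch <- sample.int(nch, 1)
      t0 <- sample.int(max(n_t - 25, 1), 1)
      idx <- t0:min(t0 + 25, n_t)
      data[e, ch, idx] <- data[e, ch, idx] +
        sample(c(-1, 1), 1) * config$artifact_amplitude
    }
    artifact_epochs <- hit
  }

  epochs <- pg_epochs(data, config$sfreq, times, layout$channel, layout)
  truth <- list(
    factor_scores = scores,
    effect_support = outer(w > 0, tmask,
                           FUN = function(a, b) a & b),
    bin_amplitudes = bin_amplitudes,
    amplitudes = amplitudes,
    artifact_epochs = artifact_epochs,
    config = config)
  list(epochs = epochs, trials = trials, truth = truth)
}

#' Simulate trial-level discomfort ratings only
#'
#' Same generative model for the per-trial five-point discomfort ratings as
#' [simulate_epochs()], without generating any EEG; useful for behavioural
#' analyses at participant counts where full EEG volumes would be wasteful.
#'
#' @param config a `pg_sim_config`.
#' @param truth a truth list holding `factor_scores` (e.g. from
#'   [simulate_epochs()]), or `NULL` to draw fresh scores.
#' @return list with `trials` (trial table without EEG linkage) and `truth`.
#' @export
simulate_ratings <- function(config, truth = NULL) {
  set.seed(config$seed)
  if (is.null(truth)) {
    scores <- matrix(stats::rnorm(config$n_participants * 3),
                     ncol = 3,
                     dimnames = list(NULL, c("visual_stress", "headache",
                                             "discomfort")))
    truth <- list(factor_scores = scores)
  } else if (nrow(truth$factor_scores) != config$n_participants) {
    stop("truth and config participant counts differ")
  }
  trials <- sim_trial_table(config, truth$factor_scores[, "discomfort"])
  list(trials = trials, truth = truth)
}

# fixed questionnaire loading structure: a visual-stress block (CHi, VDS),
# a headache block (frequency, intensity, duration, aura); the seventh
# measure, the in-experiment discomfort index, is derived from the trial
# ratings rather than drawn here.
behavioral_loadings <- function() {
  L <- matrix(0, 6, 3, dimnames = list(
    c("chi", "vds", "headache_frequency", "headache_intensity",
      "headache_duration", "sensory_aura"),
    c("visual_stress", "headache", "discomfort")))
  L["chi", "visual_stress"] <- 0.85
  L["vds", "visual_stress"] <- 0.85
  L["headache_frequency", "headache"] <- 0.85
  L["headache_intensity", "headache"] <- 0.80
  L["headache_duration", "headache"] <- 0.75
  L["sensory_aura", "headache"] <- 0.60
  L
}

# per-measure affine transforms giving the questionnaires realistic,
# deliberately incommensurate ranges (they are standardised before factoring)
behavioral_scales <- function() {
  data.frame(
    measure = rownames(behavioral_loadings()),
    offset = c(25, 60, 3, 4, 5, 1.5),
    scale = c(10, 20, 1.5, 2, 4, 1),
    stringsAsFactors = FALSE)
}

#' Simulate questionnaire measures
#'
#' Generates the six questionnaire totals (CHi, VDS, headache frequency /
#' intensity / duration, sensory aura) from the true factor scores through a
#' fixed block loading matrix plus independent unique noise, on
#' questionnaire-realistic scales. If a trial table is supplied, the seventh
#' measure -- the in-experiment discomfort index -- is appended via
#' [discomfort_index()].
#'
#' @param config a `pg_sim_config`.
#' @param truth truth list with `factor_scores` (participants must match).
#' @param trial_table optional trial table with ratings.
#' @param noise_scale multiplier on the unique noise SDs (0 gives the exact
#'   linear model).
#' @return data.frame, one row per participant.
#' @export
simulate_behavioral <- function(config, truth, trial_table = NULL,
                                noise_scale = 1) {
  F <- truth$factor_scores
  if (nrow(F) != config$n_participants) {
    stop("truth and config participant counts differ")
  }
  set.seed(config$seed + 104729L)    # independent stream from the EEG draw
  L <- behavioral_loadings()
  uniq_sd <- sqrt(pmax(1 - rowSums(L^2), 0)) * noise_scale
  n <- nrow(F)
  Z <- F %*% t(L) +
    matrix(stats::rnorm(n * nrow(L)), n) %*% diag(uniq_sd)
  sc <- behavioral_scales()
  out <- data.frame(participant = seq_len(n))
  for (j in seq_len(nrow(sc))) {
    out[[sc$measure[j]]] <- sc$offset[j] + sc$scale[j] * Z[, j]
  }
  if (!is.null(trial_table)) {
    di <- discomfort_index(trial_table)
    out$discomfort_index <- di$discomfort_index[match(out$participant,
                                                      di$participant)]
  }
  out
}
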