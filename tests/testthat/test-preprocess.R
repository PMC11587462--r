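make_epochs <- function(data, sfreq, t0 = 0) {
  nt <- dim(data)[3]
  pg_epochs(data, sfreq, t0 + (seq_len(nt) - 1) / sfreq,
            sprintf("C%02d", seq_len(dim(data)[2])))
}

test_that("the band-pass keeps the passband, kills the stopband and nulls DC", {
  sf <- 256
  t <- (0:2047) / sf
  mk <- function(x) make_epochs(array(x, c(1, 1, length(x))), sf, 0)
  mid <- 513:1536                       # away from edge effects
  # 10 Hz sinusoid through 0.1-30 Hz: amplitude preserved within 5%
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(mk(x10), 0.1, 30)$data[1, 1, ]
  expect_lt(max(abs(y10[mid] - x10[mid])), 0.05)
  # 60 Hz sinusoid: residual < 10% of input
  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass_filter(mk(x60), 0.1, 30)$data[1, 1, ]
  expect_lt(max(abs(y60[mid])), 0.10)
  # DC attenuated (kernel has exactly zero DC gain by construction)
  ydc <- bandpass_filter(mk(rep(5, length(t))), 0.1, 30)$data[1, 1, ]
  expect_lt(max(abs(ydc[mid])), 5 * 10^(-20 / 20))
})

test_that("white-noise variance drops by the filter's spectral energy fraction", {
  sf <- 128
  set.seed(1)
  x <- rnorm(4096)
  ep <- make_epochs(array(x, c(1, 1, 4096)), sf)
  y <- bandpass_filter(ep, 1, 30, trans_bandwidth = c(1, 7.5))$data[1, 1, ]
  expect_lt(var(y), var(x))
  # oracle: integrate the kernel's squared frequency response directly
  h <- patternglare:::fir_bandpass_kernel(sf, 1, 30, c(1, 7.5), 4096)
  H2 <- Mod(fft(c(h, rep(0, 8192 - length(h)))))^2
  expect_equal(var(y) / var(x), mean(H2), tolerance = 0.05)
})

test_that("decimation is exact subsampling at the right rate", {
  sf <- 2048
  t <- (0:4095) / sf
  x <- sin(2 * pi * 2 * t)
  ep <- make_epochs(array(x, c(1, 1, 4096)), sf)
  expect_identical(decimate_epochs(ep, 1), ep)
  dec <- decimate_epochs(ep, 4)
  expect_equal(dec$sfreq, 512)
  expect_equal(dim(dec$data)[3], 1024)
  expect_equal(dec$data[1, 1, ], sin(2 * pi * 2 * dec$times),
               tolerance = 1e-6)
  expect_error(decimate_epochs(ep, 0), "factor")
})

test_that("average referencing has its closed form and is idempotent", {
  d <- array(0, c(1, 2, 3)); d[1, 1, ] <- c(1, 4, -2); d[1, 2, ] <- c(3, 0, 6)
  ep <- make_epochs(d, 10)
  rr <- rereference_average(ep)
  expect_equal(rr$data[1, 1, ], (d[1, 1, ] - d[1, 2, ]) / 2)
  expect_equal(rr$data[1, 2, ], (d[1, 2, ] - d[1, 1, ]) / 2)
  expect_equal(rereference_average(rr)$data, rr$data)
  set.seed(2)
  big <- make_epochs(array(rnorm(1 * 8 * 100), c(1, 8, 100)), 100)
  out <- rereference_average(big)
  expect_lt(max(abs(apply(out$data[1, , ], 2, mean))), 1e-12)
  expect_error(rereference_average(make_epochs(array(1, c(1, 1, 4)), 10)),
               "channels")
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  sf <- 10
  nt <- 31
  times <- -0.2 + (seq_len(nt) - 1) / sf
  mk <- function(x) pg_epochs(array(x, c(1, 1, nt)), sf, times, "C01")
  expect_true(all(baseline_correct(mk(rep(3.7, nt)))$data == 0))
  step <- ifelse(times > 0, 5, 0)
  expect_equal(baseline_correct(mk(step))$data[1, 1, ], step)
  ramp <- baseline_correct(mk(times))$data[1, 1, ]
  expect_equal(ramp, times + 0.1, tolerance = 1e-12)
  expect_error(baseline_correct(mk(times), window = c(-2, -1)), "window")
})

test_that("threshold rejection drops exactly the offending epochs", {
  set.seed(3)
  d <- array(runif(5 * 2 * 20, -50, 50), c(5, 2, 20))
  ep <- make_epochs(d, 20)
  expect_true(all(reject_threshold(ep, 100)$keep))
  d[3, 2, 7] <- 150
  ep <- make_epochs(d, 20)
  rej <- reject_threshold(ep, 100)
  expect_equal(which(!rej$keep), 3L)
  expect_equal(rej$log$epoch, 3L)
  expect_equal(rej$log$channel, "C02")
  expect_equal(rej$log$extremum, 150)
})

test_that("participant inclusion is an inclusive 20% boundary per condition", {
  mk_tt <- function(fracs) {
    do.call(rbind, lapply(seq_along(fracs), function(p) {
      do.call(rbind, lapply(c("thin", "medium", "thick"), function(s) {
        n_us <- if (s == "medium") round(fracs[p] * 100) else 100
        data.frame(participant = p, stimulus = s, partition = 1,
                   trial = 1:100, onset = 1, rating = 3,
                   usable = c(rep(TRUE, n_us), rep(FALSE, 100 - n_us)),
                   epoch = NA)
      }))
    }))
  }
  tt <- mk_tt(c(1, 0.19, 0.20))
  expect_equal(include_participants(tt, 0.2), c(1, 3))
  expect_equal(include_participants(mk_tt(c(1, 1))), c(1, 2))
  expect_error(include_participants(tt[0, ]), "empty")
})

test_that("bin averaging follows the onset exclusion rules and cell means", {
  lay <- default_layout(4)
  nt <- 5
  tt <- data.frame(participant = 1, stimulus = "medium", partition = 1,
                   trial = c(1, 1, 1), onset = c(1, 2, 3), rating = 3,
                   usable = TRUE, epoch = 1:3)
  tt <- rbind(tt, data.frame(participant = 1, stimulus = "thin", partition = 1,
                             trial = 1, onset = 2, rating = 3, usable = TRUE,
                             epoch = 4),
              data.frame(participant = 1, stimulus = "thick", partition = 1,
                         trial = 1, onset = 2, rating = 3, usable = TRUE,
                         epoch = 5))
  d <- array(0, c(5, 4, nt))
  d[2, , ] <- 1; d[3, , ] <- 3; d[1, , ] <- 99    # onset-1 epoch is ignored
  ep <- pg_epochs(d, 10, (0:4) / 10, lay$channel, lay)
  b <- bin_average(ep, tt, "onsets_2_8")
  expect_equal(unique(as.vector(b$data[1, 1, match("medium", b$conditions), , ])), 2)
  expect_equal(b$counts[1, 1, match("medium", b$conditions)], 2L)
})

test_that("noise-free binned cells equal the generator's ground truth", {
  lay <- default_layout(4)
  cfg <- tiny_config(dc_amplitude = 1.5, factor_effect_gain = 0.8,
                     lambda_partition = 0.7, lambda_onset = 0.4,
                     effect_topography = delta_topography(lay, "B16"),
                     onsets_prob = c("8" = 1))
  sim <- simulate_epochs(cfg)
  b <- bin_average(sim$epochs, sim$trials, "partition_by_onset_pair")
  ch <- match("B16", b$channels)
  tmask <- b$times >= 0.5 & b$times <= 3
  mi <- match("medium", b$conditions)
  for (p in seq_len(cfg$n_participants)) {
    for (j in 1:3) for (i in 1:3) {
      bin <- (j - 1) * 3 + i
      expect_equal(unique(round(b$data[p, bin, mi, ch, tmask], 10)),
                   round(sim$truth$amplitudes[p, j, i], 10))
    }
  }
})

test_that("the pooled-onsets average is the count-weighted mean of its parts", {
  cfg <- tiny_config(noise_sd = 2, onsets_prob = c("8" = 1), seed = 8L)
  sim <- simulate_epochs(cfg)
  full <- bin_average(sim$epochs, sim$trials, "onsets_2_8")
  pairs <- bin_average(sim$epochs, sim$trials, "onset_pairs")
  # onset-8 epochs enter the pooled average but no onset-pair bin
  on8 <- sim$trials[sim$trials$onset == 8, ]
  mi <- match("medium", full$conditions)
  for (p in seq_len(cfg$n_participants)) {
    e8 <- on8$epoch[on8$participant == p & on8$stimulus == "medium"]
    m8 <- colMeans(sim$epochs$data[e8, , , drop = FALSE], dims = 1)
    w <- pairs$counts[p, , mi]
    pooled <- (apply(sweep(pairs$data[p, , mi, , ], 1, w, `*`), c(2, 3), sum) +
                 length(e8) * m8) / (sum(w) + length(e8))
    expect_equal(unname(full$data[p, 1, mi, , ]), unname(pooled), tolerance = 1e-12)
  }
})

test_that("PGI identities hold to machine precision", {
  mkb <- function(med, thin, thick) {
    dat <- array(0, c(1, 1, 3, 2, 4))
    dat[1, 1, 1, , ] <- thin; dat[1, 1, 2, , ] <- med; dat[1, 1, 3, , ] <- thick
    pg_binned(dat, "onsets_2_8", 1, "onsets_2_8",
              c("thin", "medium", "thick"), c("C1", "C2"), (0:3) / 10, 10)
  }
  expect_true(all(compute_pgi(mkb(2, 2, 2))$data == 0))
  expect_true(all(compute_pgi(mkb(2, 3, 1))$data == 0))
  expect_true(all(compute_pgi(mkb(5, 2, 1))$data == 3.5))
  # linearity under dataset addition
  set.seed(4)
  a <- mkb(rnorm(8), rnorm(8), rnorm(8))
  b <- mkb(rnorm(8), rnorm(8), rnorm(8))
  ab <- a; ab$data <- a$data + b$data
  expect_equal(compute_pgi(ab)$data,
               compute_pgi(a)$data + compute_pgi(b)$data, tolerance = 1e-12)
})

test_that("baseline correction and average referencing commute", {
  set.seed(5)
  sf <- 50
  nt <- 60
  times <- -0.2 + (seq_len(nt) - 1) / sf
  ep <- pg_epochs(array(rnorm(3 * 6 * nt), c(3, 6, nt)), sf, times,
                  sprintf("C%02d", 1:6))
  ab <- baseline_correct(rereference_average(ep))
  ba <- rereference_average(baseline_correct(ep))
  expect_lt(max(abs(ab$data - ba$data)), 1e-9)
})

test_that("only decimation changes the channel set or time axis", {
  cfg <- tiny_config(noise_sd = 1)
  sim <- simulate_epochs(cfg)
  for (f in list(function(e) bandpass_filter(e, 0.5, 8),
                 rereference_average, baseline_correct)) {
    out <- f(sim$epochs)
    expect_identical(out$channels, sim$epochs$channels)
    expect_identical(out$times, sim$epochs$times)
  }
  dec <- decimate_epochs(sim$epochs, 2)
  expect_lt(length(dec$times), length(sim$epochs$times))
})
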