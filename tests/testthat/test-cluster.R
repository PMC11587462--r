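test_that("adjacency matches brute-force pairwise distances", {
  lay2 <- data.frame(channel = c("A", "B"), x = c(0, 0.3), y = c(0, 0))
  adj <- build_adjacency(lay2, 0.3)
  expect_true(adj$matrix["A", "B"])
  expect_false(any(diag(adj$matrix)))
  expect_warning(build_adjacency(lay2, 0), "edgeless")
  g <- grid_layout(4, h = 0.2)
  adj <- build_adjacency(g, 1.5 * 0.2)
  # oracle: brute force
  D <- as.matrix(dist(g[, c("x", "y")]))
  expect_identical(unname(adj$matrix), unname(D <= 0.3 & D > 0))
  interior <- which(abs(g$x) < 0.2 & abs(g$y) < 0.2)
  # 1.5h reaches the sqrt(2)h diagonals, so interior sites have 8 neighbours
  expect_true(all(rowSums(adj$matrix)[interior] == 8))
  # a sub-diagonal threshold keeps only the 4 rook neighbours
  rook <- build_adjacency(g, 1.2 * 0.2)
  expect_true(all(rowSums(rook$matrix)[interior] == 4))
})

test_that("the samplewise statistic has its closed forms and null law", {
  b <- as_pgi_binned(array(c(1, 2, 3), c(3, 1, 1)), times = 1, sfreq = 1,
                     channels = "C1")
  sm <- samplewise_stat(b, intercept_regressor(b))
  expect_equal(unname(sm$t[1, 1]), 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(sm$df, 2L)
  # degenerate zero-residual fit is capped and flagged
  x <- setNames(c(1, 2, 3, 4), 1:4)
  bd <- as_pgi_binned(array(x, c(4, 1, 1)), 1, 1, "C1")
  reg <- factor_regressor(x)
  smd <- samplewise_stat(bd, reg)
  expect_true(smd$capped)
  expect_equal(unname(abs(smd$t[1, 1])), 1e6)
  # under independence the slope t follows Student t with df = n - 2
  set.seed(30)
  n <- 10
  Y <- array(rnorm(n * 1 * 10000), c(n, 1, 10000))
  bN <- as_pgi_binned(Y, times = seq_len(10000), sfreq = 1, channels = "C1")
  regN <- factor_regressor(setNames(rnorm(n), seq_len(n)))
  tN <- as.vector(samplewise_stat(bN, regN)$t)
  ks <- ks.test(tN, pt, df = n - 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster formation agrees with an independent flood-fill", {
  lay <- grid_layout(3, h = 0.2)
  adj <- build_adjacency(lay, 0.25)
  set.seed(31)
  tmat <- matrix(rnorm(9 * 30), 9, 30)
  tmat[2, 5:9] <- 5; tmat[5, 5:9] <- 5        # joined block (2 and 5 adjacent)
  tmat[9, 20:22] <- 5                          # separate block
  sm <- as_statmap(tmat, df = 20, channels = lay$channel)
  cl <- form_clusters(sm, adj, forming_alpha = 0.001, tail = 1)
  oracle <- oracle_clusters(tmat, qt(0.999, 20), adj$matrix, 1)
  expect_equal(length(cl), length(oracle))
  got <- lapply(cl, function(c) sort(c$member_index))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle, paste, collapse = ","))
  # masses sorted by |mass| descending, members suprathreshold on the tail
  masses <- vapply(cl, function(c) abs(c$mass), 0)
  expect_true(all(diff(masses) <= 0))
  expect_true(all(unlist(lapply(cl, function(c) c$members$t)) > qt(0.999, 20)))
  # an all-zero map yields no clusters on either tail
  smz <- as_statmap(matrix(0, 9, 30), df = 20, channels = lay$channel)
  expect_length(form_clusters(smz, adj, 0.025, 1), 0)
  expect_length(form_clusters(smz, adj, 0.025, -1), 0)
  # a single suprathreshold sample is a size-1 cluster with mass = t
  sm1 <- as_statmap(matrix(c(rep(0, 10), 4, rep(0, 9 * 30 - 11)), 9, 30),
                    df = 20, channels = lay$channel)
  cl1 <- form_clusters(sm1, adj, 0.025, 1)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$n_samples, 1)
  expect_equal(cl1[[1]]$mass, 4)
})

test_that("raising the forming threshold never grows a cluster", {
  lay <- grid_layout(3, h = 0.2)
  adj <- build_adjacency(lay, 0.25)
  set.seed(32)
  tmat <- matrix(rnorm(9 * 40, sd = 2), 9, 40)
  sm <- as_statmap(tmat, df = 15, channels = lay$channel)
  for (tail in c(1, -1)) {
    loose <- form_clusters(sm, adj, 0.05, tail)
    tight <- form_clusters(sm, adj, 0.01, tail)
    expect_lte(sum(vapply(tight, `[[`, 0L, "n_samples")),
               sum(vapply(loose, `[[`, 0L, "n_samples")))
  }
})

test_that("permutation p-values follow the add-one Monte-Carlo estimator", {
  null <- structure(list(pos = c(1, 2, 3, 10), neg = c(0, 0, 0, 0),
                         n_perm = 4, scheme = "sign_flip",
                         exhaustive = FALSE, forming_alpha = 0.025),
                    class = "pg_perm_null")
  cl <- list(list(mass = 5, tail = 1, member_index = 1,
                  members = data.frame(channel = "C1", time = 1, t = 5)))
  out <- cluster_pvalues(cl, null, alpha = 0.05)
  expect_equal(out[[1]]$p_value, (1 + 1) / (4 + 1))
  # observed above every permutation max
  cl[[1]]$mass <- 99
  expect_equal(cluster_pvalues(cl, null)[[1]]$p_value, 1 / 5)
  # observed below all of them
  cl[[1]]$mass <- 0.5
  expect_equal(cluster_pvalues(cl, null)[[1]]$p_value, 1)
})

test_that("sign-flip Monte Carlo at full enumeration equals the exact null", {
  set.seed(33)
  n <- 5
  arr <- array(rnorm(n * 2 * 8), c(n, 2, 8))
  arr[, 1, 3:6] <- arr[, 1, 3:6] + 1.5
  b <- as_pgi_binned(arr, times = seq_len(8), sfreq = 1,
                     channels = c("A", "B"))
  lay <- data.frame(channel = c("A", "B"), x = c(0, 0.1), y = c(0, 0))
  adj <- build_adjacency(lay, 0.2)
  reg <- intercept_regressor(b)
  null <- permutation_null(b, reg, adj, scheme = "sign_flip",
                           exhaustive = TRUE)
  expect_equal(null$n_perm, 2^n)
  # oracle: direct enumeration with plain loops
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tcrit <- qt(0.975, n - 1)
  ora <- apply(S, 1, function(sg) {
    Ys <- arr * sg
    tm <- apply(Ys, c(2, 3), function(v) mean(v) / (sd(v) / sqrt(n)))
    max(c(0, vapply(oracle_clusters(tm, tcrit, adj$matrix, 1),
                    function(m) abs(sum(tm[m])), 0)))
  })
  expect_equal(sort(null$pos), sort(ora), tolerance = 1e-10)
})

test_that("rescaling a regressor changes no statistic, cluster, or p-value", {
  set.seed(34)
  n <- 12
  arr <- array(rnorm(n * 3 * 20), c(n, 3, 20))
  b <- as_pgi_binned(arr, times = seq_len(20), sfreq = 1,
                     channels = c("A", "B", "C"))
  lay <- data.frame(channel = c("A", "B", "C"), x = c(0, 0.1, 0.2), y = 0)
  adj <- build_adjacency(lay, 0.15)
  s <- setNames(rnorm(n), seq_len(n))
  r1 <- factor_regressor(s)
  r2 <- r1; r2$values <- 2.7 * r1$values
  m1 <- run_mua(b, list(a = r1), adj, window = c(1, 20), n_perm = 120,
                seed = 99)
  m2 <- run_mua(b, list(a = r2), adj, window = c(1, 20), n_perm = 120,
                seed = 99)
  expect_equal(m1$a$stat_map$t, m2$a$stat_map$t, tolerance = 1e-9)
  expect_equal(lapply(m1$a$clusters, `[[`, "p_value"),
               lapply(m2$a$clusters, `[[`, "p_value"))
})

test_that("fixed seeds make the whole inference bit-reproducible", {
  set.seed(35)
  arr <- array(rnorm(8 * 2 * 15), c(8, 2, 15))
  arr[, 1, 5:10] <- arr[, 1, 5:10] + 1
  b <- as_pgi_binned(arr, times = seq_len(15), sfreq = 1,
                     channels = c("A", "B"))
  lay <- data.frame(channel = c("A", "B"), x = c(0, 0.1), y = 0)
  adj <- build_adjacency(lay, 0.2)
  m1 <- run_mua(b, list(mean = intercept_regressor(b)), adj,
                window = c(1, 15), n_perm = 100, seed = 7)
  m2 <- run_mua(b, list(mean = intercept_regressor(b)), adj,
                window = c(1, 15), n_perm = 100, seed = 7)
  expect_identical(m1$mean$null$pos, m2$mean$null$pos)
  expect_identical(cluster_table(m1, 1.1), cluster_table(m2, 1.1))
})

test_that("effect sizes and peak selection follow their stated conventions", {
  cl <- list(member_index = 1:3,
             members = data.frame(channel = c("A", "A", "B"),
                                  time = c(1, 2, 2), t = c(3, 15.1, 4)),
             mass = 22.1, tail = 1, n_samples = 3, time_range = c(1, 2))
  out <- effect_sizes(cl, n_participants = 34, df = 33)
  expect_equal(out$peak_t, 15.1)
  expect_equal(out$peak_time, 2)
  expect_equal(out$r, sqrt(15.1^2 / (15.1^2 + 33)))
  expect_equal(out$d_one_sample, 15.1 / sqrt(34), tolerance = 1e-4)
  expect_equal(round(out$d_one_sample, 2), 2.59)
  expect_equal(out$d_regression, 2 * 15.1 / sqrt(33))
  # r at t = df
  cl2 <- cl; cl2$members$t <- c(1, 33, 2)
  expect_equal(effect_sizes(cl2, 34, 33)$r, sqrt(33 / 34))
  # peak electrode: most member timepoints, then larger sum |t|, then name
  expect_equal(select_peak_electrode(cl), "A")
  tie <- cl
  tie$members <- data.frame(channel = c("A", "A", "B", "B"),
                            time = c(1, 2, 1, 2), t = c(1, 1, 3, 3))
  expect_equal(select_peak_electrode(tie), "B")
  tie$members$t <- rep(1, 4)
  expect_equal(select_peak_electrode(tie), "A")
  expect_error(effect_sizes(cl, 34, 0), "df")
})

test_that("an empty analysis window is rejected", {
  arr <- array(rnorm(4 * 2 * 10), c(4, 2, 10))
  b <- as_pgi_binned(arr, times = seq_len(10), sfreq = 1,
                     channels = c("A", "B"))
  lay <- data.frame(channel = c("A", "B"), x = c(0, 0.1), y = 0)
  adj <- build_adjacency(lay, 0.2)
  expect_error(run_mua(b, list(m = intercept_regressor(b)), adj,
                       window = c(100, 200), n_perm = 10),
               "window")
})
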