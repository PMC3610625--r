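mk_seq <- function(log2f, kinds, context = context_spec("broad")) {
  structure(list(
    context = context,
    events = data.frame(onset_s = (seq_along(log2f) - 1) * 0.5,
                        log2f = log2f, kind = kinds,
                        stringsAsFactors = FALSE),
    seed = 0L), class = "stim_sequence")
}

test_that("N_a counts the run of out-of-window tones before the probe", {
  # toy sequence: 2.05 is inside the 1/3-octave window and stops the run
  s <- mk_seq(c(0.1, 2.05, 0.3, 0.2, 2),
              c("contextual", "contextual", "contextual", "contextual",
                "odd_probe"))
  expect_equal(compute_na(s, 5, 1 / 3), 2)
  # tone immediately before the probe inside the window: N_a = 0
  s2 <- mk_seq(c(0.3, 1.95, 2), c("contextual", "contextual", "odd_probe"))
  expect_equal(compute_na(s2, 3, 1 / 3), 0)
  # probe first in the sequence: empty run
  s3 <- mk_seq(2, "odd_probe")
  expect_equal(compute_na(s3, 1, 1 / 3), 0)
  # preceding probes count as in-window tones ("tones of all types")
  s4 <- mk_seq(c(2, 0.1, 2), c("odd_probe", "contextual", "odd_probe"))
  expect_equal(compute_na(s4, 3, 1 / 3), 1)
  expect_error(compute_na(s, 3, 1 / 3), "odd probe")
  expect_error(compute_na(s, 5, -1), "positive")
})

test_that("compute_na agrees with a brute-force scan on random sequences", {
  brute <- function(log2f, i, delta, centre = 2) {
    # independent oracle: mark out-of-window tones, take the trailing run
    out <- abs(log2f - centre) > delta / 2
    before <- rev(out[seq_len(i - 1)])
    run <- which(!before)
    if (length(run) == 0) i - 1 else run[1] - 1
  }
  withr::with_seed(42, {
    for (r in 1:1000) {
      n <- sample(2:30, 1)
      log2f <- round(runif(n, -1, 3), 2)
      probe_at <- n
      log2f[probe_at] <- 2
      kinds <- rep("contextual", n)
      kinds[probe_at] <- "odd_probe"
      delta <- runif(1, 0.1, 2)
      s <- mk_seq(log2f, kinds)
      expect_identical(as.integer(compute_na(s, probe_at, delta)),
                       as.integer(brute(log2f, probe_at, delta)))
    }
  })
})

test_that("probe grouping by threshold and bin behaves correctly", {
  n <- 40
  labels <- data.frame(
    event_index = 1:n,
    kind = rep(c("odd_probe", "contextual"), each = n / 2),
    context = rep(c("narrow", "broad"), n / 2),
    stringsAsFactors = FALSE)
  na <- c(rep(c(0, 1, 3, 8, 20), 4), rep(NA, n / 2))
  y <- matrix(rnorm(10 * n), 10, n)
  g <- group_probes(y, labels, na, "threshold", cutpoints = c(0, 2, 8, 15))
  # cutpoint 0 captures every odd probe of the context
  expect_equal(g$n[g$context == "narrow" & g$cutpoint == 0], 10)
  # counts weakly decrease as the threshold grows
  for (ctx in c("narrow", "broad")) {
    expect_true(all(diff(g$n[g$context == ctx]) <= 0))
  }
  # group ERF is the mean of member traces
  i1 <- g$indices[g$context == "narrow" & g$cutpoint == 2][[1]]
  expect_equal(g$erf[g$context == "narrow" & g$cutpoint == 2][[1]],
               rowMeans(y[, i1]))
  # bins partition: counts sum to the total per context
  gb <- group_probes(y, labels, na, "bin", cutpoints = c(0, 2, 8, 15))
  expect_equal(sum(gb$n[gb$context == "broad"]), 10)
  # empty groups are retained and flagged
  g2 <- group_probes(y, labels, na, "threshold", cutpoints = c(0, 100))
  expect_true(any(!g2$ok & g2$n == 0))
  expect_error(group_probes(y, labels, na, "threshold", c(3, 1)),
               "increasing")
})

test_that("peak extraction averages around the ERF minimum", {
  times <- seq(-0.1, 0.35, by = 0.005)
  # flat zero responses give zero peaks
  z <- matrix(0, length(times), 4)
  pv0 <- peak_value(rep(0, length(times)), z, times)
  expect_equal(unname(pv0$peaks), rep(0, 4))
  # planted negative bump: latency found, peak = windowed mean (closed form)
  kern <- -exp(-(times - 0.15)^2 / (2 * 0.03^2))
  pv <- peak_value(kern, cbind(kern, 2 * kern), times)
  expect_equal(pv$latency, 0.15)
  win <- abs(times - 0.15) <= 0.030 + 1e-9
  expect_equal(unname(pv$peaks), c(mean(kern[win]), 2 * mean(kern[win])))
  # a response equal to the ERF has peak = the ERF's own windowed mean
  expect_equal(pv$peaks[[1]], mean(kern[win]))
  expect_error(peak_value(kern, z, times, search = c(0.05, 0.6)),
               "outside")
})

test_that("the sampled permutation test is valid and matches enumeration", {
  # identical constant groups: all permutations tie, p = 1
  pt <- permutation_test(rep(1, 5), rep(1, 7), n_perm = 100, seed = 1)
  expect_equal(pt$p, 1)
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  # determinism given the seed
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(permutation_test(a, b, 500, seed = 9)$p,
               permutation_test(a, b, 500, seed = 9)$p)

  # perfectly separated groups, n = 8 + 8: exact enumeration gives
  # p_exact = 1/C(16,8); the sampled test must be as extreme as possible
  narrow <- -(10:3); broad <- 3:10
  pt2 <- permutation_test(narrow, broad, n_perm = 2500, seed = 2)
  expect_lte(pt2$p, 0.01)
  # only re-draws of the observed split tie it; a handful at most in 2500
  expect_lte(pt2$p, 3 / 2501)

  # exhaustive oracle for small groups: enumerate all C(12,6) assignments
  exhaustive_p <- function(x1, x2) {
    pooled <- c(x1, x2)
    n1 <- length(x1)
    d_obs <- mean(x2) - mean(x1)
    combs <- combn(length(pooled), n1)
    d <- apply(combs, 2, function(idx) {
      mean(pooled[-idx]) - mean(pooled[idx])
    })
    mean(d >= d_obs)
  }
  withr::with_seed(11, {
    for (r in 1:5) {
      x1 <- rnorm(6); x2 <- rnorm(6) + 0.5
      p_ex <- exhaustive_p(x1, x2)
      p_s <- permutation_test(x1, x2, n_perm = 2000, seed = r)$p
      se <- sqrt(p_ex * (1 - p_ex) / 2000)
      expect_lt(abs(p_s - p_ex), 3 * se + 2 / 2000)
    }
  })
})

test_that("null permutation p-values are close to uniform", {
  withr::with_seed(23, {
    ps <- sapply(1:300, function(r) {
      x <- rnorm(15); y <- rnorm(15)
      permutation_test(x, y, n_perm = 300, seed = r)$p
    })
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  # Kolmogorov distance bounded by Monte Carlo + discreteness slack
  expect_lt(unname(ks$statistic), 1.63 / sqrt(300) + 1 / 301)
})

test_that("the adaptation grid reflects the planted adaptation model", {
  # small end-to-end simulation, strong adaptation in broad context only
  cfg <- run_config(n_subjects = 4, n_tones_per_block = 400, n_channels = 24,
                    gen = gen_params(spatial_mix_rank = 8),
                    deltas = c(1 / 3, 1), thresholds = c(0, 2, 8),
                    n_perm_adapt = 500, n_perm_group = 200, grid = 16,
                    master_seed = 5)
  rep <- run_experiment(cfg, verbose = FALSE)
  ad <- subset(rep$adaptation, abs(delta - 1 / 3) < 1e-9)
  broad <- ad[ad$context == "broad", ]
  narrow <- ad[ad$context == "narrow", ]
  # broad-context peaks deepen with threshold; narrow stays deeper and flat
  expect_lt(broad$peak_mean[broad$cutpoint == 8],
            broad$peak_mean[broad$cutpoint == 0])
  expect_true(all(narrow$peak_mean < broad$peak_mean))
  expect_true(all(ad$p < 0.05))

  # a generator without adaptation yields a flat grid in both contexts
  cfg0 <- run_config(n_subjects = 2, n_tones_per_block = 400, n_channels = 24,
                     gen = gen_params(spatial_mix_rank = 8,
                                      adapt_rho = c(narrow = 0, broad = 0),
                                      noise_sd = 0.1, white_sd = 0.05),
                     deltas = 1 / 3, thresholds = c(0, 2, 8),
                     n_perm_adapt = 200, n_perm_group = 200, grid = 16,
                     master_seed = 6)
  rep0 <- run_experiment(cfg0, verbose = FALSE)
  for (ctx in c("narrow", "broad")) {
    pk <- rep0$adaptation$peak_mean[rep0$adaptation$context == ctx]
    expect_lt(max(pk) - min(pk), 0.05 * max(abs(pk)))
  }
})
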