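# Small planted-component epoch sets for filter tests: one spatial pattern
# carrying a temporal kernel, plus white noise.
planted_epochs <- function(n_epochs = 60, n_ch = 24, n_s = 40, amp = 1,
                           noise = 0.5, seed = 1, condition = "ol") {
  withr::with_seed(seed, {
    pat <- rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
    times <- seq(0, 0.39, length.out = n_s)
    kern <- -sin(2 * pi * times / 0.4)
    arr <- array(rnorm(n_s * n_ch * n_epochs, 0, noise),
                 c(n_s, n_ch, n_epochs))
    for (e in seq_len(n_epochs)) {
      arr[, , e] <- arr[, , e] + amp * kern %o% pat
    }
    ep <- manual_epochs(arr, labels = data.frame(
      event_index = seq_len(n_epochs), condition = condition))
    attr(ep, "pattern") <- pat
    ep
  })
}

test_that("signal power is the time-averaged outer product of the ERF", {
  ep <- planted_epochs(noise = 0)
  S <- signal_power(ep, "ol")
  expect_equal(S, t(S))
  # a single planted pattern gives a rank-1 matrix
  expect_equal(sum(eigen(S, symmetric = TRUE, only.values = TRUE)$values >
                     1e-10 * sum(diag(S))), 1)
  # trace identity: trace(S) = mean squared ERF amplitude
  xbar <- rowSums(ep$data, dims = 2) / dim(ep$data)[3]
  expect_equal(sum(diag(S)), mean(rowSums(xbar^2)))
  # zero-mean data gives the zero matrix
  x <- array(rnorm(40 * 4 * 2), c(40, 4, 2))
  x[, , 2] <- -x[, , 1]
  ep0 <- manual_epochs(x, labels = data.frame(event_index = 1:2,
                                              condition = "ol"))
  expect_equal(max(abs(signal_power(ep0, "ol"))), 0)
  one <- subset_epochs(ep, 1)
  expect_error(signal_power(one, "ol"), ">= 2 epochs")
})

test_that("noise covariance matches residual structure", {
  # identical epochs: zero residual covariance
  x <- array(rnorm(30 * 5), c(30, 5, 1))[, , c(1, 1, 1)]
  ep <- manual_epochs(array(x, c(30, 5, 3)),
                      labels = data.frame(event_index = 1:3,
                                          condition = "sl"))
  expect_lt(max(abs(noise_cov(ep, "sl"))), 1e-12)
  # white-noise epochs: V ~ sigma^2 I
  sig <- 0.7
  epw <- withr::with_seed(4, manual_epochs(
    array(rnorm(50 * 6 * 400, 0, sig), c(50, 6, 400)),
    labels = data.frame(event_index = 1:400, condition = "sl")))
  V <- noise_cov(epw, "sl")
  expect_equal(V, t(V))
  n_eff <- 50 * 400
  expect_lt(max(abs(diag(V) - sig^2)), 3 * sig^2 * sqrt(2 / n_eff))
  expect_lt(max(abs(V[upper.tri(V)])), 3 * sig^2 / sqrt(n_eff))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
})

test_that("the generalized eigenproblem maximizes the Rayleigh quotient", {
  # identity matrices: lambda 1, first canonical axis
  f0 <- solve_filter(diag(6), diag(6), ridge = 0)
  expect_equal(f0$lambda, 1, tolerance = 1e-9)
  expect_equal(abs(f0$w), c(1, 0, 0, 0, 0, 0), tolerance = 1e-6)
  expect_error(solve_filter(diag(2), matrix(0, 2, 2), ridge = 0), "ridge")

  ep <- planted_epochs(n_epochs = 120, amp = 1.2, noise = 0.6, seed = 9)
  S <- signal_power(ep, "ol")
  V <- noise_cov(ep, "ol")
  f <- solve_filter(S, V)
  # lambda equals the Rayleigh quotient at w
  rq <- function(w) drop(w %*% S %*% w / (w %*% (V + diag(f$ridge, 24)) %*% w))
  expect_equal(rq(f$w), f$lambda, tolerance = 1e-9)
  # and dominates 10^4 random directions
  W <- withr::with_seed(2, matrix(rnorm(24 * 1e4), 24))
  num <- colSums((S %*% W) * W)
  den <- colSums(((V + diag(f$ridge, 24)) %*% W) * W)
  expect_true(all(num / den <= f$lambda + 1e-9))
})

test_that("whitening route reproduces the generalized solution", {
  ep <- planted_epochs(n_epochs = 80, seed = 3)
  S <- signal_power(ep, "ol")
  V <- noise_cov(ep, "ol")
  ridge <- 1e-6 * mean(diag(V))
  f <- solve_filter(S, V, ridge = ridge)
  # independent oracle: symmetric eigenproblem through V^{-1/2}
  eV <- eigen(V + diag(ridge, nrow(V)), symmetric = TRUE)
  Vmh <- eV$vectors %*% diag(1 / sqrt(eV$values)) %*% t(eV$vectors)
  M <- Vmh %*% S %*% Vmh
  u <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1]
  w_oracle <- drop(Vmh %*% u)
  cosang <- abs(sum(w_oracle * f$w)) /
    sqrt(sum(w_oracle^2) * sum(f$w^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("planted spatial patterns are recovered across seeds", {
  cors <- sapply(1:20, function(s) {
    ep <- planted_epochs(n_epochs = 100, amp = 1.5, noise = 0.5, seed = s)
    S <- signal_power(ep, "ol")
    V <- noise_cov(ep, "ol")
    f <- solve_filter(S, V)
    abs(cor(effective_pattern(V, f$w), attr(ep, "pattern")))
  })
  expect_true(all(cors > 0.95))
})

test_that("effective patterns and filtering behave linearly", {
  w <- c(0, 0, 1, 0)
  expect_equal(effective_pattern(diag(4), w), w)
  V <- crossprod(matrix(rnorm(16), 4))
  expect_equal(effective_pattern(V, 2 * w), 2 * effective_pattern(V, w))

  ep <- planted_epochs(n_epochs = 10, n_ch = 4, seed = 6)
  # a one-hot filter returns that channel
  y <- apply_filter(ep, w)
  expect_equal(y[, 3], ep$data[, 3, 3])
  expect_equal(y[, 1], ep$data[, 3, 1])
  # filter-then-average equals average-then-filter
  wf <- rnorm(4)
  yf <- apply_filter(ep, wf)
  expect_equal(rowMeans(yf),
               drop((rowSums(ep$data, dims = 2) / 10) %*% wf),
               tolerance = 1e-12)
  expect_error(apply_filter(ep, rnorm(5)), "channel count")

  # noiseless planted epochs filter to a trace proportional to the kernel
  ep0 <- planted_epochs(n_epochs = 5, noise = 0, seed = 8)
  f <- solve_filter(signal_power(ep0, "ol"),
                    noise_cov(ep0, "ol") + diag(1e-8, 24))
  y0 <- apply_filter(ep0, f)
  kern <- -sin(2 * pi * seq(0, 0.39, length.out = 40) / 0.4)
  expect_gt(abs(cor(y0[, 1], kern)), 1 - 1e-8)
})
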