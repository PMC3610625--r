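test_that("condition ERFs average epochs correctly", {
  ep <- condition_epochs(n_per = 3, noise = 0)
  e <- average_erf(ep, "ol")
  expect_equal(e$n_epochs, 3)
  expect_equal(e$mean, rowSums(ep$data[, , ep$labels$condition == "ol"],
                               dims = 2) / 3)
  # single epoch: the ERF is that epoch
  one <- manual_epochs(array(rnorm(91 * 2), c(91, 2, 1)),
                       labels = data.frame(event_index = 1, condition = "sl"))
  expect_equal(average_erf(one, "sl")$mean, one$data[, , 1])
  # x and -x average to zero
  x <- array(rnorm(91 * 2 * 2), c(91, 2, 2))
  x[, , 2] <- -x[, , 1]
  two <- manual_epochs(x, labels = data.frame(event_index = 1:2,
                                              condition = "oh"))
  expect_equal(max(abs(average_erf(two, "oh")$mean)), 0)
  expect_error(average_erf(one, "oh"), "no epochs.*'oh'")
})

test_that("scalp interpolation is exact on constant and affine fields", {
  lay <- tiny_layout(30)
  interp <- scalp_interpolator(lay, grid = 32)
  img_c <- scalp_image(rep(4.2, 30), interp)
  expect_equal(max(abs(img_c[interp$mask] - 4.2)), 0, tolerance = 1e-7)
  # affine-in-position fields are reproduced exactly inside the hull
  f <- 0.7 + 1.3 * lay$pos2d[, 1] - 2.1 * lay$pos2d[, 2]
  img_a <- scalp_image(f, interp)
  px <- rep(interp$gx, times = 32)[interp$mask]
  py <- rep(interp$gy, each = 32)[interp$mask]
  expect_equal(img_a[interp$mask], 0.7 + 1.3 * px - 2.1 * py,
               tolerance = 1e-6)
  # out-of-hull pixels are masked
  expect_true(all(is.na(img_a[!interp$mask])))
  # a one-hot field peaks at (a pixel adjacent to) that sensor
  k <- 7
  img_1 <- scalp_image(as.numeric(seq_len(30) == k), interp)
  pk <- which(img_1 == max(img_1, na.rm = TRUE), arr.ind = TRUE)[1, ]
  px_step <- diff(interp$gx[1:2])
  expect_lt(abs(interp$gx[pk[1]] - lay$pos2d[k, 1]), 2 * px_step)
  expect_lt(abs(interp$gy[pk[2]] - lay$pos2d[k, 2]), 2 * px_step)
  expect_error(scalp_image(rep(1, 29), interp), "29")
})

test_that("spatio-temporal volumes stack scalp maps over time", {
  lay <- tiny_layout(20)
  interp <- scalp_interpolator(lay, grid = 64)
  m <- matrix(rnorm(91 * 20), 91, 20)
  vol <- build_volume(m, interp, times = seq(-0.1, 0.35, length.out = 91))
  expect_equal(dim(vol$values), c(64, 64, 91))
  expect_equal(vol$values[, , 5][interp$mask],
               scalp_image(m[5, ], interp)[interp$mask])
  vol0 <- build_volume(matrix(0, 3, 20), interp)
  expect_equal(max(abs(vol0$values), na.rm = TRUE), 0)
  expect_equal(dim(vol0$values)[3], 3)
  v1 <- build_volume(matrix(0, 1, 20), interp)
  expect_equal(dim(v1$values), c(64, 64, 1))
  expect_error(build_volume(matrix(0, 3, 7), interp), "mismatch")
})

test_that("the condition GLM recovers means and ignores confounds", {
  ep <- condition_epochs(n_per = 6, noise = 0)
  fit <- fit_glm(ep)
  # balanced noiseless design: betas are the condition means
  for (cc in c("sl", "sh", "ol", "oh")) {
    expect_equal(fit$beta[cc, , ], average_erf(ep, cc)$mean,
                 tolerance = 1e-10)
  }
  # condition-average mode agrees on balanced data
  fit_avg <- fit_glm(ep, mode = "average")
  expect_equal(fit$beta, fit_avg$beta, tolerance = 1e-10)
  # adding a block/context confound leaves condition differences unchanged
  ep2 <- ep
  ep2$labels$block <- ifelse(ep2$labels$context == "narrow", 1, 2)
  fit2 <- fit_glm(ep2)
  expect_equal(fit2$beta["ol", , ] - fit2$beta["sl", , ],
               fit$beta["ol", , ] - fit$beta["sl", , ], tolerance = 1e-10)
  # missing condition errors
  ep3 <- subset_epochs(ep, ep$labels$condition != "oh")
  expect_error(fit_glm(ep3), "oh")
})

test_that("surprise and interaction contrasts behave as designed", {
  ep <- condition_epochs(n_per = 5, noise = 0,
                         amps = c(sl = -0.3, sh = -0.3, ol = -0.3, oh = -0.3))
  fit <- fit_glm(ep)
  # equal betas: both contrasts vanish
  expect_lt(max(abs(contrast_surprise(fit)$field)), 1e-10)
  expect_lt(max(abs(contrast_interaction(fit)$field)), 1e-10)
  # equal MMN in both contexts: interaction zero, surprise nonzero
  ep2 <- condition_epochs(n_per = 5, noise = 0,
                          amps = c(sl = -0.2, sh = -0.5, ol = -0.7,
                                   oh = -1.0))
  fit2 <- fit_glm(ep2)
  expect_lt(max(abs(contrast_interaction(fit2)$field)), 1e-10)
  expect_gt(max(abs(contrast_surprise(fit2)$field)), 0.1)
  # the two weight vectors are orthogonal
  w_s <- contrast_surprise(fit)$weights
  w_i <- contrast_interaction(fit)$weights
  expect_equal(sum(unlist(w_s)[names(w_i)] * unlist(w_i)), 0)
  # narrow-deeper MMN gives an interaction with the planted sign
  ep3 <- condition_epochs(n_per = 5, noise = 0)
  ci <- contrast_interaction(fit_glm(ep3))
  # (ol - sl) - (oh - sh) = (-1.2 + 0.2) - (-0.7 + 0.5) = -0.8 at the peak
  pk <- which.max(abs(attr(ep3, "kernel")))
  expect_equal(ci$field[pk, ], -0.8 * attr(ep3, "pattern"), tolerance = 1e-8)
})

test_that("group sign-flip inference detects planted effects and not null", {
  lay <- tiny_layout(12)
  interp <- scalp_interpolator(lay, grid = 16)
  mk_vol <- function(m) build_volume(m, interp,
                                     times = seq(0, 1, length.out = nrow(m)))
  # all-zero volumes: nothing significant
  vols0 <- lapply(1:6, function(i) mk_vol(matrix(0, 10, 12)))
  res0 <- group_inference(vols0, n_perm = 200, seed = 1)
  expect_equal(sum(res0$mask$values > 0, na.rm = TRUE), 0)
  # planted strong effect in a channel/time block across 12 subjects
  withr::with_seed(8, {
    vols <- lapply(1:12, function(i) {
      m <- matrix(rnorm(10 * 12, 0, 0.3), 10, 12)
      m[4:6, 3] <- m[4:6, 3] + 3
      mk_vol(m)
    })
  })
  res <- group_inference(vols, n_perm = 500, seed = 2)
  # the voxel nearest sensor 3 at times 4..6 must be inside the mask
  d2 <- (rep(interp$gx, times = 16) - lay$pos2d[3, 1])^2 +
    (rep(interp$gy, each = 16) - lay$pos2d[3, 2])^2
  vox <- arrayInd(which.min(d2 + !interp$mask), c(16, 16))
  expect_true(all(res$mask$values[vox[1], vox[2], 4:6] > 0))
  expect_error(group_inference(vols[1], n_perm = 200), "2 subjects")
  expect_warning(group_inference(vols0, n_perm = 50), "100")
})

test_that("family-wise error of max-statistic inference is controlled", {
  lay <- tiny_layout(8)
  interp <- scalp_interpolator(lay, grid = 8)
  n_rep <- 200
  rejections <- withr::with_seed(31, {
    sapply(seq_len(n_rep), function(r) {
      vols <- lapply(1:8, function(i) {
        build_volume(matrix(rnorm(6 * 8, 0, 1), 6, 8), interp,
                     times = seq(0, 1, length.out = 6))
      })
      res <- group_inference(vols, n_perm = 200, alpha = 0.05,
                             seed = r + 1000)
      any(res$mask$values > 0, na.rm = TRUE)
    })
  })
  fwer <- mean(rejections)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
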