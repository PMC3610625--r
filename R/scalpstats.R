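#' Average evoked response field for one condition
#'
#' @param epochs an `epoch_set` with a `condition` label column.
#' @param condition condition code, one of `"sl"`, `"sh"`, `"ol"`, `"oh"`
#'   (standard/odd probe x low/high contextual variance).
#' @return object of class `erf`: `mean` (samples x channels), `n_epochs`,
#'   `condition`, `times`, `fs_hz`.
#' @export
average_erf <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- which(!is.na(epochs$labels$condition) &
                 epochs$labels$condition == condition)
  if (length(sel) == 0) {
    stop(sprintf("no epochs with condition '%s'", condition))
  }
  arr <- epochs$data[, , sel, drop = FALSE]
  m <- rowSums(arr, dims = 2) / length(sel)
  structure(list(mean = m, n_epochs = length(sel), condition = condition,
                 times = epochs$times, fs_hz = epochs$fs_hz),
            class = "erf")
}

#' @export
print.erf <- function(x, ...) {
  cat(sprintf("<erf> condition %s: %d samples x %d channels, %d epochs\n",
              x$condition, nrow(x$mean), ncol(x$mean), x$n_epochs))
  invisible(x)
}

# Point-in-convex-polygon test (vertices in hull order); boundary counts in.
in_convex_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- rep(TRUE, length(px))
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (sgn == 0 && any(abs(cr) > 1e-12)) sgn <- sign(cr[which.max(abs(cr))])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  inside
}

#' Precompute the scalp-map interpolation operator
#'
#' Builds the linear operator that maps a per-channel field to a `grid x
#' grid` image over the fixed bounding square `[-1, 1]^2`, using exact
#' thin-plate-spline interpolation through the sensor positions (exact on
#' affine fields). Pixels outside the convex hull of the sensors are masked.
#' The operator is computed once per layout and reused for every time bin.
#'
#' @param layout a [make_layout()] result.
#' @param grid image size per side (default 64).
#' @return list with `W` (`grid^2 x n_channels` interpolation matrix),
#'   `mask` (`grid x grid` logical, in-hull pixels), `grid`, and the pixel
#'   coordinate vectors `gx`, `gy`.
#' @export
scalp_interpolator <- function(layout, grid = 64) {
  stopifnot(inherits(layout, "sensor_layout"))
  pos <- layout$pos2d
  n <- nrow(pos)
  tps_k <- function(r2) ifelse(r2 <= 0, 0, 0.5 * r2 * log(r2))
  d2 <- as.matrix(stats::dist(pos))^2
  K <- tps_k(d2)
  P <- cbind(1, pos)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  gx <- seq(-1, 1, length.out = grid)
  gy <- seq(-1, 1, length.out = grid)
  px <- rep(gx, times = grid)
  py <- rep(gy, each = grid)
  # pixel-to-centre basis
  r2 <- outer(px, pos[, 1], "-")^2 + outer(py, pos[, 2], "-")^2
  E <- cbind(tps_k(r2), 1, px, py)
  W <- (E %*% solve(M))[, seq_len(n), drop = FALSE]
  hull <- grDevices::chull(pos)
  mask <- matrix(in_convex_hull(px, py, pos[hull, 1], pos[hull, 2]),
                 grid, grid)
  list(W = W, mask = mask, grid = grid, gx = gx, gy = gy)
}

#' Interpolate one sensor field onto the scalp grid
#'
#' @param field numeric vector, one value per channel.
#' @param interp a [scalp_interpolator()] result (or a `sensor_layout`, from
#'   which one is built).
#' @return `grid x grid` matrix; out-of-hull pixels are `NA`.
#' @export
scalp_image <- function(field, interp) {
  if (inherits(interp, "sensor_layout")) interp <- scalp_interpolator(interp)
  if (length(field) != ncol(interp$W)) {
    stop(sprintf("field has %d values but the layout has %d channels",
                 length(field), ncol(interp$W)))
  }
  img <- matrix(interp$W %*% field, interp$grid, interp$grid)
  img[!interp$mask] <- NA_real_
  img
}

#' Build a spatio-temporal volume from an ERF
#'
#' Interpolates each time bin's sensor field into a 2-D scalp image and
#' stacks the images in peristimulus order: a 91-sample ERF yields a
#' 64 x 64 x 91 volume.
#'
#' @param erf an [average_erf()] result, or a samples x channels matrix.
#' @param interp a [scalp_interpolator()] result or a `sensor_layout`.
#' @param times optional time vector when `erf` is a bare matrix.
#' @return object of class `st_volume`: `values` (grid x grid x samples,
#'   `NA` outside the sensor hull), `mask`, `times`.
#' @export
build_volume <- function(erf, interp, times = NULL) {
  if (inherits(interp, "sensor_layout")) interp <- scalp_interpolator(interp)
  m <- if (inherits(erf, "erf")) erf$mean else erf
  if (inherits(erf, "erf")) times <- erf$times
  stopifnot(is.matrix(m))
  if (ncol(m) != ncol(interp$W)) {
    stop("sample/channel mismatch between ERF and layout")
  }
  flat <- interp$W %*% t(m)                      # pixels x samples
  flat[!interp$mask, ] <- NA_real_
  vol <- array(flat, dim = c(interp$grid, interp$grid, nrow(m)))
  structure(list(values = vol, mask = interp$mask, times = times),
            class = "st_volume")
}

#' Fit the mass-univariate condition GLM
#'
#' Ordinary least squares per (channel, sample) with one regressor per probe
#' condition (`sl`, `sh`, `ol`, `oh`) plus nuisance regressors for block and
#' the block-context (variance factor) assignment. Nuisance columns are first
#' orthogonalized against the condition regressors; columns entirely
#' explained by them (as happens when context is blocked) drop out, so
#' condition effects remain estimable. Because volumization is linear, betas
#' are fitted in channel space and can be converted to volumes afterwards,
#' which is algebraically identical to fitting per-epoch volumes.
#'
#' @param epochs an `epoch_set` of probe epochs with `condition` labels and,
#'   optionally, `block` labels.
#' @param mode `"epoch"` fits per-epoch OLS (default); `"average"` fits the
#'   cell-means model to condition-average ERFs (no nuisance).
#' @return object of class `glm_fit`: `beta` (4 x samples x channels array
#'   with condition dimnames), `conditions`, `n_per_condition`, `times`.
#' @export
fit_glm <- function(epochs, mode = c("epoch", "average")) {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode)
  conds <- c("sl", "sh", "ol", "oh")
  lab <- epochs$labels
  if (!all(conds %in% lab$condition)) {
    stop("missing condition(s): ",
         paste(setdiff(conds, unique(lab$condition)), collapse = ", "))
  }
  d <- dim(epochs$data)
  times <- epochs$times
  if (mode == "average") {
    beta <- array(NA_real_, c(4, d[1], d[2]), dimnames = list(conds))
    n_c <- integer(4)
    for (k in seq_along(conds)) {
      e <- average_erf(epochs, conds[k])
      beta[k, , ] <- e$mean
      n_c[k] <- e$n_epochs
    }
    return(structure(list(beta = beta, conditions = conds,
                          n_per_condition = stats::setNames(n_c, conds),
                          times = times, mode = mode),
                     class = "glm_fit"))
  }
  keep <- which(!is.na(lab$condition))
  X_cond <- sapply(conds, function(cc) as.numeric(lab$condition[keep] == cc))
  nuis <- NULL
  if (!is.null(lab$block) && length(unique(lab$block[keep])) > 1) {
    blocks <- sort(unique(lab$block[keep]))
    nuis <- cbind(nuis,
                  sapply(blocks[-1],
                         function(b) as.numeric(lab$block[keep] == b)))
  }
  if (!is.null(lab$context)) {
    nuis <- cbind(nuis, as.numeric(lab$context[keep] == "broad"))
  }
  X <- X_cond
  if (!is.null(nuis)) {
    # orthogonalize nuisance on conditions; drop annihilated columns
    proj <- X_cond %*% solve(crossprod(X_cond), crossprod(X_cond, nuis))
    nperp <- nuis - proj
    norms <- sqrt(colSums(nperp^2))
    keep_n <- norms > 1e-8 * sqrt(length(keep))
    if (any(keep_n)) X <- cbind(X_cond, nperp[, keep_n, drop = FALSE])
  }
  colnames(X) <- c(conds,
                   if (ncol(X) > 4) paste0("nuisance", seq_len(ncol(X) - 4)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- matrix(aperm(epochs$data[, , keep, drop = FALSE], c(3, 1, 2)),
              nrow = length(keep))
  B <- solve(crossprod(X), crossprod(X, Y))
  beta <- array(B[seq_len(4), , drop = FALSE], c(4, d[1], d[2]),
                dimnames = list(conds))
  structure(list(beta = beta, conditions = conds,
                 n_per_condition = colSums(X_cond),
                 times = times, mode = mode),
            class = "glm_fit")
}

contrast_field <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  miss <- setdiff(names(weights), dimnames(fit$beta)[[1]])
  if (length(miss)) stop("missing condition(s): ", paste(miss, collapse = ", "))
  f <- 0
  for (cc in names(weights)) {
    f <- f + weights[[cc]] * fit$beta[cc, , ]
  }
  structure(list(field = f, weights = weights, times = fit$times),
            class = "contrast_field")
}

#' Surprise contrast (standards minus odds, both contexts)
#'
#' Weight vector `(b_sl + b_sh) - (b_ol + b_oh)`: the main effect of surprise
#' regardless of contextual variance. The MMN makes odd-probe responses more
#' negative, so this contrast is positive where an MMN-like deflection is
#' present.
#'
#' @param fit a [fit_glm()] result.
#' @return `contrast_field`: per-subject contrast in channel space
#'   (samples x channels) with its weights.
#' @export
contrast_surprise <- function(fit) {
  contrast_field(fit, c(sl = 1, sh = 1, ol = -1, oh = -1))
}

#' Interaction contrast (MMN difference between contexts)
#'
#' Weight vector `(b_ol - b_sl) - (b_oh - b_sh)`: the difference between the
#' odd-minus-standard effect under the low-variance (narrow) and the
#' high-variance (broad) context. Orthogonal to the surprise contrast.
#'
#' @param fit a [fit_glm()] result.
#' @return a `contrast_field`.
#' @export
contrast_interaction <- function(fit) {
  contrast_field(fit, c(sl = -1, sh = 1, ol = 1, oh = -1))
}

#' Group-level inference by sign-flip max-statistic permutation
#'
#' Computes a voxelwise one-sample t statistic across subject contrast
#' volumes and controls the family-wise error over the whole spatio-temporal
#' volume with a sign-flip max-|t| permutation distribution (subject signs
#' are exchangeable under the null of zero mean contrast).
#'
#' @param volumes list of subject `st_volume`s (same geometry), `>= 2`.
#' @param n_perm number of sign-flip permutations (a warning is issued below
#'   100).
#' @param alpha family-wise significance level.
#' @param seed integer seed for the permutation draws.
#' @return object of class `contrast_result`: `t`, `p` (corrected) and
#'   `mask` as `st_volume`s, plus `max_dist`, `alpha`, `n_perm`,
#'   `n_subjects`.
#' @export
group_inference <- function(volumes, n_perm = 1000, alpha = 0.05, seed = 1) {
  if (length(volumes) < 2) stop("group inference needs at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  nsub <- length(volumes)
  vox_ok <- !is.na(volumes[[1]]$values)
  X <- sapply(volumes, function(v) v$values[vox_ok])   # voxels x subjects
  n <- nsub
  ssq <- rowSums(X^2)
  mu <- rowMeans(X)
  vv <- pmax(ssq - n * mu^2, 0) / (n - 1)
  t_obs <- mu / sqrt(vv / n + 1e-300)
  max_dist <- with_seed(seed, {
    out <- numeric(n_perm)
    chunk <- 100L
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      Sg <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
      Mu <- (X %*% Sg) / n
      Tm <- abs(Mu) / sqrt(pmax(ssq - n * Mu^2, 0) / (n - 1) / n + 1e-300)
      out[done + seq_len(m)] <- apply(Tm, 2, max)
      done <- done + m
    }
    out
  })
  srt <- sort(max_dist)
  n_ge <- n_perm - findInterval(abs(t_obs) - 1e-12, srt)
  p_vox <- (1 + n_ge) / (1 + n_perm)
  mk_vol <- function(vals) {
    v <- volumes[[1]]
    v$values[vox_ok] <- vals
    v
  }
  structure(list(t = mk_vol(t_obs), p = mk_vol(p_vox),
                 mask = mk_vol(as.numeric(p_vox <= alpha)),
                 max_dist = max_dist, alpha = alpha, n_perm = n_perm,
                 n_subjects = nsub),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  nsig <- sum(x$mask$values > 0, na.rm = TRUE)
  cat(sprintf(
    "<contrast_result> %d subjects, %d permutations: %d voxel(s) significant at corrected p <= %g (max |t| = %.2f)\n",
    x$n_subjects, x$n_perm, nsig, x$alpha,
    max(abs(x$t$values), na.rm = TRUE)))
  invisible(x)
}
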