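#' Condition-specific signal power matrix
#'
#' Time-averaged outer product of the condition-mean ERF:
#' `S_c = (1/T) sum_t xbar_c(t) xbar_c(t)'`. This captures the spatial power
#' of the phase-locked (evoked) part of the response.
#'
#' @param epochs an `epoch_set` with condition labels.
#' @param condition condition code (`"sl"`, `"sh"`, `"ol"`, `"oh"`).
#' @return channels x channels positive semi-definite matrix.
#' @export
signal_power <- function(epochs, condition) {
  sel <- which(!is.na(epochs$labels$condition) &
                 epochs$labels$condition == condition)
  if (length(sel) < 2) {
    stop(sprintf("need >= 2 epochs in condition '%s'", condition))
  }
  xbar <- rowSums(epochs$data[, , sel, drop = FALSE], dims = 2) / length(sel)
  crossprod(xbar) / nrow(xbar)
}

#' Condition-specific noise covariance matrix
#'
#' Covariance of the residuals about the condition mean, pooled over epochs
#' and time samples:
#' `V_c = (1/(N_c T)) sum_n sum_t (x_n(t) - xbar(t))(x_n(t) - xbar(t))'`.
#'
#' @inheritParams signal_power
#' @return channels x channels symmetric positive semi-definite matrix.
#' @export
noise_cov <- function(epochs, condition) {
  sel <- which(!is.na(epochs$labels$condition) &
                 epochs$labels$condition == condition)
  if (length(sel) < 2) {
    stop(sprintf("need >= 2 epochs in condition '%s'", condition))
  }
  arr <- epochs$data[, , sel, drop = FALSE]
  d <- dim(arr)
  xbar <- rowSums(arr, dims = 2) / d[3]
  resid <- arr - array(xbar, d)                 # recycles over epochs
  M <- matrix(aperm(resid, c(1, 3, 2)), ncol = d[2])
  crossprod(M) / (d[1] * d[3])
}

#' Averaged signal-power and noise-covariance pair
#'
#' Computes `S_c` and `V_c` for each of the four probe conditions and
#' averages them into the overall pair `(S, V)` used by [solve_filter()].
#'
#' @param epochs an `epoch_set` with condition labels.
#' @param conditions condition codes to include.
#' @return object of class `cov_pair`: `S`, `V`, per-condition `S_c`, `V_c`,
#'   and epoch counts `N_c`.
#' @export
cov_pair <- function(epochs, conditions = c("sl", "sh", "ol", "oh")) {
  S_c <- lapply(conditions, function(cc) signal_power(epochs, cc))
  V_c <- lapply(conditions, function(cc) noise_cov(epochs, cc))
  names(S_c) <- names(V_c) <- conditions
  N_c <- vapply(conditions, function(cc) {
    sum(!is.na(epochs$labels$condition) & epochs$labels$condition == cc)
  }, numeric(1))
  structure(list(S = Reduce(`+`, S_c) / length(S_c),
                 V = Reduce(`+`, V_c) / length(V_c),
                 S_c = S_c, V_c = V_c, N_c = N_c),
            class = "cov_pair")
}

#' Average two or more covariance pairs (e.g. across subjects)
#'
#' @param pairs list of `cov_pair`s with identical conditions.
#' @return a pooled `cov_pair` (unweighted average of the matrices, summed
#'   counts).
#' @export
pool_cov_pairs <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  avg <- function(get) Reduce(`+`, lapply(pairs, get)) / length(pairs)
  structure(list(S = avg(function(p) p$S), V = avg(function(p) p$V),
                 S_c = NULL, V_c = NULL,
                 N_c = Reduce(`+`, lapply(pairs, function(p) p$N_c))),
            class = "cov_pair")
}

#' Maximum signal-to-noise spatial filter
#'
#' Solves the generalized eigenvalue problem `S w = lambda (V + ridge I) w`
#' and returns the eigenvector with the largest eigenvalue: the channel
#' weighting that maximizes the ratio of evoked signal power to noise power.
#' Internally the problem is whitened through a Cholesky factor of the
#' regularized noise covariance and solved as a symmetric eigenproblem. The
#' weight vector is normalized to unit norm in the noise metric
#' (`w' (V + ridge I) w = 1`).
#'
#' The sign of a (generalized) eigenvector is arbitrary; if `orient_erf` is
#' supplied (samples x channels, with `times`), the sign is fixed so that the
#' filtered trace is negative on average within `orient_window` — pass the
#' grand-mean odd-minus-standard difference ERF so the extracted MMN deflects
#' downward. Otherwise the largest-magnitude weight is made positive.
#'
#' @param S signal power matrix (symmetric PSD).
#' @param V noise covariance matrix (symmetric).
#' @param ridge Tikhonov regularization added to `V`'s diagonal; default
#'   `1e-6 * mean(diag(V))`.
#' @param orient_erf optional samples x channels reference ERF for the sign
#'   convention.
#' @param times,orient_window time vector of `orient_erf` and the window (s)
#'   over which its filtered mean must be negative.
#' @return object of class `spatial_filter`: `w`, `lambda`, `pattern`
#'   (`V %*% w`, the effective forward pattern of the extracted component),
#'   `ridge`.
#' @export
solve_filter <- function(S, V, ridge = 1e-6 * mean(diag(V)),
                         orient_erf = NULL, times = NULL,
                         orient_window = c(0.100, 0.200)) {
  stopifnot(is.matrix(S), is.matrix(V), all(dim(S) == dim(V)))
  Vr <- V + diag(ridge, nrow(V))
  R <- tryCatch(chol(Vr), error = function(e) {
    stop("noise covariance is singular; increase `ridge`")
  })
  Rinv <- backsolve(R, diag(nrow(V)))
  Mw <- t(Rinv) %*% S %*% Rinv
  Mw <- (Mw + t(Mw)) / 2
  eg <- eigen(Mw, symmetric = TRUE)
  u <- eg$vectors[, 1]
  # deterministic tie-break for a degenerate top eigenvalue: project the
  # first canonical axis onto the tied eigenspace
  tied <- which(eg$values >= eg$values[1] - 1e-10 * max(abs(eg$values[1]), 1))
  if (length(tied) > 1) {
    U <- eg$vectors[, tied, drop = FALSE]
    cand <- drop(U %*% U[1, ])
    if (sqrt(sum(cand^2)) > 1e-8) u <- cand / sqrt(sum(cand^2))
  }
  w <- drop(Rinv %*% u)                 # w' Vr w = u'u = 1
  if (!is.null(orient_erf)) {
    stopifnot(!is.null(times))
    y <- drop(orient_erf %*% w)
    sel <- times >= orient_window[1] & times <= orient_window[2]
    if (mean(y[sel]) > 0) w <- -w
  } else if (w[which.max(abs(w))] < 0) {
    w <- -w
  }
  structure(list(w = w, lambda = eg$values[1], pattern = drop(V %*% w),
                 ridge = ridge),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d channels, lambda (SNR) = %.3f\n",
              length(x$w), x$lambda))
  invisible(x)
}

#' Effective forward pattern of a spatial filter
#'
#' The filter weights trade signal capture against noise suppression; the
#' spatial pattern of the *extracted component* is recovered by
#' pre-multiplying the weights by the noise covariance: `V %*% w`.
#'
#' @param V noise covariance matrix.
#' @param w filter weight vector.
#' @return numeric pattern vector.
#' @export
effective_pattern <- function(V, w) {
  stopifnot(ncol(V) == length(w))
  drop(V %*% w)
}

#' Apply a spatial filter to epochs
#'
#' Projects every epoch onto the filter: `y_e(t) = w' x_e(t)`, yielding
#' one-dimensional filtered traces. Filtering commutes with averaging.
#'
#' @param epochs an `epoch_set`.
#' @param w a `spatial_filter` or a bare weight vector.
#' @return samples x epochs matrix of filtered traces, with the epoch times
#'   as the `times` attribute.
#' @export
apply_filter <- function(epochs, w) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (inherits(w, "spatial_filter")) w <- w$w
  d <- dim(epochs$data)
  if (d[2] != length(w)) stop("filter length does not match channel count")
  y <- matrix(0, d[1], d[3])
  for (e in seq_len(d[3])) {
    y[, e] <- epochs$data[, , e] %*% w
  }
  attr(y, "times") <- epochs$times
  y
}

#' Serialize a spatial filter to JSON
#'
#' @param filter a `spatial_filter`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter <- function(filter, path) {
  jsonlite::write_json(list(w = filter$w, lambda = filter$lambda,
                            pattern = filter$pattern, ridge = filter$ridge),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
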