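# Length of the maximal run of tones immediately preceding `index` whose
# log2-frequencies all fall outside the window of full width `delta` centred
# at `centre`; the run stops at the first in-window tone.
na_run_length <- function(log2f, index, delta, centre) {
  n <- 0L
  i <- index - 1L
  half <- delta / 2
  while (i >= 1L && abs(log2f[i] - centre) > half) {
    n <- n + 1L
    i <- i - 1L
  }
  n
}

#' Local-adaptation count for an odd probe
#'
#' `N_a` is the number of consecutive tones (of all types) immediately
#' preceding the probe whose log2-frequencies fall *outside* a frequency
#' window of full width `delta` octaves centred at the odd-probe frequency.
#' The count stops at the first in-window tone. Larger `N_a` means the probe
#' arrives after a longer period without frequency-local stimulation, hence
#' less local adaptation.
#'
#' @param sequence a `stim_sequence`.
#' @param probe_index index (row) of an odd probe in the sequence.
#' @param delta window full width, octaves (`> 0`).
#' @param centre window centre in log2-octave units; defaults to the
#'   context's odd-probe offset.
#' @return integer `N_a >= 0`.
#' @export
compute_na <- function(sequence, probe_index, delta, centre = NULL) {
  stopifnot(inherits(sequence, "stim_sequence"))
  if (delta <= 0) stop("delta must be positive")
  ev <- sequence$events
  if (probe_index < 1 || probe_index > nrow(ev) ||
      ev$kind[probe_index] != "odd_probe") {
    stop("probe_index must point at an odd probe")
  }
  if (is.null(centre)) {
    centre <- if (!is.null(sequence$context)) {
      sequence$context$odd_offset_octaves
    } else {
      ev$log2f[probe_index]
    }
  }
  na_run_length(ev$log2f, probe_index, delta, centre)
}

#' Attach adaptation labels for a grid of window widths
#'
#' Computes `N_a` for every odd-probe epoch against each window width and
#' stores the counts in the epoch labels as columns `na_<k>` (one per entry
#' of `deltas`, with the widths recorded in the `na_deltas` attribute).
#'
#' @param epochs an `epoch_set` whose labels carry `event_index` into
#'   `sequence$events`.
#' @param sequence the `stim_sequence` the epochs came from.
#' @param deltas window full widths, octaves.
#' @return the `epoch_set` with adaptation label columns added.
#' @export
label_adaptation <- function(epochs, sequence,
                             deltas = c(1, 2, 3, 4, 5) / 3) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(sequence, "stim_sequence"))
  lab <- epochs$labels
  odd <- which(lab$kind == "odd_probe")
  na_mat <- matrix(NA_real_, nrow(lab), length(deltas))
  for (k in seq_along(deltas)) {
    for (i in odd) {
      na_mat[i, k] <- compute_na(sequence, lab$event_index[i], deltas[k])
    }
  }
  colnames(na_mat) <- paste0("na_", seq_along(deltas))
  epochs$labels <- cbind(lab, as.data.frame(na_mat))
  attr(epochs$labels, "na_deltas") <- deltas
  epochs
}

#' Group odd-probe responses by adaptation state
#'
#' Threshold mode forms, for each cutpoint `g`, the group of odd probes with
#' `N_a >= g` (groups overlap and counts weakly decrease as the cutpoint
#' grows). Bin mode forms disjoint ranges `[cut_k, cut_{k+1})` (the last bin
#' is open-ended), so bin counts sum to the total number of odd probes.
#'
#' @param y samples x epochs matrix of filtered traces ([apply_filter()]).
#' @param labels epoch label data.frame with `kind`, `context`, and an `na`
#'   vector for the chosen window width.
#' @param na numeric vector of `N_a` values, one per epoch (NA for
#'   non-odd-probe epochs).
#' @param mode `"threshold"` or `"bin"`.
#' @param cutpoints strictly increasing cutpoints.
#' @return data.frame with one row per (context, group): `context`, `group`,
#'   `cutpoint`, `n`, `ok` (FALSE for empty groups), plus list columns
#'   `indices` (epoch indices) and `erf` (group-mean filtered trace).
#' @export
group_probes <- function(y, labels, na, mode = c("threshold", "bin"),
                         cutpoints = c(0, 1, 2, 4, 8, 15)) {
  mode <- match.arg(mode)
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  odd <- which(labels$kind == "odd_probe")
  rows <- list()
  for (ctx in unique(labels$context[odd])) {
    in_ctx <- odd[labels$context[odd] == ctx]
    ngrp <- if (mode == "threshold") length(cutpoints) else length(cutpoints)
    for (g in seq_len(ngrp)) {
      if (mode == "threshold") {
        idx <- in_ctx[na[in_ctx] >= cutpoints[g]]
        label <- sprintf(">=%g", cutpoints[g])
      } else {
        hi <- if (g < length(cutpoints)) cutpoints[g + 1] else Inf
        idx <- in_ctx[na[in_ctx] >= cutpoints[g] & na[in_ctx] < hi]
        label <- sprintf("[%g,%s)", cutpoints[g],
                         if (is.finite(hi)) sprintf("%g", hi) else "Inf")
      }
      erf <- if (length(idx)) rowMeans(y[, idx, drop = FALSE]) else NULL
      rows[[length(rows) + 1]] <-
        list(context = ctx, group = label, cutpoint = cutpoints[g],
             n = length(idx), ok = length(idx) > 0,
             indices = idx, erf = erf)
    }
  }
  out <- data.frame(context = vapply(rows, `[[`, "", "context"),
                    group = vapply(rows, `[[`, "", "group"),
                    cutpoint = vapply(rows, `[[`, 0, "cutpoint"),
                    n = vapply(rows, `[[`, 0, "n"),
                    ok = vapply(rows, `[[`, TRUE, "ok"),
                    stringsAsFactors = FALSE)
  out$indices <- lapply(rows, `[[`, "indices")
  out$erf <- lapply(rows, `[[`, "erf")
  out
}

#' Per-response peak values around the ERF minimum
#'
#' Finds the latency of the minimum of the group ERF within the search
#' interval, then computes, for each individual response, the mean of its
#' samples within `half_window` of that latency. Averaging a +/-30 ms
#' neighbourhood stabilizes single-response peak estimates.
#'
#' @param erf group-mean filtered trace (numeric vector).
#' @param traces samples x responses matrix of individual filtered traces.
#' @param times sample times, seconds.
#' @param half_window half-width of the averaging window, seconds.
#' @param search search interval for the ERF minimum, seconds post-onset.
#' @return list with `latency` (s) and `peaks` (one value per response).
#' @export
peak_value <- function(erf, traces, times, half_window = 0.030,
                       search = c(0.05, 0.25)) {
  if (search[1] < min(times) - 1e-9 || search[2] > max(times) + 1e-9) {
    stop("search interval extends outside the epoch window")
  }
  sel <- which(times >= search[1] - 1e-9 & times <= search[2] + 1e-9)
  lat <- times[sel[which.min(erf[sel])]]
  win <- which(abs(times - lat) <= half_window + 1e-9)
  peaks <- colMeans(traces[win, , drop = FALSE])
  list(latency = lat, peaks = peaks)
}

#' One-tailed sampled permutation test for a context difference
#'
#' Tests whether broad-context peak values exceed narrow-context peak values
#' (peaks are negative, so a deeper narrow-context MMN gives a positive
#' observed statistic `d = mean(broad) - mean(narrow)`). Context labels are
#' randomly permuted `n_perm` times; the p-value is the add-one-corrected
#' fraction of permutations whose statistic is at least the observed one:
#' `p = (1 + #[d_perm >= d_obs]) / (1 + n_perm)`. The correction keeps
#' `p > 0` and makes the test valid (if slightly conservative).
#'
#' @param peaks_narrow,peaks_broad numeric vectors of per-response peaks.
#' @param n_perm number of permutations.
#' @param seed integer seed (the test is deterministic given the seed).
#' @return object of class `perm_test`: `p`, `statistic` (`d_obs`),
#'   `n_perm`, group sizes.
#' @export
permutation_test <- function(peaks_narrow, peaks_broad, n_perm = 2500,
                             seed = 1) {
  n1 <- length(peaks_narrow)
  n2 <- length(peaks_broad)
  if (n1 == 0 || n2 == 0) stop("both context groups must be non-empty")
  d_obs <- mean(peaks_broad) - mean(peaks_narrow)
  pooled <- c(peaks_narrow, peaks_broad)
  tot <- sum(pooled)
  n <- n1 + n2
  count <- with_seed(seed, {
    cnt <- 0L
    for (j in seq_len(n_perm)) {
      s1 <- sum(pooled[sample.int(n, n1)])
      d <- (tot - s1) / n2 - s1 / n1
      if (d >= d_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(p = (1 + count) / (1 + n_perm), statistic = d_obs,
                 n_perm = n_perm, n_narrow = n1, n_broad = n2, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> d(broad - narrow) = %.4g, p = %.4g (%d permutations, n = %d/%d)\n",
    x$statistic, x$p, x$n_perm, x$n_narrow, x$n_broad))
  invisible(x)
}

#' Full local-adaptation analysis grid
#'
#' For every (window width, cutpoint) pair: groups odd probes by adaptation
#' state in each context, averages their filtered responses, extracts
#' per-response peak values around the group-ERF minimum, and compares the
#' contexts with the sampled permutation test. Each pair is tested at an
#' independent significance threshold.
#'
#' @param epochs an `epoch_set` labelled by [label_adaptation()].
#' @param filter a `spatial_filter` (or weight vector).
#' @param deltas window full widths, octaves; must match the widths used in
#'   [label_adaptation()].
#' @param cutpoints threshold (or bin) cutpoints for `N_a`.
#' @param mode `"threshold"` (default) or `"bin"`.
#' @param n_perm permutations per test.
#' @param seed master seed (a child seed is drawn per grid cell).
#' @param alpha per-test significance threshold.
#' @param half_window,search peak extraction parameters (see
#'   [peak_value()]).
#' @return object of class `adaptation_result`: a tidy data.frame with
#'   columns `delta`, `cutpoint`, `context`, `n`, `peak_mean`, `peak_se`,
#'   `latency`, `p`, `significant`.
#' @export
run_adaptation_analysis <- function(epochs, filter,
                                    deltas = attr(epochs$labels, "na_deltas"),
                                    cutpoints = c(0, 1, 2, 4, 8, 15),
                                    mode = c("threshold", "bin"),
                                    n_perm = 2500, seed = 1, alpha = 0.05,
                                    half_window = 0.030,
                                    search = c(0.05, 0.25)) {
  mode <- match.arg(mode)
  if (is.null(deltas)) stop("epochs carry no adaptation labels; run label_adaptation()")
  y <- apply_filter(epochs, filter)
  times <- epochs$times
  lab <- epochs$labels
  out <- list()
  for (k in seq_along(deltas)) {
    na <- lab[[paste0("na_", k)]]
    groups <- group_probes(y, lab, na, mode, cutpoints)
    for (cp in unique(groups$cutpoint)) {
      gn <- groups[groups$cutpoint == cp & groups$context == "narrow", ]
      gb <- groups[groups$cutpoint == cp & groups$context == "broad", ]
      res <- list(narrow = gn, broad = gb)
      pk <- list()
      for (ctx in names(res)) {
        g <- res[[ctx]]
        if (nrow(g) == 1 && g$ok) {
          pv <- peak_value(g$erf[[1]], y[, g$indices[[1]], drop = FALSE],
                           times, half_window, search)
          pk[[ctx]] <- pv
          out[[length(out) + 1]] <- data.frame(
            delta = deltas[k], cutpoint = cp, context = ctx, n = g$n,
            peak_mean = mean(pv$peaks),
            peak_se = stats::sd(pv$peaks) / sqrt(g$n),
            latency = pv$latency, p = NA_real_, significant = NA)
        } else {
          out[[length(out) + 1]] <- data.frame(
            delta = deltas[k], cutpoint = cp, context = ctx, n = 0,
            peak_mean = NA_real_, peak_se = NA_real_,
            latency = NA_real_, p = NA_real_, significant = NA)
        }
      }
      if (!is.null(pk$narrow) && !is.null(pk$broad)) {
        pt <- permutation_test(pk$narrow$peaks, pk$broad$peaks, n_perm,
                               seed = child_seed(seed, k, round(100 * cp)))
        m <- length(out)
        out[[m - 1]]$p <- out[[m]]$p <- pt$p
        out[[m - 1]]$significant <- out[[m]]$significant <- pt$p < alpha
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("adaptation_result", "data.frame")
  res
}
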