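#' Construct a recording object from a data matrix
#'
#' Thin constructor used by the simulator and by tests. Data are stored
#' samples x channels; event onsets are 0-based sample indices (sample 0 is
#' time 0).
#'
#' @param data samples x channels numeric matrix.
#' @param fs_hz sampling rate, Hz.
#' @param events optional data.frame with at least a `sample` column.
#' @param layout optional [make_layout()] result.
#' @param context optional [context_spec()].
#' @return object of class `meg_recording`.
#' @export
as_recording <- function(data, fs_hz, events = NULL, layout = NULL,
                         context = NULL) {
  stopifnot(is.matrix(data))
  if (is.null(events)) {
    events <- data.frame(sample = integer(0))
  }
  structure(list(data = data, fs_hz = fs_hz, events = events,
                 layout = layout, context = context,
                 ground_truth = NULL, passband = NULL),
            class = "meg_recording")
}

# Zero-phase Butterworth filtering of a samples x channels matrix.
# `filt` is a signal::butter() coefficient object; pad in samples.
# With in_place = TRUE the input matrix is overwritten (for multi-GB
# pipeline data); callers must own the matrix exclusively.
zerophase <- function(x, filt, pad, in_place = FALSE) {
  if (in_place) {
    .filtfilt_cols_inplace(x, as.numeric(filt$b), as.numeric(filt$a),
                           as.integer(pad))
    x
  } else {
    .filtfilt_cols(x, as.numeric(filt$b), as.numeric(filt$a),
                   as.integer(pad))
  }
}

#' Zero-phase band-pass filter a continuous recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to the
#' continuous data, realized as a cascade of a 2nd-order high-pass at `lo`
#' and a 4th-order low-pass at `hi` (each run forward and backward, so the
#' effective orders double and the phase response is zero). The cascade is
#' numerically robust at the very low normalized high-pass cutoff and removes
#' DC.
#'
#' @param recording a `meg_recording`.
#' @param lo,hi passband edges, Hz; requires `0 < lo < hi < fs/2`.
#' @param in_place overwrite the recording's data matrix instead of copying
#'   (halves peak memory; any other reference to the matrix sees the change).
#' @return the filtered recording, with its `passband` recorded.
#' @export
bandpass <- function(recording, lo = 0.5, hi = 30, in_place = FALSE) {
  stopifnot(inherits(recording, "meg_recording"))
  fs <- recording$fs_hz
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("high edge must be below the Nyquist frequency")
  hp <- signal::butter(2, lo / (fs / 2), type = "high")
  lp <- signal::butter(4, hi / (fs / 2), type = "low")
  pad <- min(nrow(recording$data) - 1, round(3 * fs / lo))
  x <- zerophase(recording$data, hp, pad, in_place)
  x <- zerophase(x, lp, min(nrow(x) - 1, round(0.5 * fs)), in_place = TRUE)
  recording$data <- x
  recording$passband <- c(lo, hi)
  recording
}

#' Downsample a recording by an integer factor
#'
#' Decimates to the target rate after anti-alias low-pass filtering. If the
#' recording has already been band-passed with an upper edge comfortably
#' below the target Nyquist frequency (`hi <= 0.4 * target`), the `"auto"`
#' mode skips the redundant anti-alias filter.
#'
#' @param recording a `meg_recording`.
#' @param target target sampling rate, Hz; `fs / target` must be an integer.
#' @param antialias `"auto"`, `"on"` or `"off"`.
#' @return the decimated recording; event sample indices are rescaled.
#' @export
downsample <- function(recording, target = 200,
                       antialias = c("auto", "on", "off")) {
  stopifnot(inherits(recording, "meg_recording"))
  antialias <- match.arg(antialias)
  fs <- recording$fs_hz
  factor <- fs / target
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("sampling rate %g is not an integer multiple of target %g",
                 fs, target))
  }
  factor <- as.integer(round(factor))
  x <- recording$data
  if (factor > 1) {
    apply_aa <- switch(antialias,
      on = TRUE, off = FALSE,
      auto = is.null(recording$passband) ||
        recording$passband[2] > 0.4 * target)
    if (apply_aa) {
      lp <- signal::butter(4, 0.8 * (target / 2) / (fs / 2), type = "low")
      x <- zerophase(x, lp, min(nrow(x) - 1, round(0.5 * fs)))
    }
    x <- x[seq(1, nrow(x), by = factor), , drop = FALSE]
  }
  recording$data <- x
  recording$fs_hz <- target
  if (nrow(recording$events)) {
    recording$events$sample <- recording$events$sample %/% factor
  }
  recording
}

#' Extract epochs around event onsets
#'
#' Cuts peristimulus windows around event onsets; both window end points are
#' included, so a (-100, 350) ms window at 200 Hz yields exactly 91 samples.
#' Events whose window would extend beyond the recording are dropped and the
#' number of dropped events reported via a message and the `n_dropped`
#' attribute.
#'
#' @param recording a `meg_recording`.
#' @param events integer indices into `recording$events` (default: all).
#' @param window peristimulus window `(start, end)` in seconds.
#' @return object of class `epoch_set`: `data` (samples x channels x epochs
#'   array), `fs_hz`, `window_s`, `times`, and `labels` (one row per kept
#'   epoch, including `event_index`). An empty event list yields an empty
#'   epoch set.
#' @export
epoch_recording <- function(recording, events = NULL,
                            window = c(-0.100, 0.350)) {
  stopifnot(inherits(recording, "meg_recording"))
  fs <- recording$fs_hz
  if (is.null(events)) events <- seq_len(nrow(recording$events))
  o0 <- round(window[1] * fs)
  o1 <- round(window[2] * fs)
  if (o1 < o0) stop("window end before window start")
  S <- o1 - o0 + 1L
  Tn <- nrow(recording$data)
  C <- ncol(recording$data)
  samp <- recording$events$sample[events]      # 0-based
  ok <- (samp + o0) >= 0 & (samp + o1) <= (Tn - 1)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message(sprintf("dropping %d event(s) too close to the record edges",
                    n_drop))
  }
  keep <- events[ok]
  arr <- array(0, dim = c(S, C, length(keep)))
  for (e in seq_along(keep)) {
    s0 <- recording$events$sample[keep[e]]
    arr[, , e] <- recording$data[(s0 + o0 + 1L):(s0 + o1 + 1L), , drop = FALSE]
  }
  labels <- recording$events[keep, , drop = FALSE]
  labels$event_index <- keep
  if (!is.null(recording$context)) {
    labels$context <- recording$context$name
    if ("kind" %in% names(labels)) {
      labels$condition <- condition_code(labels$kind, recording$context$name)
    }
  }
  rownames(labels) <- NULL
  structure(list(data = arr, fs_hz = fs, window_s = window,
                 times = (o0:o1) / fs, labels = labels,
                 n_dropped = n_drop),
            class = "epoch_set")
}

# Condition code: standard/odd probe x low (narrow) / high (broad) variance.
condition_code <- function(kind, context) {
  ifelse(kind == "contextual", NA_character_,
         paste0(ifelse(kind == "standard_probe", "s", "o"),
                ifelse(context == "narrow", "l", "h")))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples at %g Hz, window [%g, %g] s\n",
    d[3], d[2], d[1], x$fs_hz, x$window_s[1], x$window_s[2]))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus interval
#' (both end points included; the 0 ms sample belongs to the baseline).
#'
#' @param epochs an `epoch_set` whose window covers the baseline interval.
#' @param interval baseline interval in seconds, default (-0.100, 0).
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, interval = c(-0.100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  tol <- 1e-9
  bsel <- epochs$times >= interval[1] - tol & epochs$times <= interval[2] + tol
  if (!any(bsel)) stop("epoch window contains no pre-stimulus baseline samples")
  arr <- epochs$data
  d <- dim(arr)
  bl <- colMeans(arr[bsel, , , drop = FALSE])           # channels x epochs
  epochs$data <- arr - aperm(array(bl, c(d[2], d[3], d[1])), c(3, 1, 2))
  epochs
}

#' Preprocess a continuous recording into baseline-corrected epochs
#'
#' The full chain in fixed order: zero-phase band-pass on the continuous
#' record, downsampling, epoching, baseline correction. Filtering before
#' epoching avoids per-epoch filter transients.
#'
#' @param recording a `meg_recording`.
#' @param lo,hi band-pass edges, Hz.
#' @param fs_out target sampling rate, Hz.
#' @param window peristimulus window, seconds.
#' @param events `"probes"` (default) to epoch only probe tones, `"all"` for
#'   every event, or an integer index vector into `recording$events`.
#' @param in_place overwrite the recording's data during filtering (see
#'   [bandpass()]).
#' @return a baseline-corrected `epoch_set`.
#' @export
preprocess_recording <- function(recording, lo = 0.5, hi = 30, fs_out = 200,
                                 window = c(-0.100, 0.350),
                                 events = "probes", in_place = FALSE) {
  rec <- bandpass(recording, lo, hi, in_place = in_place)
  rec <- downsample(rec, fs_out)
  idx <- if (identical(events, "probes")) {
    which(rec$events$kind != "contextual")
  } else if (identical(events, "all")) {
    seq_len(nrow(rec$events))
  } else {
    events
  }
  ep <- epoch_recording(rec, idx, window)
  baseline_correct(ep)
}
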