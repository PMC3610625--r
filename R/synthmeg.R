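#' Synthetic sensor layout
#'
#' Places `n_channels` sensors quasi-uniformly on the unit disk using a
#' sunflower (Fermat spiral) arrangement with a small seeded jitter. This is a
#' stand-in geometry for a whole-head axial gradiometer array (default 274
#' channels); only the 2-D coordinates are used downstream (interpolated scalp
#' maps and their convex-hull mask).
#'
#' @param n_channels number of sensors (`>= 4`).
#' @param seed integer seed for the jitter; the layout is deterministic given
#'   `(n_channels, seed)`.
#' @return object of class `sensor_layout` with `n_channels` and `pos2d`
#'   (`n_channels x 2` matrix, coordinates within the unit disk).
#' @export
make_layout <- function(n_channels = 274, seed = 1) {
  if (n_channels < 4) stop("need at least 4 channels (hull interpolation)")
  golden <- pi * (3 - sqrt(5))
  pos <- with_seed(seed, {
    i <- seq_len(n_channels)
    r <- sqrt((i - 0.5) / n_channels) * 0.92
    th <- i * golden + rnorm(n_channels, 0, 0.02)
    r <- pmin(r + rnorm(n_channels, 0, 0.005), 0.98)
    cbind(x = r * cos(th), y = r * sin(th))
  })
  structure(list(n_channels = n_channels, pos2d = pos, seed = seed),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d channels on the unit disk (seed %d)\n",
              x$n_channels, x$seed))
  invisible(x)
}

#' Generator parameters for synthetic MEG recordings
#'
#' Defines the planted evoked components and the noise model. Each tone evokes
#' an auditory component (a Gabor kernel at `aud_latency_s`, positive) with a
#' fixed spatial pattern; probe tones additionally evoke an MMN-like component
#' (a negative Gaussian bump at `mmn_latency_s`) whose amplitude depends on
#' probe type, context, and local-adaptation state:
#' `A[kind, context] * (1 - adapt_rho[context] * exp(-N_a / adapt_tau))`.
#'
#' The default amplitude table is chosen to reproduce the qualitative effect
#' directions of the study design: odd probes evoke deeper (more negative)
#' MMN than standards in both contexts; the odd-probe MMN is deeper in the
#' narrow context than in the broad one; the standard-probe response is
#' smaller in the narrow context; and adaptation (response reduction after
#' recent frequency-local stimulation) is substantial in the broad context
#' and near absent in the narrow one.
#'
#' @param fs_hz sampling rate, Hz.
#' @param aud_latency_s,aud_width_s,aud_freq_hz,aud_amp auditory Gabor kernel:
#'   latency (s), Gaussian envelope SD (s), carrier frequency (Hz), amplitude.
#' @param mmn_latency_s,mmn_width_s MMN kernel latency and envelope SD (s).
#' @param mmn_amp 2x2 amplitude table (rows `standard_probe`, `odd_probe`;
#'   columns `narrow`, `broad`), in sensor units; negative.
#' @param adapt_rho named vector, adaptation depth in `[0, 1]` per context.
#' @param adapt_tau adaptation time constant, in tones.
#' @param na_delta full width (octaves) of the frequency window used for the
#'   generator's ground-truth adaptation state.
#' @param noise_sd marginal SD of the spatially mixed AR(1) noise per channel.
#' @param noise_ar1 AR(1) coefficient of the noise (at `fs_hz`).
#' @param spatial_mix_rank rank of the spatial noise mixing.
#' @param white_sd SD of additional independent white sensor noise.
#' @param pattern_overlap cosine between the MMN and auditory spatial
#'   patterns (the MMN generators partially overlap the auditory ones).
#' @param pattern_seed seed for the fixed spatial patterns and noise mixing
#'   matrix (shared across simulated subjects).
#' @param seed default seed for noise realizations.
#' @return object of class `gen_params`.
#' @export
gen_params <- function(fs_hz = 600,
                       aud_latency_s = 0.10, aud_width_s = 0.02,
                       aud_freq_hz = 10, aud_amp = 1.5,
                       mmn_latency_s = 0.15, mmn_width_s = 0.035,
                       mmn_amp = matrix(c(-0.10, -1.30, -0.55, -0.60), 2, 2,
                                        dimnames = list(
                                          c("standard_probe", "odd_probe"),
                                          c("narrow", "broad"))),
                       adapt_rho = c(narrow = 0.05, broad = 0.55),
                       adapt_tau = 4,
                       na_delta = 1 / 3,
                       noise_sd = 0.8, noise_ar1 = 0.95,
                       spatial_mix_rank = 40, white_sd = 0.25,
                       pattern_overlap = 0.6,
                       pattern_seed = 42, seed = 1) {
  stopifnot(all(mmn_amp["odd_probe", ] <= mmn_amp["standard_probe", ]),
            all(adapt_rho >= 0), all(adapt_rho <= 1), adapt_tau > 0,
            noise_ar1 >= 0, noise_ar1 < 1, spatial_mix_rank >= 1)
  structure(
    list(fs_hz = fs_hz, aud_latency_s = aud_latency_s,
         aud_width_s = aud_width_s, aud_freq_hz = aud_freq_hz,
         aud_amp = aud_amp, mmn_latency_s = mmn_latency_s,
         mmn_width_s = mmn_width_s, mmn_amp = mmn_amp,
         adapt_rho = adapt_rho, adapt_tau = adapt_tau, na_delta = na_delta,
         noise_sd = noise_sd, noise_ar1 = noise_ar1,
         spatial_mix_rank = spatial_mix_rank, white_sd = white_sd,
         pattern_overlap = pattern_overlap,
         pattern_seed = pattern_seed, seed = seed),
    class = "gen_params")
}

#' Planted MMN amplitude for a tone
#'
#' Phenomenological amplitude model: probes evoke
#' `A[kind, context] * (1 - adapt_rho[context] * exp(-N_a / adapt_tau))`;
#' contextual tones evoke no MMN (amplitude 0). Larger `N_a` (more preceding
#' tones outside the frequency window, i.e. less recent frequency-local
#' stimulation) means less adaptation and a deeper response.
#'
#' @param kind `"contextual"`, `"standard_probe"` or `"odd_probe"`.
#' @param context `"narrow"` or `"broad"`.
#' @param n_a adaptation state (count of consecutive preceding tones outside
#'   the frequency window), `>= 0`; may be a vector.
#' @param params a [gen_params()].
#' @return MMN amplitude(s), sensor units (negative for probes).
#' @export
mmn_amplitude <- function(kind, context, n_a, params) {
  if (!kind %in% c("contextual", "standard_probe", "odd_probe")) {
    stop("unknown tone kind: ", kind)
  }
  if (!context %in% colnames(params$mmn_amp)) {
    stop("unknown context: ", context)
  }
  if (any(n_a < 0)) stop("n_a must be >= 0")
  if (kind == "contextual") return(rep(0, length(n_a)))
  base <- params$mmn_amp[kind, context]
  base * (1 - params$adapt_rho[[context]] * exp(-n_a / params$adapt_tau))
}

# Evoked kernels (unit peak amplitude), evaluated at times t (s) from onset.
gabor_kernel <- function(t, latency, width, freq) {
  exp(-(t - latency)^2 / (2 * width^2)) * cos(2 * pi * freq * (t - latency))
}
bump_kernel <- function(t, latency, width) {
  exp(-(t - latency)^2 / (2 * width^2))
}

# Unit-norm spatial patterns and noise mixing, fixed by params$pattern_seed.
spatial_patterns <- function(layout, params) {
  with_seed(params$pattern_seed, {
    C <- layout$n_channels
    p_aud <- rnorm(C)
    p_aud <- p_aud / sqrt(sum(p_aud^2))
    q <- rnorm(C)
    q <- q - sum(q * p_aud) * p_aud
    q <- q / sqrt(sum(q^2))
    rho <- params$pattern_overlap
    p_mmn <- rho * p_aud + sqrt(1 - rho^2) * q
    mix <- matrix(rnorm(C * params$spatial_mix_rank), C) /
      sqrt(params$spatial_mix_rank)
    list(p_aud = p_aud, p_mmn = p_mmn, mix = mix)
  })
}

#' Simulate a continuous multichannel recording for a tone sequence
#'
#' Builds `data = sum_events [aud + mmn kernels x spatial patterns] + noise`,
#' where the noise is a rank-limited spatial mixture of AR(1) processes plus
#' independent white sensor noise. The adaptation state `N_a` entering the
#' planted MMN amplitude is computed on the true sequence against a window of
#' full width `params$na_delta` centred at each probe's own log2-frequency.
#' The planted patterns and per-event amplitudes are stored as ground truth
#' for testing.
#'
#' @param sequence a [generate_sequence()] result (non-empty).
#' @param layout a [make_layout()] result.
#' @param params a [gen_params()].
#' @param seed seed for the noise realization (defaults to `params$seed`).
#' @return object of class `meg_recording`: `data` (samples x channels
#'   matrix), `fs_hz`, `events` (with 0-based `sample` indices, kind, planted
#'   amplitudes and `na`), `layout`, `context`, `ground_truth`.
#' @export
simulate_recording <- function(sequence, layout, params, seed = params$seed) {
  stopifnot(inherits(sequence, "stim_sequence"),
            inherits(layout, "sensor_layout"))
  ev <- sequence$events
  if (nrow(ev) == 0) stop("sequence must be non-empty")
  ctx <- sequence$context
  fs <- params$fs_hz
  soa <- ctx$soa_s
  if (params$mmn_latency_s + 4 * params$mmn_width_s > soa ||
      params$aud_latency_s + 4 * params$aud_width_s > soa) {
    warning("evoked kernel support exceeds the onset asynchrony; ",
            "responses to successive tones will overlap")
  }
  C <- layout$n_channels
  Tn <- round((max(ev$onset_s) + soa) * fs)
  pat <- spatial_patterns(layout, params)

  # adaptation state per probe (window centred at the probe's own frequency)
  n_a <- rep(NA_real_, nrow(ev))
  probe_idx <- which(ev$kind != "contextual")
  for (i in probe_idx) {
    n_a[i] <- na_run_length(ev$log2f, i, params$na_delta, centre = ev$log2f[i])
  }
  mmn_a <- numeric(nrow(ev))
  for (i in probe_idx) {
    mmn_a[i] <- mmn_amplitude(ev$kind[i], ctx$name, n_a[i], params)
  }

  samp0 <- round(ev$onset_s * fs)  # 0-based onset sample
  # accumulate per-component source time courses, then mix once spatially
  aud_off <- seq(round((params$aud_latency_s - 4 * params$aud_width_s) * fs),
                 round((params$aud_latency_s + 4 * params$aud_width_s) * fs))
  aud_k <- gabor_kernel(aud_off / fs, params$aud_latency_s,
                        params$aud_width_s, params$aud_freq_hz)
  mmn_off <- seq(round((params$mmn_latency_s - 4 * params$mmn_width_s) * fs),
                 round((params$mmn_latency_s + 4 * params$mmn_width_s) * fs))
  mmn_k <- bump_kernel(mmn_off / fs, params$mmn_latency_s, params$mmn_width_s)
  src_aud <- numeric(Tn)
  src_mmn <- numeric(Tn)
  for (i in seq_len(nrow(ev))) {
    if (params$aud_amp != 0) {
      idx <- samp0[i] + aud_off + 1L
      keep <- idx >= 1L & idx <= Tn
      src_aud[idx[keep]] <- src_aud[idx[keep]] + params$aud_amp * aud_k[keep]
    }
    if (mmn_a[i] != 0) {
      idx <- samp0[i] + mmn_off + 1L
      keep <- idx >= 1L & idx <= Tn
      src_mmn[idx[keep]] <- src_mmn[idx[keep]] + mmn_a[i] * mmn_k[keep]
    }
  }
  data <- cbind(src_aud, src_mmn) %*% rbind(pat$p_aud, pat$p_mmn)

  if (params$noise_sd > 0 || params$white_sd > 0) {
    # noise is added in place to keep peak memory near one data-sized buffer
    with_seed(seed, {
      if (params$noise_sd > 0) {
        r <- min(params$spatial_mix_rank, C)
        innov_sd <- params$noise_sd * sqrt(1 - params$noise_ar1^2)
        z <- matrix(rnorm(Tn * r, 0, innov_sd), Tn, r)
        z <- .ar1_cols(z, params$noise_ar1)
        mixed <- z %*% t(pat$mix[, seq_len(r), drop = FALSE])
        rm(z)
        .add_inplace(data, mixed)
        rm(mixed)
      }
      if (params$white_sd > 0) {
        .add_white_inplace(data, params$white_sd)
      }
    })
  }

  events <- data.frame(onset_s = ev$onset_s, sample = samp0,
                       kind = ev$kind, log2f = ev$log2f,
                       na = n_a, mmn_amp = mmn_a,
                       aud_amp = params$aud_amp,
                       stringsAsFactors = FALSE)
  structure(
    list(data = data, fs_hz = fs, events = events, layout = layout,
         context = ctx,
         ground_truth = list(p_aud = pat$p_aud, p_mmn = pat$p_mmn,
                             mix = pat$mix, params = params),
         passband = NULL),
    class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf(
    "<meg_recording> %d samples x %d channels at %g Hz, %d events (%s context)\n",
    nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$events), x$context$name))
  invisible(x)
}
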