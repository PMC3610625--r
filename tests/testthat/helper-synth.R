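# Small synthetic objects shared across tests.

tiny_layout <- function(n = 16, seed = 3) make_layout(n, seed = seed)

# Generator scaled down for unit tests: few channels, low-rank noise.
tiny_params <- function(...) {
  gen_params(spatial_mix_rank = 6, ...)
}

# A noiseless recording for a short sequence.
noiseless_recording <- function(n_tones = 40, context = "narrow",
                                n_channels = 16, seed = 11) {
  ctx <- context_spec(context)
  seqc <- generate_sequence(ctx, n_tones, seed = seed)
  simulate_recording(seqc, tiny_layout(n_channels),
                     tiny_params(noise_sd = 0, white_sd = 0))
}

# Build an epoch_set directly from an array (samples x channels x epochs).
manual_epochs <- function(arr, fs = 200, window = c(-0.1, 0.35),
                          labels = NULL) {
  S <- dim(arr)[1]
  times <- seq(window[1], window[2], length.out = S)
  if (is.null(labels)) {
    labels <- data.frame(event_index = seq_len(dim(arr)[3]))
  }
  structure(list(data = arr, fs_hz = fs, window_s = window, times = times,
                 labels = labels, n_dropped = 0L),
            class = "epoch_set")
}

# Epochs with planted condition structure: per condition, mean pattern x
# kernel plus white noise.
condition_epochs <- function(n_per = 12, n_ch = 8, n_s = 46, noise = 0.1,
                             amps = c(sl = -0.2, sh = -0.5, ol = -1.2,
                                      oh = -0.7),
                             seed = 5) {
  withr::with_seed(seed, {
    conds <- rep(names(amps), each = n_per)
    pat <- rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
    times <- seq(-0.1, 0.35, length.out = n_s)
    kern <- exp(-(times - 0.15)^2 / (2 * 0.035^2))
    arr <- array(rnorm(n_s * n_ch * length(conds), 0, noise),
                 c(n_s, n_ch, length(conds)))
    for (e in seq_along(conds)) {
      arr[, , e] <- arr[, , e] + amps[[conds[e]]] * kern %o% pat
    }
    labels <- data.frame(event_index = seq_along(conds), condition = conds,
                         kind = ifelse(substr(conds, 1, 1) == "s",
                                       "standard_probe", "odd_probe"),
                         context = ifelse(substr(conds, 2, 2) == "l",
                                          "narrow", "broad"),
                         stringsAsFactors = FALSE)
    ep <- manual_epochs(arr, labels = labels)
    attr(ep, "pattern") <- pat
    attr(ep, "kernel") <- kern
    ep
  })
}
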