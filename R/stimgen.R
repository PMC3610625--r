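#' Contextual distribution specification
#'
#' Describes one statistical context of the tone stream: a Gaussian
#' distribution of log2-frequency (octaves relative to the centre frequency)
#' from which contextual tones are drawn, plus the two embedded probe types.
#' The "narrow" context has standard deviation 0.5 octaves and the "broad"
#' context 1.5 octaves; both are centred at 500 Hz. Standard probes sit at the
#' centre (offset 0), odd probes two octaves above it (2000 Hz), and each
#' probe type occupies 10% of the stream.
#'
#' @param name `"narrow"` or `"broad"` (sets the default `sigma_octaves`).
#' @param centre_hz centre frequency of the context, Hz.
#' @param sigma_octaves standard deviation of contextual log2-frequency,
#'   octaves. Defaults to 0.5 for `"narrow"`, 1.5 for `"broad"`.
#' @param soa_s onset asynchrony between successive tones, seconds.
#' @param tone_dur_s tone-pulse duration, seconds (metadata only; no audio is
#'   synthesized).
#' @param p_standard,p_odd probabilities of standard and odd probes.
#' @param odd_offset_octaves offset of the odd probe above the centre, octaves.
#' @return an object of class `context_spec`.
#' @examples
#' context_spec("broad")$sigma_octaves
#' @export
context_spec <- function(name = c("narrow", "broad"),
                         centre_hz = 500,
                         sigma_octaves = NULL,
                         soa_s = 0.5,
                         tone_dur_s = 0.05,
                         p_standard = 0.10,
                         p_odd = 0.10,
                         odd_offset_octaves = 2) {
  name <- match.arg(name)
  if (is.null(sigma_octaves)) {
    sigma_octaves <- if (name == "narrow") 0.5 else 1.5
  }
  if (centre_hz <= 0) stop("centre_hz must be positive")
  if (sigma_octaves <= 0) stop("sigma_octaves must be positive")
  if (p_standard < 0 || p_odd < 0 || p_standard + p_odd >= 1) {
    stop("need 0 <= p_standard + p_odd < 1")
  }
  structure(
    list(name = name, centre_hz = centre_hz, sigma_octaves = sigma_octaves,
         soa_s = soa_s, tone_dur_s = tone_dur_s,
         p_standard = p_standard, p_odd = p_odd,
         odd_offset_octaves = odd_offset_octaves),
    class = "context_spec")
}

#' @export
print.context_spec <- function(x, ...) {
  cat(sprintf(
    "<context_spec> %s: centre %g Hz, sigma %g octaves, SOA %g s, probes %g%%/%g%% (odd at +%g oct)\n",
    x$name, x$centre_hz, x$sigma_octaves, x$soa_s,
    100 * x$p_standard, 100 * x$p_odd, x$odd_offset_octaves))
  invisible(x)
}

#' Convert an octave offset to a frequency in Hz
#'
#' @param offset offset in octaves relative to `centre`.
#' @param centre centre frequency, Hz (must be positive).
#' @return `centre * 2^offset`, Hz.
#' @examples
#' octaves_to_hz(2, 500)   # 2000
#' octaves_to_hz(-1, 500)  # 250
#' @export
octaves_to_hz <- function(offset, centre) {
  if (any(centre <= 0)) stop("centre frequency must be positive")
  centre * 2^offset
}

#' Draw contextual log2-frequencies
#'
#' I.i.d. Gaussian draws with mean 0 and standard deviation
#' `context$sigma_octaves`, in octave units relative to the context centre.
#'
#' @param context a [context_spec()].
#' @param n number of draws (`n >= 0`).
#' @param seed integer seed; the draw is deterministic given the seed and does
#'   not disturb the caller's RNG state.
#' @return numeric vector of length `n`.
#' @export
sample_contextual <- function(context, n, seed) {
  stopifnot(inherits(context, "context_spec"))
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(numeric(0))
  with_seed(seed, rnorm(n, mean = 0, sd = context$sigma_octaves))
}

#' Generate a stochastic tone sequence
#'
#' Each tone is independently assigned a kind with probabilities
#' (`p_standard`, `p_odd`, remainder contextual). Contextual tones draw their
#' log2-frequency from the context Gaussian; standard probes sit exactly at
#' offset 0 and odd probes exactly at `odd_offset_octaves`. Onsets are spaced
#' by the onset asynchrony (`k * soa_s` for the k-th tone, starting at 0).
#'
#' @param context a [context_spec()].
#' @param n_tones number of tones (`>= 1`).
#' @param seed integer seed; sequences are reproducible from
#'   `(context, n_tones, seed)`.
#' @param spaced_probes if `TRUE`, enforce at least one contextual tone
#'   between successive probes (re-drawing probe positions); the default
#'   `FALSE` places probes i.i.d. per tone.
#' @return an object of class `stim_sequence` with elements `context`,
#'   `events` (data.frame: `onset_s`, `log2f`, `kind`) and `seed`.
#' @export
generate_sequence <- function(context, n_tones, seed, spaced_probes = FALSE) {
  stopifnot(inherits(context, "context_spec"))
  if (n_tones < 1) stop("n_tones must be >= 1")
  events <- with_seed(seed, {
    u <- runif(n_tones)
    kind <- ifelse(u < context$p_standard, "standard_probe",
                   ifelse(u < context$p_standard + context$p_odd,
                          "odd_probe", "contextual"))
    if (spaced_probes && n_tones > 1) {
      # re-draw any probe directly following another probe until separated
      for (i in 2:n_tones) {
        while (kind[i] != "contextual" && kind[i - 1] != "contextual") {
          ui <- runif(1)
          kind[i] <- ifelse(ui < context$p_standard, "standard_probe",
                            ifelse(ui < context$p_standard + context$p_odd,
                                   "odd_probe", "contextual"))
        }
      }
    }
    log2f <- numeric(n_tones)
    is_ctx <- kind == "contextual"
    log2f[is_ctx] <- rnorm(sum(is_ctx), 0, context$sigma_octaves)
    log2f[kind == "odd_probe"] <- context$odd_offset_octaves
    data.frame(onset_s = (seq_len(n_tones) - 1) * context$soa_s,
               log2f = log2f, kind = kind, stringsAsFactors = FALSE)
  })
  structure(list(context = context, events = events, seed = seed),
            class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  tab <- table(x$events$kind)
  cat(sprintf("<stim_sequence> %d tones (%s context, seed %d): %s\n",
              nrow(x$events), x$context$name, x$seed,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Probability that a contextual tone falls within a frequency band
#'
#' For a Gaussian context with standard deviation `sigma` (octaves), returns
#' the probability that a contextual tone's log2-frequency falls within a band
#' of full width `band_width` centred `band_centre` octaves from the context
#' centre: `Phi((c + w/2)/sigma) - Phi((c - w/2)/sigma)`. With the broad
#' context (`sigma = 1.5`) and a semitone-wide band (`1/12` octave) around the
#' odd-probe frequency (`c = 2`), this is about 0.9%, i.e. roughly 1% of
#' contextual tones fall near the odd probe even in the broad context.
#'
#' @param sigma context standard deviation, octaves (`> 0`).
#' @param band_centre band centre offset from the context centre, octaves.
#' @param band_width full band width, octaves (`> 0`).
#' @return probability in `[0, 1]`.
#' @examples
#' band_probability(1.5, 2, 1/12)  # ~0.0091
#' @export
band_probability <- function(sigma, band_centre, band_width) {
  if (sigma <= 0) stop("sigma must be positive")
  if (band_width <= 0) stop("band_width must be positive")
  pnorm((band_centre + band_width / 2) / sigma) -
    pnorm((band_centre - band_width / 2) / sigma)
}

#' Write a stimulus sequence to CSV
#'
#' Events are written with columns `onset_s`, `log2f`, `kind` at full float
#' precision so that [read_sequence()] round-trips exactly. The context
#' specification can optionally be written to a JSON sidecar.
#'
#' @param x a `stim_sequence`.
#' @param path output CSV path.
#' @param context_path optional path for a JSON dump of the context spec and
#'   seed.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(x, path, context_path = NULL) {
  stopifnot(inherits(x, "stim_sequence"))
  ev <- x$events
  df <- data.frame(onset_s = sprintf("%.17g", ev$onset_s),
                   log2f = sprintf("%.17g", ev$log2f),
                   kind = ev$kind, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(context_path)) {
    meta <- c(unclass(x$context), list(seed = x$seed))
    jsonlite::write_json(meta, context_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a stimulus sequence from CSV
#'
#' @param path CSV path with columns `onset_s`, `log2f`, `kind`.
#' @param context optional [context_spec()] to attach; a JSON sidecar written
#'   by [write_sequence()] can be supplied via `context_path`.
#' @param context_path optional JSON sidecar path.
#' @return a `stim_sequence`.
#' @export
read_sequence <- function(path, context = NULL, context_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "numeric", "character"))
  if (!identical(names(df), c("onset_s", "log2f", "kind"))) {
    stop("malformed sequence CSV: expected columns onset_s, log2f, kind")
  }
  valid <- c("contextual", "standard_probe", "odd_probe")
  bad <- which(!(df$kind %in% valid))
  if (length(bad)) {
    stop(sprintf("malformed sequence CSV: unknown kind '%s' at data line %d",
                 df$kind[bad[1]], bad[1]))
  }
  seed <- NA_integer_
  if (!is.null(context_path)) {
    meta <- jsonlite::read_json(context_path, simplifyVector = TRUE)
    seed <- meta$seed
    context <- context_spec(meta$name, centre_hz = meta$centre_hz,
                            sigma_octaves = meta$sigma_octaves,
                            soa_s = meta$soa_s, tone_dur_s = meta$tone_dur_s,
                            p_standard = meta$p_standard, p_odd = meta$p_odd,
                            odd_offset_octaves = meta$odd_offset_octaves)
  }
  structure(list(context = context, events = df, seed = seed),
            class = "stim_sequence")
}
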