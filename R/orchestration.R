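#' Experiment run configuration
#'
#' Bundles every setting of the synthetic study: the two contextual
#' distributions, the recording generator, preprocessing, and the analysis
#' grids. Defaults reproduce the reference design: 18 subjects, two
#' 13-minute blocks (1560 tones at 500 ms onset asynchrony) per subject with
#' counter-balanced context order, 2500-permutation adaptation tests.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_tones_per_block tones per block (1560 = 13 min at 500 ms SOA).
#' @param n_channels sensors in the synthetic layout.
#' @param gen a [gen_params()] object.
#' @param lo,hi,fs_out,window preprocessing settings (band-pass edges, Hz;
#'   target rate, Hz; epoch window, s).
#' @param deltas adaptation window widths, octaves.
#' @param thresholds `N_a` threshold cutpoints.
#' @param n_perm_adapt permutations per adaptation test.
#' @param n_perm_group sign-flip permutations for group scalp inference.
#' @param alpha significance level (used for both analyses).
#' @param grid scalp-image size per side.
#' @param master_seed master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 18, n_tones_per_block = 1560,
                       n_channels = 274, gen = gen_params(),
                       lo = 0.5, hi = 30, fs_out = 200,
                       window = c(-0.100, 0.350),
                       deltas = c(1, 2, 3, 4, 5) / 3,
                       thresholds = c(0, 1, 2, 4, 8, 15),
                       n_perm_adapt = 2500, n_perm_group = 1000,
                       alpha = 0.05, grid = 64, master_seed = 1) {
  structure(list(n_subjects = n_subjects,
                 n_tones_per_block = n_tones_per_block,
                 n_channels = n_channels, gen = gen,
                 lo = lo, hi = hi, fs_out = fs_out, window = window,
                 deltas = deltas, thresholds = thresholds,
                 n_perm_adapt = n_perm_adapt, n_perm_group = n_perm_group,
                 alpha = alpha, grid = grid, master_seed = master_seed),
            class = "run_config")
}

#' Combine epoch sets with identical geometry into one
#'
#' @param sets list of `epoch_set`s with equal sample/channel dimensions.
#' @return a single `epoch_set` with concatenated epochs and labels.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  d1 <- dim(sets[[1]]$data)
  n_tot <- sum(vapply(sets, function(s) dim(s$data)[3], 0))
  arr <- array(0, c(d1[1], d1[2], n_tot))
  labs <- vector("list", length(sets))
  at <- 0L
  for (i in seq_along(sets)) {
    ne <- dim(sets[[i]]$data)[3]
    if (ne > 0) arr[, , at + seq_len(ne)] <- sets[[i]]$data
    labs[[i]] <- sets[[i]]$labels
    at <- at + ne
  }
  out <- sets[[1]]
  out$data <- arr
  out$labels <- do.call(rbind, labs)
  rownames(out$labels) <- NULL
  attr(out$labels, "na_deltas") <- attr(sets[[1]]$labels, "na_deltas")
  out
}

#' Subset an epoch set by epoch index
#'
#' @param epochs an `epoch_set`.
#' @param idx integer or logical epoch index.
#' @return the reduced `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  na_deltas <- attr(epochs$labels, "na_deltas")
  epochs$labels <- epochs$labels[idx, , drop = FALSE]
  rownames(epochs$labels) <- NULL
  attr(epochs$labels, "na_deltas") <- na_deltas
  epochs
}

#' Run the full synthetic experiment
#'
#' Per subject: two blocks (narrow and broad context, order counter-balanced
#' across subjects), each simulated as a continuous multichannel recording,
#' band-passed, downsampled, epoched around probe tones, baseline-corrected,
#' and labelled with adaptation counts. Then: (1) per-subject mass-univariate
#' GLMs with surprise and interaction contrasts carried to group sign-flip
#' max-statistic inference; (2) a pooled max-SNR spatial filter; (3) the
#' local-adaptation grid with sampled permutation tests.
#'
#' Fully deterministic given `config$master_seed`; every stage draws a child
#' seed from it.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress.
#' @return a report list: `scalp` (surprise and interaction
#'   `contrast_result`s), `dss` (`filter`, condition ERFs of the filtered
#'   signal), `adaptation` (`adaptation_result`), `summary` (named list of
#'   headline numbers), `config`.
#' @export
run_experiment <- function(config = run_config(), verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(config, "run_config"))
  ms <- config$master_seed
  layout <- make_layout(config$n_channels, seed = child_seed(ms, 0, 1))
  contexts <- list(narrow = context_spec("narrow"),
                   broad = context_spec("broad"))

  # One pass over subjects; only what later stages need is retained:
  # per-subject GLM contrast volumes, covariance pairs, condition ERFs,
  # and the odd-probe epochs (for the spatially filtered adaptation
  # analysis). The full-channel probe epochs of a subject are dropped as
  # soon as the subject is processed, keeping peak memory modest.
  interp <- scalp_interpolator(layout, config$grid)
  conds <- c("sl", "sh", "ol", "oh")
  vols_sur <- vector("list", config$n_subjects)
  vols_int <- vector("list", config$n_subjects)
  pairs <- vector("list", config$n_subjects)
  odd_sets <- vector("list", config$n_subjects)
  erf_sums <- stats::setNames(vector("list", 4), conds)
  erf_ns <- stats::setNames(numeric(4), conds)
  n_epochs_total <- 0L
  for (s in seq_len(config$n_subjects)) {
    order_names <- if (s %% 2 == 1) c("narrow", "broad") else
      c("broad", "narrow")
    blocks <- vector("list", 2)
    for (b in 1:2) {
      ctx <- contexts[[order_names[b]]]
      seqc <- generate_sequence(ctx, config$n_tones_per_block,
                                seed = child_seed(ms, s, b, 1))
      rec <- simulate_recording(seqc, layout, config$gen,
                                seed = child_seed(ms, s, b, 2))
      ep <- suppressMessages(
        preprocess_recording(rec, config$lo, config$hi, config$fs_out,
                             config$window, events = "probes",
                             in_place = TRUE))
      rm(rec)
      ep <- label_adaptation(ep, seqc, config$deltas)
      ep$labels$subject <- s
      ep$labels$block <- b
      blocks[[b]] <- ep
    }
    ep_s <- bind_epoch_sets(blocks)
    rm(blocks)
    n_epochs_total <- n_epochs_total + dim(ep_s$data)[3]
    fit <- fit_glm(ep_s)
    vols_sur[[s]] <- build_volume(contrast_surprise(fit)$field, interp,
                                  times = fit$times)
    vols_int[[s]] <- build_volume(contrast_interaction(fit)$field, interp,
                                  times = fit$times)
    pairs[[s]] <- cov_pair(ep_s)
    for (cc in conds) {
      e <- average_erf(ep_s, cc)
      erf_sums[[cc]] <- if (is.null(erf_sums[[cc]])) {
        e$mean * e$n_epochs
      } else {
        erf_sums[[cc]] + e$mean * e$n_epochs
      }
      erf_ns[cc] <- erf_ns[cc] + e$n_epochs
    }
    odd_sets[[s]] <- subset_epochs(ep_s,
                                   which(ep_s$labels$kind == "odd_probe"))
    rm(ep_s, fit)
    gc(verbose = FALSE)
    say("subject %d/%d simulated and fitted", s, config$n_subjects)
  }
  times <- odd_sets[[1]]$times

  say("group permutation inference on contrast volumes")
  inf_sur <- group_inference(vols_sur, config$n_perm_group, config$alpha,
                             seed = child_seed(ms, 0, 2))
  inf_int <- group_inference(vols_int, config$n_perm_group, config$alpha,
                             seed = child_seed(ms, 0, 3))
  rm(vols_sur, vols_int)

  # ---- max-SNR spatial filter (common to all subjects) ------------------
  say("solving pooled max-SNR spatial filter")
  pooled <- pool_cov_pairs(pairs)
  grand_erf <- lapply(conds, function(cc) erf_sums[[cc]] / erf_ns[cc])
  names(grand_erf) <- conds
  odd_mean <- (grand_erf$ol + grand_erf$oh) / 2
  std_mean <- (grand_erf$sl + grand_erf$sh) / 2
  filt <- solve_filter(pooled$S, pooled$V,
                       orient_erf = odd_mean - std_mean, times = times)

  # ---- local adaptation -------------------------------------------------
  say("running local-adaptation permutation grid")
  odd_epochs <- bind_epoch_sets(odd_sets)
  rm(odd_sets)
  gc(verbose = FALSE)
  adapt <- run_adaptation_analysis(
    odd_epochs, filt, deltas = config$deltas, cutpoints = config$thresholds,
    n_perm = config$n_perm_adapt, seed = child_seed(ms, 0, 4),
    alpha = config$alpha)

  cond_erfs <- sapply(conds, function(cc) drop(grand_erf[[cc]] %*% filt$w))

  summary <- list(
    n_subjects = config$n_subjects,
    n_epochs = n_epochs_total,
    surprise_min_p = min(inf_sur$p$values, na.rm = TRUE),
    surprise_n_sig = sum(inf_sur$mask$values > 0, na.rm = TRUE),
    interaction_min_p = min(inf_int$p$values, na.rm = TRUE),
    interaction_n_sig = sum(inf_int$mask$values > 0, na.rm = TRUE),
    filter_lambda = filt$lambda,
    adapt_all_sig_erb = isTRUE(with(
      subset(adapt, abs(delta - 1 / 3) < 1e-9 & context == "narrow"),
      all(p < config$alpha))))
  structure(list(scalp = list(surprise = inf_sur, interaction = inf_int),
                 dss = list(filter = filt, cond_erfs = cond_erfs,
                            times = times),
                 adaptation = adapt,
                 odd_labels = odd_epochs$labels,
                 layout = layout, summary = summary, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  s <- x$summary
  cat("<experiment_report>\n")
  cat(sprintf("  subjects: %d, probe epochs: %d\n", s$n_subjects, s$n_epochs))
  cat(sprintf("  surprise contrast: %d significant voxels (min corrected p = %.4g)\n",
              s$surprise_n_sig, s$surprise_min_p))
  cat(sprintf("  interaction contrast: %d significant voxels (min corrected p = %.4g)\n",
              s$interaction_n_sig, s$interaction_min_p))
  cat(sprintf("  spatial filter SNR lambda = %.3f\n", s$filter_lambda))
  cat(sprintf("  adaptation: narrow vs broad significant at every ERB threshold: %s\n",
              s$adapt_all_sig_erb))
  invisible(x)
}

#' Write an experiment report to CSV/JSON files
#'
#' Writes the adaptation grid as tidy CSV, the spatial filter as JSON, and
#' the headline summary as JSON into `dir`.
#'
#' @param report a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adapt <- report$adaptation
  adapt$latency <- round(adapt$latency, 6)
  utils::write.csv(as.data.frame(adapt),
                   file.path(dir, "adaptation_grid.csv"), row.names = FALSE)
  write_filter(report$dss$filter, file.path(dir, "spatial_filter.json"))
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
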