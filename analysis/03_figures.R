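#!/usr/bin/env Rscript
# Figures from the experiment report written by 02_experiment.R:
#   - adaptation curves (ERF peak vs N_a threshold, by context and window)
#   - spatial-filter weight and effective-pattern scalp maps
# Requires ggplot2; writes PDFs under results/figures/.

library(statoddball)
library(ggplot2)

grid_csv <- "results/experiment/adaptation_grid.csv"
if (!file.exists(grid_csv)) {
  stop("run analysis/02_experiment.R first (missing ", grid_csv, ")")
}
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

ad <- read.csv(grid_csv)
ad$window <- sprintf("%.2f oct", ad$delta)
p1 <- ggplot(ad, aes(cutpoint, peak_mean, colour = context,
                     alpha = window, group = interaction(context, window))) +
  geom_line() + geom_point(size = 1) +
  geom_errorbar(aes(ymin = peak_mean - peak_se, ymax = peak_mean + peak_se),
                width = 0.3) +
  scale_colour_manual(values = c(narrow = "#2166ac", broad = "#b2182b")) +
  scale_alpha_discrete(range = c(0.45, 1)) +
  labs(x = expression("threshold value of " * N[a]),
       y = "ERF peak (filtered signal, a.u.)",
       title = "Local adaptation of odd-probe responses by context") +
  theme_minimal()
ggsave(file.path(fig_dir, "adaptation_curves.pdf"), p1, width = 7, height = 5)

# spatial filter topographies (recomputed from the stored filter + layout)
filt <- jsonlite::read_json("results/experiment/spatial_filter.json",
                            simplifyVector = TRUE)
lay <- make_layout(length(filt$w), seed = child_seed(1, 0, 1))
interp <- scalp_interpolator(lay, 64)
as_df <- function(img, what) {
  data.frame(x = rep(interp$gx, times = 64), y = rep(interp$gy, each = 64),
             z = as.vector(img), what = what)
}
topo <- rbind(as_df(scalp_image(filt$w, interp), "filter weights"),
              as_df(scalp_image(filt$pattern, interp), "effective pattern"))
p2 <- ggplot(topo[!is.na(topo$z), ], aes(x, y, fill = z)) +
  geom_raster() + facet_wrap(~what) + coord_equal() +
  scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
  labs(title = "Max-SNR spatial filter", x = NULL, y = NULL) +
  theme_void()
ggsave(file.path(fig_dir, "spatial_filter.pdf"), p2, width = 8, height = 4)

cat(sprintf("figures written to %s\n", fig_dir))
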