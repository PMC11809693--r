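#!/usr/bin/env Rscript
# Minute-level cough-rate agreement between the gold standard and each
# phone: Pearson correlation, linear fit, and Bland-Altman percentage
# error. Writes results/agreement.csv and, when ggplot2 is available,
# scatter and Bland-Altman figures under results/figures/.

suppressPackageStartupMessages(library(coughval))

cfg <- run_config(manifest = "results/cohort/manifest.yaml",
                  out_dir = "results/evaluation", seed = 20260923L)
ev <- run_pipeline(cfg)

cat("Rate agreement (device counts vs gold counts per minute):\n")
print(ev$agreement, row.names = FALSE)
ba <- ev$bland_altman
cat(sprintf("\nBland-Altman: bias %.1f%%, LoA [%.1f%%, %.1f%%], %d segments (%d zero-gold excluded)\n",
            ba$mean_pct_error, ba$loa_lower, ba$loa_upper,
            ba$n_segments_used, ba$n_zero_gold_excluded))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
  seg <- ev$rate_segments
  set.seed(cfg$seed)
  jit <- function(x) x + runif(length(x), -0.3, 0.3)
  p1 <- ggplot(seg, aes(jit(gold_count), jit(device_count),
                        colour = device_id)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Human annotated coughs / minute",
         y = "Detected coughs / minute",
         colour = NULL,
         title = "Cough rate: monitor vs gold standard",
         subtitle = "points jittered by up to 0.3 counts; dashed line = perfect monitor")
  ggsave("results/figures/rate_scatter.png", p1, width = 6, height = 5,
         dpi = 150)
  use <- seg[seg$gold_count > 0, ]
  use$pct <- 100 * (use$device_count - use$gold_count) / use$gold_count
  p2 <- ggplot(use, aes(jit(gold_count), pct)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_hline(yintercept = c(ba$mean_pct_error, ba$loa_lower,
                              ba$loa_upper),
               linetype = c(1, 2, 2)) +
    labs(x = "Human annotated coughs / minute",
         y = "Percentage error in detections",
         title = "Bland-Altman, percentage error")
  ggsave("results/figures/bland_altman.png", p2, width = 6, height = 5,
         dpi = 150)
  cat("Figures written to results/figures/\n")
}
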