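#!/usr/bin/env Rscript
# Step 4 — figures.
#
# Forest-style summary of rBias and rRMSE per method and sample selection
# (the study's headline layout), plus forecast error versus lead time.

library(vancoforecast)
library(ggplot2)

dir.create("results/figures", recursive = FALSE, showWarnings = FALSE)

metrics <- read.csv("results/metrics_by_cell.csv", stringsAsFactors = FALSE)
pairs <- read.csv("results/forecast_pairs.csv", stringsAsFactors = FALSE)

method_order <- c("first_order", "conventional",
                  grep("^flat_", unique(metrics$method), value = TRUE),
                  "weighted")
metrics$method <- factor(metrics$method, levels = rev(method_order))

long <- rbind(
  data.frame(metrics[c("method", "samples_used")], metric = "rBias (%)",
             est = metrics$rbias, lo = metrics$rbias_lo, hi = metrics$rbias_hi),
  data.frame(metrics[c("method", "samples_used")], metric = "rRMSE (%)",
             est = metrics$rrmse, lo = metrics$rrmse_lo, hi = metrics$rrmse_hi))

p1 <- ggplot(long, aes(x = est, y = method, colour = samples_used)) +
  geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
  geom_pointrange(aes(xmin = lo, xmax = hi),
                  position = position_dodge(width = 0.7), linewidth = 0.4,
                  size = 0.3) +
  facet_wrap(~metric, scales = "free_x") +
  labs(x = NULL, y = NULL, colour = "samples used",
       title = "Forecasting accuracy and precision by method and sampling") +
  theme_bw(base_size = 10)
ggsave("results/figures/metrics_forest.pdf", p1, width = 9, height = 5)

pairs$dev <- pair_deviation(pairs$c_forecast, pairs$c_observed)
p2 <- ggplot(pairs, aes(lead_time_days, abs(dev))) +
  geom_point(alpha = 0.1, size = 0.5) +
  geom_smooth(method = "gam", formula = y ~ s(x, bs = "cs"),
              se = TRUE, colour = "firebrick") +
  labs(x = "forecast lead time (days)",
       y = "absolute symmetric deviation (%)",
       title = "Forecast error grows with lead time") +
  theme_bw(base_size = 10)
ggsave("results/figures/lead_time_error.pdf", p2, width = 6, height = 4)

cat("wrote results/figures/metrics_forest.pdf and lead_time_error.pdf\n")
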