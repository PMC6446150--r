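#!/usr/bin/env Rscript
# Stage 4: activity-tracking metrics.
#
# Tracker-device logs only (phone-source rows are passive and excluded).
# Raw tracking ratio k/n over the inclusive first-to-last-log span, shrunk
# toward the population mean with a 10-day prior; steps per distinct
# calendar week tracked; metrics eligibility = two logs >= 10 days apart.

library(adheretrack)

bundle <- read_bundle("results/bundle")
metrics <- tracking_metrics(bundle$activity, bundle$demographics)
write.csv(metrics, "results/tracking_metrics.csv", row.names = FALSE)

prior <- attr(metrics, "prior")
tr <- metrics[metrics$ever_tracked_any, ]
message(sprintf("%d trackers of %d individuals; r_mean = %.3f (prior strength %d days)",
                nrow(tr), nrow(metrics), prior$r_mean, prior$strength))
message(sprintf("raw ratio quartiles: %s", paste(round(quantile(tr$raw_ratio), 3), collapse = " ")))
message(sprintf("adjusted ratio quartiles: %s (pulled toward r_mean)",
                paste(round(quantile(tr$adjusted_ratio), 3), collapse = " ")))
message(sprintf("%d of %d trackers are metrics-eligible; median steps/week %.0f",
                sum(tr$metrics_eligible), nrow(tr),
                median(tr$steps_per_week, na.rm = TRUE)))
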