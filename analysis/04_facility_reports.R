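#!/usr/bin/env Rscript
# Step 4 — per-facility feedback: where should stewardship effort go?
#
# Summarizes the facility feedback reports written in step 2 into a
# region-wide list of improvement targets: for each nursing home, the
# proxy indicators outside their consensus target band, with the
# facility's value, percentile rank and the regional benchmark — the
# starting point of a personalized action plan.

suppressMessages({
  library(nhabx)
  library(dplyr)
})

fi <- readr::read_csv("results/indicators/facility_indicators.csv",
                      show_col_types = FALSE)
reg <- readr::read_csv("results/indicators/regional_summary.csv",
                       show_col_types = FALSE)

targets <- bind_rows(lapply(unique(fi$facility_id), function(f) {
  facility_report(fi[fi$facility_id == f, ], fi, reg) |>
    filter(status == "improvement_target")
}))

readr::write_csv(targets, "results/improvement_targets.csv")
cat(sprintf("%d improvement targets across %d facilities\n",
            nrow(targets), length(unique(targets$facility_id))))
cat("most frequent out-of-target indicators:\n")
print(sort(table(targets$indicator_id), decreasing = TRUE))
worst <- targets |>
  group_by(facility_id) |>
  summarise(n_targets = n(), .groups = "drop") |>
  arrange(desc(n_targets)) |>
  head(5)
cat("facilities with the most improvement targets:\n")
print(as.data.frame(worst))
cat("wrote results/improvement_targets.csv\n")
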