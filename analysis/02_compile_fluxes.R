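#!/usr/bin/env Rscript
# Step 2 — ingest and prepare the flux compilation.
#
# Reads the compilation CSV written by step 1, filters out unusable records
# (indirect methods, beaver ponds, missing metadata), disaggregates reported
# averages into their component observations, applies the 0.7 diel correction
# to daytime-only measurements, and assigns each record an ecoclimatic type.
# Writes the prepared records and a rejection report with one reason each.

library(lakech4)
library(readr)

seed <- if (length(commandArgs(TRUE)) > 0) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- generator_config(seed = seed, lon_range = c(0, 2))
layers <- generate_geophysical_layers(cfg)
type_map <- classify_ecoclimatic(layers)

records <- read_compilation("results/compilation.csv")
prep <- prepare_records(records, type_map, layers)

write_csv(prep$records, "results/records_prepared.csv")
write_csv(prep$rejected[, c("record_id", "reason")],
          "results/rejection_report.csv")

message(sprintf("%d raw records -> %d prepared (%d disaggregated in), %d rejected",
                nrow(records), nrow(prep$records), prep$n_disaggregated,
                nrow(prep$rejected)))
print(table(prep$rejected$reason))
day_frac <- mean(prep$records$sampling_window == "daytime")
message(sprintf("%.0f%% of kept records were daytime-only and diel-corrected x0.7",
                100 * day_frac))
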