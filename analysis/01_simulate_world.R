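#!/usr/bin/env Rscript
# Step 1 — simulate a synthetic world.
#
# Generates every input the upscaling pipeline consumes: a flux-measurement
# compilation (with planted metadata defects), gridded geophysical layers and
# a monthly temperature climatology, two multi-year phenology sources, and a
# lake-area grid split by size class. Ground truth (type map, generator
# parameters) is known, so later steps can be checked against it.

library(lakech4)
library(readr)

seed <- if (length(commandArgs(TRUE)) > 0) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed, lon_range = c(0, 2))
world <- generate_world(cfg)

write_compilation_csv(world, "results/compilation.csv")
write_csv(grid_to_tidy(world$grid, world$layers$true_type, "lake_type"),
          "results/true_type_map.csv")
write_csv(grid_to_tidy(world$grid, world$areas$area_small, "area_small_km2"),
          "results/lake_area_small.csv")

n_lake <- sum(world$areas$area_small + world$areas$area_large > 0)
message(sprintf("world: %d cells (%d with lakes), %d flux records, seed %d",
                prod(dim(world$layers$soc)), n_lake, nrow(world$records), seed))
message(sprintf("lake area: %.0f km2 small-class, %.0f km2 large-class",
                sum(world$areas$area_small), sum(world$areas$area_large)))
message("all seven ecoclimatic types present: ",
        setequal(unique(as.vector(world$layers$true_type)), lake_types()))
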