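#!/usr/bin/env Rscript
# Stage 1: build the synthetic study landscape.
#
# A 30 x 30 lattice of 2428-ha cells (4927 m wide) emulating the two-state
# forest-inventory grid: ~55% forest land, humid-subtropical climate
# covariates, and six sparse low-occupancy (<25%) privet foci confined to
# forest cells.

suppressPackageStartupMessages(library(privetspread))

SEED <- 42
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n_foci = 6)
grid <- generate_grid(900, cfg, seed = SEED)
write_cell_table(grid, "results/cells.csv", config = cfg)

cat("Landscape:", n_cells(grid), "cells;", sum(forest_mask(grid)),
    "forest cells\n")
cat("Land types:\n")
print(table(grid$cells$land_type))
foci <- which(grid$occupancy0 > 0)
cat("Invasion foci:", length(foci), "forest cells, occupancy",
    paste(round(grid$occupancy0[foci], 1), collapse = ", "), "%\n")
cat("Wrote results/cells.csv\n")
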