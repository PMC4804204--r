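#!/usr/bin/env Rscript
# Stage 3: intrinsic spread rates.
#
# A second occupancy survey five years after the first is generated with
# exponential growth at rates given by the published r ~ HQ curve plus
# lognormal noise; per-cell rates are then re-estimated from the paired
# surveys (r = ln(P2/P1)/(t2-t1), with the standard exclusions), the seven
# candidate r ~ HQ functional forms are fitted and compared, and the best
# curve imputes rates for cells without usable pairs.

suppressPackageStartupMessages(library(privetspread))

SEED <- 44
grid <- read_cell_table("results/cells.csv")
fmask <- forest_mask(grid)
hq_tab <- read.csv("results/hq_predictions.csv")

truth_hq <- synthetic_hq_truth(grid, 0.3)
r_true <- predict(reference_spread_rate_model(),
                  predict_hq(truth_hq, grid$cells))

# the rate survey covers every invaded forest plot (the stage-2 presence
# draw), not just the sparse simulation foci; leading-edge occupancies are
# small (<1%) so that five years of exponential growth stays below K for
# every habitat quality -- larger starts saturate at K and censor the
# log-ratio rate estimator
grid_survey <- grid
inv <- rep(FALSE, n_cells(grid))
inv[match(hq_tab$cell_id[hq_tab$presence == 1], grid$cells$cell_id)] <- TRUE
set.seed(SEED)
grid_survey$occupancy0[inv] <- runif(sum(inv), 0.1, 0.8)

pair <- generate_survey_pair(grid_survey, r_true, interval = 5,
                             noise_sd = 0.25, seed = SEED + 1,
                             prop_treated = 0.02)
est <- estimate_r(pair)
est$P_t1 <- pair$P_t1
est$P_t2 <- pair$P_t2
cat("Survey pair", pair$t1, "->", pair$t2, ":",
    sum(!est$excluded & pair$P_t1 > 0), "usable pairs;",
    "exclusions:", paste(names(table(est$reason)), table(est$reason),
                         collapse = ", "), "\n")

hq_hat <- hq_tab$hq[match(grid$cells$cell_id[fmask], hq_tab$cell_id)]
rfit <- fit_r_hq(est$r[fmask], hq_hat)
cat("r ~ HQ comparison (best:", rfit$best, "):\n")
print(rfit$table, digits = 3)

curve <- if (!is.na(rfit$best)) rfit$best_model else reference_spread_rate_model()
r_forest <- impute_r(curve, hq_hat, est$r[fmask])
est$r_final <- 0
est$r_final[fmask] <- r_forest

write.csv(est, "results/r_estimates.csv", row.names = FALSE)
write.csv(rfit$table, "results/r_hq_table.csv", row.names = FALSE)
cat(sprintf("Imputed rates for %d unsurveyed forest cells; r at HQ = 0.95: %.2f\n",
            sum(is.na(est$r[fmask])), predict(curve, 0.95)))
cat("Wrote results/r_estimates.csv, results/r_hq_table.csv\n")
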