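#!/usr/bin/env Rscript
# Fits the pathway model to the two-dose synthetic dataset by hybrid
# simulated annealing + local refinement and reports the chi-squared, the
# estimated parameters and the fitted observables.

suppressPackageStartupMessages(library(stat1dyn))
if (!file.exists("results/dataset.csv")) {
  stop("run analysis/02_synthesize_data.R first")
}
dataset <- read_dataset_csv("results/dataset.csv")

fit <- fit_pathway(dataset, settings = optimizer_settings(seed = 7))
print(fit)

write_fit_json(fit, "results/fit.json")
utils::write.csv(fit$fitted, "results/fitted_observables.csv",
                 row.names = FALSE)
for (dose in fit$doses) {
  write_trajectory_csv(fitted_trajectory(fit, dose),
                       sprintf("results/fit_trajectory_dose%03d.csv", dose))
}
saveRDS(fit, "results/fit.rds")   # reused by the sweep driver

cover <- mean(abs(fit$fitted$y_mod - fit$fitted$mean) <= 2 * fit$fitted$sem)
cat(sprintf("fitted curves within 2 SEM of the data at %.0f%% of points\n",
            100 * cover))
cat("wrote results/fit.json, fitted_observables.csv, fit trajectories\n")
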