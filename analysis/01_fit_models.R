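#!/usr/bin/env Rscript
# Stage 1 — fit the twelve development-rate models to the Telenomus remus
# egg-adult means and tabulate fit statistics (S, AIC, BIC, deltas),
# fitted parameters and derived thermal thresholds.

suppressMessages(library(phenotherm))
dir.create("results", showWarnings = FALSE)

dev <- remus_development()
cat("Development data:\n")
print(dev)

fits <- suppressWarnings(fit_all_models(dev, seed = 1))
cmp <- compare_models(fits, species = "te_remus")

cat("\nModel comparison (sorted by delta AIC):\n")
print(cmp[order(cmp$delta_aic),
          c("model", "k", "s", "delta_aic", "delta_bic",
            "t_l", "t_opt", "t_h", "n_plausible")], digits = 3)

cat("\nLinear model: t_l =", round(cmp$t_l[cmp$model == "linear"], 2),
    "C, thermal constant k =",
    round(fits$linear$thresholds$k, 2), "degree-days\n")
cat("Best fit by delta AIC:", cmp$model[cmp$delta_aic == 0], "\n")

utils::write.csv(as.data.frame(cmp), "results/fit_comparison_remus.csv",
                 row.names = FALSE)

# persist the refitted parameter sets for downstream stages
cfg <- list(te_remus = lapply(fits, function(f) {
  p <- f$params
  attr(p, "thresholds") <- f$thresholds
  p
}))
write_params_config(cfg, "results/fitted_params_remus.yaml")
cat("\nWrote results/fit_comparison_remus.csv and",
    "results/fitted_params_remus.yaml\n")
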