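#!/usr/bin/env Rscript
# Step 5 — render the report: CDB-versus-speed figure with model overlays,
# model-component curves (prior, g(v), h(c)), and a machine-readable summary.
#
# Inputs: results/ tables from steps 1-2 (the dataset is regenerated from
# the recorded seed; figures and summary land in results/report/).

library(speedprior)

out_dir <- "results"
observer <- observer_from_json(file.path(out_dir, "observer_true.json"))
dataset <- generate_dataset(observer, build_design(), master_seed = 42)

tab <- read_pse_table(file.path(out_dir, "pse_table.csv"))
stopifnot(isTRUE(all.equal(pse_summary(dataset)$mean_pse, tab$mean_pse)))

alpha_hat <- calibrate_alpha(dataset)
fit <- fit_model(tab, fit_config(n_multistart = 20, alpha = alpha_hat,
                                 n_trials = 35))

files <- render_report(dataset, fits = list(bayesian = fit),
                       out_dir = file.path(out_dir, "report"))
cat("report files:\n")
cat(paste(" ", files, collapse = "\n"), "\n")
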