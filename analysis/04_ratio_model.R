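#!/usr/bin/env Rscript
# Step 4 — characterize the temporal-filter ratio front end and the combined
# (ratio + Bayesian) model.
#
# Writes the front end's speed-transfer curves at the three experimental
# contrasts, locates the speed below which contrast still affects the
# output, and checks that the combined fit nests and beats the plain
# Bayesian fit on front-end-generated data.

library(speedprior)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

rp <- ratio_params()   # combined-model values: tau 0.0353/0.0211, k 0.55, s 0.5
grid <- seq(0.1, 12, by = 0.01)
curves <- data.frame(
  speed = grid,
  out_c03 = ratio_output(rp, grid, 0.03, sf = 2),
  out_c15 = ratio_output(rp, grid, 0.15, sf = 2),
  out_c95 = ratio_output(rp, grid, 0.95, sf = 2)
)
utils::write.csv(curves, file.path(out_dir, "ratio_model_curves.csv"),
                 row.names = FALSE)

cross <- ratio_crossover_speed(rp, sf = 2, grid = grid)
cat(sprintf("largest speed with a >1%% contrast effect (95%% vs 3%%): %.2f deg/s\n",
            cross))
cat(sprintf("output at v = 8, c = 0.95: %.2f deg/s (true 8)\n",
            ratio_output(rp, 8, 0.95, sf = 2)))

# combined vs plain Bayesian on data generated WITH the front end
cfg <- fit_config(n_multistart = 4,
                  outer_grid = list(s = c(0.25, 0.5, 1),
                                    k = c(0.3, 0.55, 1),
                                    tau_scale = c(2.5, 4.9, 7.5)),
                  outer_refine = FALSE)
truth <- default_observer(ratio = rp)
tab <- local({
  t <- build_design()$conditions[, c("condition_id", "v_ref", "c_ref", "c_test")]
  t$n_staircases <- 40L
  t$mean_pse <- vapply(seq_len(nrow(t)), function(i) predict_pse(truth, t[i, ]),
                       numeric(1))
  t$pse_var <- vapply(seq_len(nrow(t)), function(i) {
    predict_pse_var(truth, t[i, ], cfg, pse = t$mean_pse[i])
  }, numeric(1))
  class(t) <- c("pse_table", "data.frame")
  t
})
fit_b <- fit_model(tab, cfg)
fit_c <- fit_combined(tab, cfg)
cat(sprintf("\nplain Bayesian fit deviance: %.4g\n", fit_b$deviance))
cat(sprintf("combined fit deviance:       %.4g\n", fit_c$deviance))
cat(sprintf("selected front end: s = %.2f, k = %.2f, tau scale = %.2f\n",
            fit_c$outer$s, fit_c$outer$k, fit_c$outer$tau_scale))
fit_to_json(fit_c, file.path(out_dir, "fit_combined.json"))
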