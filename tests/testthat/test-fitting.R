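test_that("the predicted PSE solves the posterior-mean equality", {
  cond <- list(condition_id = "x", v_ref = 4, c_ref = 0.03, c_test = 0.95)
  # zero slopes: the PSE is the reference speed exactly
  expect_equal(predict_pse(zero_slope_observer(), cond), 4, tolerance = 1e-7)
  # constant slope and g: closed form v2 = v1 + a (sigma1^2 - sigma2^2)
  ob <- constant_observer(a = -0.2, g = 0.8)
  s1 <- likelihood_sigma(ob$likelihood, 4, 0.03)
  s2 <- likelihood_sigma(ob$likelihood, 4, 0.95)
  expect_equal(predict_pse(ob, cond), 4 - 0.2 * (s1^2 - s2^2), tolerance = 1e-6)
  # Thompson direction for negative slopes
  expect_lt(predict_pse(default_observer(), cond), 4)
  # no sign change on a bad bracket is reported as non-identifiable
  expect_error(predict_pse(default_observer(), cond, bracket = c(0.05, 0.5)),
               "non-identifiable")
})

test_that("the predicted PSE variance is alpha (sigma1^2 + sigma2^2) / N and is linear", {
  ob <- constant_observer(a = 0, g = 0.8)
  cond <- list(condition_id = "x", v_ref = 4, c_ref = 0.03, c_test = 0.95)
  cfg <- fit_config(alpha = 6.6, n_trials = 40)
  s1sq <- likelihood_sigma(ob$likelihood, 4, 0.03)^2
  s2sq <- likelihood_sigma(ob$likelihood, 4, 0.95)^2
  expect_equal(predict_pse_var(ob, cond, cfg), 6.6 * (s1sq + s2sq) / 40)
  # doubling both sigma^2 doubles the prediction
  ob2 <- constant_observer(a = 0, g = 0.8 * sqrt(2))
  expect_equal(predict_pse_var(ob2, cond, cfg), 2 * predict_pse_var(ob, cond, cfg))
  # equal widths, the classic divisor 6: sigma^2 / 3
  expect_equal(6.6 * (3 + 3) / 40, 6 / 6.06060606, tolerance = 1e-6)
})

test_that("prior reconstruction integrates the slope field", {
  grid <- seq(1, 12, by = 0.05)
  # constant slope: exact exponential
  pr_const <- prior_model(rep(-0.25, 4))
  expect_equal(reconstruct_prior(pr_const, grid), exp(-0.25 * (grid - 1)),
               tolerance = 1e-9)
  # zero slopes: flat prior of ones
  expect_equal(reconstruct_prior(prior_model(rep(0, 4)), grid),
               rep(1, length(grid)))
  # piecewise-linear slopes: refinement oracle on a non-aligned grid
  pr <- prior_model(c(-0.3, -0.15, -0.08, -0.05))
  coarse <- seq(0.7, 13.3, by = 0.35)
  fine <- seq(0.7, 13.3, by = 0.35 / 64)
  dens_c <- reconstruct_prior(pr, coarse)
  dens_f <- reconstruct_prior(pr, fine)
  at <- match(round(coarse, 10), round(fine, 10))
  expect_true(all(is.finite(at)))
  expect_equal(dens_c, dens_f[at], tolerance = 1e-6)
  # normalization convention: density 1 at the first grid point
  expect_equal(dens_c[1], 1)
  expect_error(reconstruct_prior(pr, numeric(0)), "empty")
  expect_error(reconstruct_prior(pr, c(3, 2)), "increasing")
})

test_that("CDB goodness of fit matches its definition", {
  ob <- default_observer()
  cfg <- fit_config()
  tab <- noise_free_table(ob, cfg)
  # the generating observer predicts its own table perfectly
  gof <- goodness_of_fit(ob, tab)
  expect_equal(gof$sse, 0, tolerance = 1e-10)
  expect_equal(gof$r2, 1, tolerance = 1e-6)
  # predicting the mean CDB everywhere gives r2 = 0 by definition
  cdb <- tab$mean_pse / tab$v_ref
  g0 <- speedprior:::cdb_gof(cdb, rep(mean(cdb), length(cdb)))
  expect_equal(g0$r2, 0)
  # a zero-residual condition leaves the SSE unchanged
  g1 <- speedprior:::cdb_gof(c(cdb, 0.9), c(rep(mean(cdb), length(cdb)), 0.9))
  expect_equal(g1$sse, g0$sse)
})

test_that("the fast fit is deterministic and self-consistent on noise-free tables", {
  ob <- default_observer()
  cfg <- fit_config(n_multistart = 2, master_seed = 5)
  tab <- noise_free_table(ob, cfg)
  f1 <- fit_model(tab, cfg)
  f2 <- fit_model(tab, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$best_start, f2$best_start)
  expect_lt(f1$deviance, 1e-6)
  expect_equal(f1$r2, 1, tolerance = 1e-4)
  expect_true(all(f1$observer$prior$knot_slopes < 0))
  expect_error(fit_model(tab[1:4, ], cfg), "identifiability")
})

test_that("the combined fit with an identity front end reproduces the Bayesian fit exactly", {
  ob <- default_observer()
  cfg <- fit_config(n_multistart = 2, master_seed = 5)
  tab <- noise_free_table(ob, cfg)
  fb <- fit_model(tab, cfg)
  fc <- fit_combined(tab, cfg, ratio = ratio_identity(cfg$spatial_frequency))
  expect_equal(fc$params, fb$params)
  expect_equal(fc$deviance, fb$deviance)
  expect_equal(fc$sse, fb$sse)
})

test_that("the combined fit beats the Bayesian fit on front-end-generated data", {
  ob_r <- default_observer(ratio = ratio_params())
  cfg <- fit_config(n_multistart = 2, master_seed = 5,
                    outer_grid = list(s = 0.5, k = 0.55, tau_scale = 4.9),
                    outer_refine = FALSE)
  tab <- noise_free_table(ob_r, cfg)
  fb <- fit_model(tab, cfg)
  fc <- fit_combined(tab, cfg)
  expect_lte(fc$deviance, fb$deviance + 1e-9)
  # at the true front end the inner problem still has 10 free parameters
  expect_equal(length(fc$params), 10)
})

test_that("the trial-level likelihood prefers the generating parameters and is seed-stable", {
  ob <- default_observer()
  des <- small_design(sessions = 1, trials = 20)
  ds <- generate_dataset(ob, des, master_seed = 61)
  tl <- trial_log(ds)
  # Bernoulli log-likelihood, computed directly from choice_probability
  loglik <- function(obs) {
    p <- choice_probability(obs, tl$v_ref, tl$c_ref, tl$v_test, tl$c_test)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(log(ifelse(tl$response_test_faster, p, 1 - p)))
  }
  perturbed <- ob
  perturbed$prior$knot_slopes <- ob$prior$knot_slopes * -1
  expect_gt(loglik(ob), loglik(perturbed))

  cfg <- fit_config(n_multistart = 2, master_seed = 5)
  f1 <- fit_full_likelihood(tl, cfg, table = pse_summary(ds))
  f2 <- fit_full_likelihood(tl, cfg, table = pse_summary(ds))
  expect_identical(f1$params, f2$params)
  expect_true(is.finite(f1$logLik))
  expect_equal(nrow(f1$residual_table), 12)
  expect_error(fit_full_likelihood(tl[, 1:3], cfg), "columns")
})

test_that("alpha calibration recovers the variance scale of a known generator", {
  ob <- default_observer()
  cfg <- fit_config()
  # on a noise-free table built with a known alpha, calibration returns it
  for (a_true in c(2, 6.6)) {
    cfg_a <- fit_config(alpha = a_true, n_trials = 35)
    tab <- noise_free_table(ob, cfg_a)
    expect_equal(calibrate_alpha(tab, observer = ob, n_trials = 35), a_true,
                 tolerance = 1e-6)
  }
})
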