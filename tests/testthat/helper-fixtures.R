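# Shared fixtures: all built in code, sized for fast unit runs. Heavier
# simulations live in test-acceptance.R.

# observer with constant prior slope and constant g (closed-form cases)
constant_observer <- function(a = -0.2, g = 0.8, q = 2, c50 = 0.1) {
  observer_spec(
    prior = prior_model(rep(a, 4)),
    likelihood = likelihood_model(rep(g, 4), contrast_response(q, c50))
  )
}

zero_slope_observer <- function(g = c(0.2, 0.5, 0.9, 1.4)) {
  observer_spec(
    prior = prior_model(rep(0, 4)),
    likelihood = likelihood_model(g, contrast_response(2, 0.1))
  )
}

# near-deterministic observer: tiny widths, zero slopes
noiseless_observer <- function() {
  observer_spec(
    prior = prior_model(rep(0, 4)),
    likelihood = likelihood_model(rep(1e-3, 4), contrast_response(2, 0.1))
  )
}

# noise-free pse_table: model predictions as "observations"
noise_free_table <- function(observer, config = fit_config(),
                             design = build_design(), n_staircases = 40L) {
  tab <- design$conditions[, c("condition_id", "v_ref", "c_ref", "c_test")]
  tab$n_staircases <- n_staircases
  tab$mean_pse <- vapply(seq_len(nrow(tab)), function(i) {
    predict_pse(observer, tab[i, ], bracket = config$bracket)
  }, numeric(1))
  tab$pse_var <- vapply(seq_len(nrow(tab)), function(i) {
    predict_pse_var(observer, tab[i, ], config, pse = tab$mean_pse[i])
  }, numeric(1))
  class(tab) <- c("pse_table", "data.frame")
  tab
}

# a miniature design for end-to-end smoke tests
small_design <- function(sessions = 1, trials = 20) {
  build_design(sessions = sessions,
               staircases_per_session = c(low_speed = 2, high_speed = 2),
               trials_per_staircase = trials)
}

# independent oracle: nested numeric double integration of the sampling rule
# p(sample2 > sample1) over the Gaussian posteriors (full real line)
choice_prob_oracle <- function(observer, v1, c1, v2, c2) {
  e1 <- posterior_mean(observer, v1, c1)
  sd1 <- sqrt(posterior_var(observer, v1, c1))
  e2 <- posterior_mean(observer, v2, c2)
  sd2 <- sqrt(posterior_var(observer, v2, c2))
  outer_f <- function(x) {
    sapply(x, function(xx) {
      stats::dnorm(xx, e2, sd2) *
        stats::integrate(function(y) stats::dnorm(y, e1, sd1),
                         lower = e1 - 12 * sd1, upper = xx,
                         rel.tol = 1e-10)$value
    })
  }
  stats::integrate(outer_f, e2 - 12 * sd2, e2 + 12 * sd2,
                   rel.tol = 1e-10)$value
}
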