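test_that("quest recommendation is the posterior mode with low-speed tie-break", {
  cfg <- quest_config()
  st <- quest_init(cfg, prior_mean_guess = 4)
  # flat posterior: first (lowest) grid point wins
  st_flat <- st
  st_flat$log_posterior[] <- 0
  expect_equal(quest_recommend(st_flat), cfg$grid_lo)
  # peaked posterior: that grid point
  st_peak <- st_flat
  j <- 137L
  st_peak$log_posterior[j] <- 5
  expect_equal(quest_recommend(st_peak), 10^st_peak$log10_grid[j])
  # invariance to adding a constant
  st2 <- st
  st2$log_posterior <- st$log_posterior + 123.4
  expect_equal(quest_recommend(st2), quest_recommend(st))
  # degenerate posterior errors
  st_bad <- st
  st_bad$log_posterior[] <- -Inf
  expect_error(quest_recommend(st_bad), "degenerate")
})

test_that("quest updates commute and the kernel crosses guess_gamma at the candidate PSE", {
  cfg <- quest_config()
  st0 <- quest_init(cfg, prior_mean_guess = 4)
  a <- quest_update(quest_update(st0, 3, TRUE, cfg), 6, FALSE, cfg)
  b <- quest_update(quest_update(st0, 6, FALSE, cfg), 3, TRUE, cfg)
  expect_equal(a$log_posterior, b$log_posterior)
  # shown speed == candidate PSE contributes the chance-level factor there
  k0 <- speedprior:::quest_kernel(0, cfg$slope_beta, cfg$lapse_delta,
                                  cfg$guess_gamma)
  expect_equal(k0, cfg$guess_gamma)
  expect_error(quest_update(st0, 1000, TRUE, cfg), "outside")
})

test_that("repeated 'test faster' responses drive the mode monotonically down", {
  cfg <- quest_config()
  st <- quest_init(cfg, prior_mean_guess = 4)
  modes <- numeric(20)
  for (i in 1:20) {
    st <- quest_update(st, 4, TRUE, cfg)
    modes[i] <- quest_recommend(st)
  }
  expect_true(all(diff(modes) <= 0))
  expect_lt(modes[20], 4)
})

test_that("simulated choices match the closed-form probability in the long run", {
  ob <- default_observer()
  p_true <- choice_probability(ob, 4, 0.03, 5, 0.95)
  set.seed(10)
  n <- 10000
  hits <- sum(vapply(seq_len(n), function(i) {
    simulate_choice(ob, 4, 0.03, 5, 0.95)
  }, logical(1)))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(hits / n - p_true), 3 * se)
  # identical stimuli: about half
  set.seed(11)
  half <- mean(vapply(seq_len(4000), function(i) {
    simulate_choice(ob, 4, 0.15, 4, 0.15)
  }, logical(1)))
  expect_lt(abs(half - 0.5), 3 * sqrt(0.25 / 4000))
  # deterministic limit
  obn <- noiseless_observer()
  expect_true(all(vapply(1:20, function(s) {
    simulate_choice(obn, 4, 0.03, 4.2, 0.95, rng_seed = s)
  }, logical(1))))
  # reproducible under a fixed seed
  expect_equal(simulate_choice(ob, 4, 0.03, 4.1, 0.95, rng_seed = 7),
               simulate_choice(ob, 4, 0.03, 4.1, 0.95, rng_seed = 7))
})

test_that("a staircase runs its full length, logs consistently, and is seed-deterministic", {
  cond <- list(condition_id = "v4_c3_95", v_ref = 4, c_ref = 0.03, c_test = 0.95)
  cfg <- quest_config(n_trials = 25)
  ob <- default_observer()
  r1 <- run_staircase(ob, cond, cfg, rng_seed = 5)
  r2 <- run_staircase(ob, cond, cfg, rng_seed = 5)
  expect_identical(r1$trials, r2$trials)
  expect_equal(r1$pse, r2$pse)
  expect_equal(r1$n_trials, 25)
  expect_equal(nrow(r1$trials), 25)
  expect_true(all(r1$trials$c_ref < r1$trials$c_test))
  expect_true(r1$pse >= cfg$grid_lo && r1$pse <= cfg$grid_hi)
  # reversed contrasts are rejected
  bad <- list(condition_id = "x", v_ref = 4, c_ref = 0.95, c_test = 0.03)
  expect_error(run_staircase(ob, bad, cfg, rng_seed = 1), "lower contrast")
})

test_that("a noiseless observer drives the staircase to the reference speed", {
  cond <- list(condition_id = "v4", v_ref = 4, c_ref = 0.03, c_test = 0.95)
  cfg <- quest_config()
  r <- run_staircase(noiseless_observer(), cond, cfg, rng_seed = 3)
  grid_step <- 10^(diff(seq(log10(cfg$grid_lo), log10(cfg$grid_hi),
                            length.out = cfg$grid_n))[1])
  expect_lt(abs(log10(r$pse) - log10(4)), log10(grid_step) * 1.5)
})

test_that("negative slopes push staircase PSEs below the reference speed", {
  cond <- list(condition_id = "v4_c3_95", v_ref = 4, c_ref = 0.03, c_test = 0.95)
  ob <- default_observer()
  cfg <- quest_config()
  pses <- vapply(1:100, function(s) {
    run_staircase(ob, cond, cfg, rng_seed = s)$pse
  }, numeric(1))
  expect_lt(mean(pses), 4)
  # the analytic PSE sits inside the central 95% of the staircase PSEs
  analytic <- predict_pse(ob, cond)
  qs <- stats::quantile(pses, c(0.025, 0.975))
  expect_gt(analytic, qs[1])
  expect_lt(analytic, qs[2])
})
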