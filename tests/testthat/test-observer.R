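test_that("slope interpolation hits knots, midpoints, and clamps outside", {
  pr <- prior_model(c(-0.3, -0.15, -0.08, -0.05))
  expect_equal(slope_at(pr, 4), -0.15)
  expect_equal(slope_at(pr, 2.5), (-0.3 + -0.15) / 2)
  expect_equal(slope_at(pr, 20), -0.05)   # clamp above
  expect_equal(slope_at(pr, 0.2), -0.3)   # clamp below
  expect_error(slope_at(pr, -1), "positive")
  expect_error(prior_model(c(-0.1, -0.1), knot_speeds = c(4, 1)), "increasing")
  expect_error(prior_model(c(-0.1), knot_speeds = c(1, 4)), "one slope per")
})

test_that("contrast gain has the stated limits and is strictly decreasing", {
  cr <- contrast_response(q = 2, c50 = 0.1)
  expect_equal(contrast_gain(cr, 0), 5)            # 1 / r_base
  expect_equal(contrast_gain(cr, 0.1), 1 / 0.7)    # half saturation
  expect_equal(contrast_gain(cr, 1e6), 1 / 1.2, tolerance = 1e-6)
  expect_error(contrast_gain(cr, -0.1), "non-negative")

  set.seed(1)
  for (i in 1:20) {
    cr_i <- contrast_response(q = runif(1, 0.3, 6), c50 = runif(1, 0.02, 0.9))
    cs <- sort(runif(30, 0, 1))
    h <- contrast_gain(cr_i, cs)
    expect_true(all(diff(h) < 0))
    expect_true(all(h > 1 / (cr_i$r_max + cr_i$r_base) & h <= 1 / cr_i$r_base))
  }
})

test_that("likelihood width is the product g(v) * h(c) and shrinks with contrast", {
  cr <- contrast_response(2, 0.1)
  lik <- likelihood_model(c(0.2, 0.5, 0.9, 1.4), cr)
  expect_equal(likelihood_sigma(lik, 4, 0.15), 0.5 * contrast_gain(cr, 0.15))
  expect_gt(likelihood_sigma(lik, 4, 0.03), likelihood_sigma(lik, 4, 0.95))
  # clamped g at a high speed, saturated contrast
  expect_equal(likelihood_sigma(lik, 30, 1e6), 1.4 / 1.2, tolerance = 1e-6)
  expect_error(likelihood_model(c(0, 0.5, 0.9, 1.4), cr), "positive")
})

test_that("posterior mean adds the prior-induced bias a(v) * sigma^2", {
  expect_equal(posterior_mean(zero_slope_observer(), c(1, 4, 8, 12), 0.15),
               c(1, 4, 8, 12))
  # forced arithmetic: a = -1, sigma^2 = 0.5 at v = 4
  ob <- constant_observer(a = -1, g = 1)
  h <- contrast_gain(ob$likelihood$contrast, 0.5)
  ob$likelihood$knot_g[] <- sqrt(0.5) / h
  expect_equal(posterior_var(ob, 4, 0.5), 0.5)
  expect_equal(posterior_mean(ob, 4, 0.5), 3.5)
  # with negative slopes the bias is larger at lower contrast
  obn <- default_observer()
  expect_lt(posterior_mean(obn, 4, 0.03), posterior_mean(obn, 4, 0.95))
  expect_lt(posterior_mean(obn, 4, 0.03), 4)
})

test_that("posterior variance is sigma^2 and ignores the prior slopes", {
  ob1 <- constant_observer(a = -0.5, g = 0.3)
  ob2 <- constant_observer(a = 0.2, g = 0.3)
  expect_equal(posterior_var(ob1, 4, 0.15), posterior_var(ob2, 4, 0.15))
  expect_equal(posterior_var(ob1, 4, 0.15),
               likelihood_sigma(ob1$likelihood, 4, 0.15)^2)
})

test_that("ratio model saturates to k*w, is veridical at high speed, and slows with contrast at low speed", {
  rp <- ratio_params()
  # weak-saturation limit (semi-saturation far above the filter drives):
  # both stages are linear in contrast and the ratio is mbar/pbar = k * w
  rp_lin <- ratio_params(k = 0.55, s_p = 1e9, s_m = 1e9)
  v <- c(0.5, 2, 8)
  expect_equal(ratio_output(rp_lin, v, 1, sf = 2), 0.55 * v * 2,
               tolerance = 1e-6)
  # full saturation (both hyperbolic stages at ceiling) collapses the ratio to 1
  rp_sat <- ratio_params(k = 0.55, s_p = 1e-12, s_m = 1e-12)
  expect_equal(ratio_output(rp_sat, v, 1, sf = 2), rep(1, 3), tolerance = 1e-6)
  # near-veridical at v = 8 with the fitted parameters
  expect_lt(abs(ratio_output(rp, 8, 0.95, sf = 2) - 8) / 8, 0.15)
  # output decreases with contrast wherever mbar > pbar, i.e. above
  # v = 1/(k*sf); below that boundary the effect reverses
  expect_lt(ratio_output(rp, 1, 0.95, sf = 2), ratio_output(rp, 1, 0.03, sf = 2))
  expect_lt(ratio_output(rp, 1.5, 0.95, sf = 2), ratio_output(rp, 1.5, 0.03, sf = 2))
  expect_gt(ratio_output(rp, 0.5, 0.95, sf = 2), ratio_output(rp, 0.5, 0.03, sf = 2))
  # contrast-invariance (within 10%) at high speeds for the extreme contrasts
  for (vv in c(5, 8, 12)) {
    lo <- ratio_output(rp, vv, 0.03, sf = 2)
    hi <- ratio_output(rp, vv, 0.95, sf = 2)
    expect_lt(abs(lo - hi) / lo, 0.10)
  }
  expect_error(ratio_output(rp, 4, 0, sf = 2), "zero contrast")
  expect_error(ratio_params(tau1 = -1), "positive")
})

test_that("identity front end reproduces the stimulus speed exactly", {
  rid <- ratio_identity(sf = 2)
  v <- c(0.3, 1, 4, 12, 25)
  for (cc in c(0.03, 0.5, 0.95)) {
    expect_equal(ratio_output(rid, v, cc, sf = 2), v)
  }
  # plugging it into an observer changes nothing
  ob <- default_observer()
  ob_id <- default_observer(ratio = ratio_identity(2))
  expect_equal(posterior_mean(ob_id, c(1, 4, 8), 0.15),
               posterior_mean(ob, c(1, 4, 8), 0.15))
})

test_that("choice probability is symmetric, complementary, and saturates", {
  ob <- default_observer()
  expect_equal(choice_probability(ob, 4, 0.5, 4, 0.5), 0.5)
  # +10 sd separation
  obz <- zero_slope_observer(g = rep(0.1, 4))
  expect_gt(choice_probability(obz, 4, 0.95, 4 + 10 * 0.2, 0.95), 1 - 1e-6)
  set.seed(2)
  for (i in 1:25) {
    v1 <- runif(1, 1, 12); v2 <- runif(1, 1, 12)
    c1 <- sample(c(0.03, 0.15, 0.95), 1); c2 <- sample(c(0.03, 0.15, 0.95), 1)
    expect_equal(choice_probability(ob, v1, c1, v2, c2) +
                   choice_probability(ob, v2, c2, v1, c1), 1)
  }
})

test_that("closed-form choice probability matches the double-integral oracle", {
  ob <- default_observer()
  set.seed(3)
  for (i in 1:20) {
    v1 <- runif(1, 1, 12); v2 <- runif(1, 1, 12)
    cs <- sample(c(0.03, 0.15, 0.95), 2)
    expect_equal(choice_probability(ob, v1, cs[1], v2, cs[2]),
                 choice_prob_oracle(ob, v1, cs[1], v2, cs[2]),
                 tolerance = 1e-8)
  }
})

test_that("crossover scan finds the last speed with a contrast effect", {
  # linear front end: no contrast effect anywhere
  expect_true(is.na(ratio_crossover_speed(ratio_identity(2))))
  cross <- ratio_crossover_speed(ratio_params())
  expect_true(is.finite(cross))
  # by direct evaluation just above/below the reported speed
  rp <- ratio_params()
  expect_lt(ratio_output(rp, cross, 0.95, 2), 0.99 * ratio_output(rp, cross, 0.03, 2))
  expect_gt(ratio_output(rp, cross + 0.5, 0.95, 2),
            0.99 * ratio_output(rp, cross + 0.5, 0.03, 2))
})
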