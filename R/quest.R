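# QUEST adaptive staircase for the 2-AFC speed comparison task. The staircase
# maintains a posterior over the candidate PSE on a fixed log-spaced speed
# grid, places each trial at the current posterior mode, and reads out the
# PSE as the mode after a fixed number of trials.

#' QUEST staircase configuration
#'
#' The published design specifies the procedure and the 35-trial termination
#' rule but not the QUEST internals; the defaults here follow common QUEST
#' practice: a wide log-spaced candidate grid, a broad Gaussian starting
#' prior in log10 speed, and a fixed-shape Weibull response kernel.
#'
#' @param grid_lo,grid_hi bounds of the candidate PSE grid in deg/s
#'   (log-spaced).
#' @param grid_n number of grid points.
#' @param prior_mean_guess initial PSE guess in deg/s; `NULL` means "use the
#'   reference speed of the condition being run".
#' @param prior_sd width of the starting prior in log10 units.
#' @param slope_beta assumed psychometric slope (Weibull, log10 units).
#' @param lapse_delta lapse rate in \[0, 0.1).
#' @param guess_gamma response probability when test and candidate PSE are
#'   equal; 0.5 for a 2-AFC comparison.
#' @param n_trials trials per staircase.
#' @return an object of class `quest_config`.
#' @export
quest_config <- function(grid_lo = 0.05, grid_hi = 40, grid_n = 201,
                         prior_mean_guess = NULL, prior_sd = 1.0,
                         slope_beta = 3.5, lapse_delta = 0.01,
                         guess_gamma = 0.5, n_trials = 35) {
  if (grid_lo <= 0 || grid_lo >= grid_hi) stop("need 0 < grid_lo < grid_hi")
  if (lapse_delta < 0 || lapse_delta >= 0.1) stop("lapse_delta must lie in [0, 0.1)")
  if (guess_gamma <= 0 || guess_gamma >= 1) stop("guess_gamma must lie in (0, 1)")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(
    list(grid_lo = grid_lo, grid_hi = grid_hi, grid_n = as.integer(grid_n),
         prior_mean_guess = prior_mean_guess, prior_sd = prior_sd,
         slope_beta = slope_beta, lapse_delta = lapse_delta,
         guess_gamma = guess_gamma, n_trials = as.integer(n_trials)),
    class = "quest_config"
  )
}

#' Initialize a QUEST state
#'
#' @param config a [quest_config()].
#' @param prior_mean_guess initial PSE guess in deg/s, overriding the config.
#' @return an object of class `quest_state` with the log-spaced candidate
#'   grid and the (unnormalized) log posterior.
#' @export
quest_init <- function(config, prior_mean_guess = NULL) {
  stopifnot(inherits(config, "quest_config"))
  guess <- prior_mean_guess %||% config$prior_mean_guess
  if (is.null(guess)) stop("an initial PSE guess is required")
  lg <- seq(log10(config$grid_lo), log10(config$grid_hi),
            length.out = config$grid_n)
  structure(
    list(log10_grid = lg,
         log_posterior = stats::dnorm(lg, log10(guess), config$prior_sd,
                                      log = TRUE)),
    class = "quest_state"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weibull response kernel in log10 speed, anchored so that the probability of
# "test faster" equals guess_gamma exactly when the shown speed equals the
# candidate PSE: psi(d) = delta*gamma + (1 - delta)(1 - (1-gamma)^(10^(beta d))).
# This makes the tracked quantity the 50% point of the comparison, i.e. the
# PSE, rather than a threshold-criterion point.
quest_kernel <- function(d, beta, delta, gamma) {
  core <- 1 - exp(log1p(-gamma) * 10^(beta * d))
  delta * gamma + (1 - delta) * core
}

#' Recommended test speed for the next trial
#'
#' Returns the candidate grid speed at the posterior mode; ties are broken
#' towards the lower speed. Deterministic given the state and invariant to
#' adding a constant to the log posterior.
#'
#' @param state a `quest_state`.
#' @return a speed in deg/s.
#' @export
quest_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  lp <- state$log_posterior
  if (all(!is.finite(lp))) stop("degenerate QUEST posterior (all -Inf)")
  10^state$log10_grid[which.max(lp)]
}

#' Bayesian update of the QUEST posterior after one trial
#'
#' Adds the log of the Weibull response kernel (for a "test faster" response)
#' or of its complement (otherwise), evaluated at the shown speed relative to
#' every candidate PSE. Updates commute over trial order.
#'
#' @param state a `quest_state`.
#' @param shown_speed test speed shown on this trial, deg/s.
#' @param response_test_faster logical response.
#' @param config the [quest_config()] supplying the kernel shape.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, shown_speed, response_test_faster, config) {
  stopifnot(inherits(state, "quest_state"), inherits(config, "quest_config"))
  if (shown_speed < config$grid_lo || shown_speed > config$grid_hi) {
    stop("shown_speed outside the candidate grid")
  }
  d <- log10(shown_speed) - state$log10_grid
  p_yes <- quest_kernel(d, config$slope_beta, config$lapse_delta,
                        config$guess_gamma)
  state$log_posterior <- state$log_posterior +
    log(if (response_test_faster) p_yes else 1 - p_yes)
  state
}

#' Simulate one 2-AFC response of the generative observer
#'
#' Draws one sample from each grating's Gaussian posterior and reports
#' whether the test sample is the larger one.
#'
#' @param observer an [observer_spec()].
#' @param v_ref,c_ref reference grating speed (deg/s) and contrast (fraction).
#' @param v_test,c_test test grating speed and contrast.
#' @param rng_seed optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [run_staircase()]).
#' @return logical: `TRUE` if the test grating was judged faster.
#' @export
simulate_choice <- function(observer, v_ref, c_ref, v_test, c_test,
                            rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  s_ref <- stats::rnorm(1, posterior_mean(observer, v_ref, c_ref),
                        sqrt(posterior_var(observer, v_ref, c_ref)))
  s_test <- stats::rnorm(1, posterior_mean(observer, v_test, c_test),
                         sqrt(posterior_var(observer, v_test, c_test)))
  s_test > s_ref
}

#' Run one QUEST staircase against a simulated observer
#'
#' Runs exactly `config$n_trials` trials: each trial's test speed comes from
#' [quest_recommend()], the response from [simulate_choice()], and the state
#' from [quest_update()]. The PSE is the mode of the final posterior. The
#' reference grating's side is randomized once per staircase (fixed within
#' it) and logged; it does not influence the simulated observer.
#'
#' @param observer an [observer_spec()].
#' @param condition a list or one-row data frame with `condition_id`,
#'   `v_ref`, `c_ref`, `c_test` (contrasts as fractions, `c_ref < c_test`).
#' @param config a [quest_config()].
#' @param rng_seed integer seed making the run reproducible in isolation.
#' @param session,staircase_id identifiers copied into the trial log.
#' @return an object of class `staircase_result`: `pse`, `n_trials`, ids and
#'   the per-trial log (a data frame).
#' @export
run_staircase <- function(observer, condition, config = quest_config(),
                          rng_seed = 1, session = 1L, staircase_id = 1L) {
  stopifnot(inherits(observer, "observer_spec"), inherits(config, "quest_config"))
  cond <- as.list(condition)
  if (cond$c_ref >= cond$c_test) {
    stop("the reference grating must have the lower contrast (c_ref < c_test)")
  }
  set.seed(rng_seed)
  reference_side <- sample(c("left", "right"), 1)
  state <- quest_init(config, prior_mean_guess = cond$v_ref)
  n <- config$n_trials
  v_test <- numeric(n)
  resp <- logical(n)
  for (i in seq_len(n)) {
    v_test[i] <- quest_recommend(state)
    resp[i] <- simulate_choice(observer, cond$v_ref, cond$c_ref,
                               v_test[i], cond$c_test)
    state <- quest_update(state, v_test[i], resp[i], config)
  }
  trials <- data.frame(
    session = as.integer(session),
    condition_id = cond$condition_id,
    staircase_id = as.integer(staircase_id),
    trial_index = seq_len(n),
    v_ref = cond$v_ref, c_ref = cond$c_ref,
    v_test = v_test, c_test = cond$c_test,
    reference_side = reference_side,
    response_test_faster = resp,
    stringsAsFactors = FALSE
  )
  structure(
    list(condition_id = cond$condition_id, session = as.integer(session),
         staircase_id = as.integer(staircase_id),
         pse = quest_recommend(state), n_trials = n, trials = trials),
    class = "staircase_result"
  )
}
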