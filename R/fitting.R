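# Fast model fitting from per-condition PSE means and across-staircase PSE
# variances, the trial-level maximum-likelihood reference fit, the nested
# combined-model (ratio front end + Bayesian) fit, and prior reconstruction.

#' Fitting configuration
#'
#' @param variant `"bayesian"` (no front end) or `"combined"` (ratio-model
#'   front end).
#' @param slope_bounds,g_bounds,q_bounds,c50_bounds box bounds on the free
#'   parameters: 4 local log-prior slopes, 4 likelihood widths g at the
#'   knots, and the contrast-response exponent q and semi-saturation c50.
#' @param n_multistart number of seeded optimizer starts.
#' @param master_seed seed for the start jitter (and any other fitting
#'   randomness).
#' @param variance_weight relative weight of the (log) variance residuals
#'   against the mean-PSE residuals.
#' @param alpha proportionality constant of the PSE-variance relation
#'   `var(PSE) = alpha * (sigma1^2 + sigma2^2) / N`; calibrated value 6.6.
#' @param n_trials N in the PSE-variance relation: trials per staircase.
#' @param knot_speeds knot speeds shared by prior and likelihood models.
#' @param spatial_frequency cycles/deg, used by the ratio front end.
#' @param bracket test-speed bracket for the PSE solve, deg/s.
#' @param outer_grid named list of candidate values for the nested
#'   combined-model search over `s` (shared semi-saturation), `k` (gain) and
#'   `tau_scale` (common scale on the literature time constants
#'   0.0072/0.0043 s).
#' @param outer_refine logical: locally refine the best outer grid point by
#'   Nelder-Mead.
#' @param outer_maxit iteration cap for the outer refinement.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(variant = c("bayesian", "combined"),
                       slope_bounds = c(-2, 0.5),
                       g_bounds = c(0.01, 10),
                       q_bounds = c(0.5, 8),
                       c50_bounds = c(0.005, 0.9),
                       n_multistart = 20,
                       master_seed = 1,
                       variance_weight = 1,
                       alpha = 6.6,
                       n_trials = 35,
                       knot_speeds = c(1, 4, 8, 12),
                       spatial_frequency = 2,
                       bracket = c(0.05, 40),
                       outer_grid = list(s = c(0.25, 0.5, 1),
                                         k = c(0.3, 0.55, 1),
                                         tau_scale = c(2.5, 4.9, 7.5)),
                       outer_refine = TRUE,
                       outer_maxit = 30) {
  variant <- match.arg(variant)
  for (b in list(slope_bounds, g_bounds, q_bounds, c50_bounds, bracket)) {
    if (length(b) != 2 || b[1] >= b[2]) stop("bounds must be ordered pairs")
  }
  if (n_multistart < 1) stop("n_multistart must be >= 1")
  if (alpha <= 0) stop("alpha must be positive")
  structure(
    list(variant = variant, slope_bounds = slope_bounds, g_bounds = g_bounds,
         q_bounds = q_bounds, c50_bounds = c50_bounds,
         n_multistart = as.integer(n_multistart), master_seed = master_seed,
         variance_weight = variance_weight, alpha = alpha,
         n_trials = as.integer(n_trials), knot_speeds = knot_speeds,
         spatial_frequency = spatial_frequency, bracket = bracket,
         outer_grid = outer_grid, outer_refine = outer_refine,
         outer_maxit = as.integer(outer_maxit)),
    class = "fit_config"
  )
}

# pack/unpack the 10 free parameters
params_to_observer <- function(th, config, ratio = NULL) {
  nk <- length(config$knot_speeds)
  observer_spec(
    prior = prior_model(th[seq_len(nk)], config$knot_speeds),
    likelihood = likelihood_model(
      knot_g = th[nk + seq_len(nk)],
      contrast = contrast_response(q = th[2 * nk + 1], c50 = th[2 * nk + 2]),
      knot_speeds = config$knot_speeds
    ),
    ratio = ratio,
    spatial_frequency = config$spatial_frequency
  )
}

observer_to_params <- function(observer) {
  c(observer$prior$knot_slopes, observer$likelihood$knot_g,
    observer$likelihood$contrast$q, observer$likelihood$contrast$c50)
}

param_bounds <- function(config) {
  nk <- length(config$knot_speeds)
  list(
    lower = c(rep(config$slope_bounds[1], nk), rep(config$g_bounds[1], nk),
              config$q_bounds[1], config$c50_bounds[1]),
    upper = c(rep(config$slope_bounds[2], nk), rep(config$g_bounds[2], nk),
              config$q_bounds[2], config$c50_bounds[2])
  )
}

#' Predicted PSE for one condition
#'
#' Solves, for the test speed, the equality of the posterior means of the
#' reference grating (at `v_ref`, `c_ref`) and the test grating (at the
#' unknown speed, `c_test`): the speed at which the two gratings are
#' perceived as equally fast. For the combined variant the posterior means
#' include the ratio-model front end.
#'
#' @param observer an [observer_spec()] (carrying a ratio front end or not).
#' @param condition list or one-row data frame with `v_ref`, `c_ref`,
#'   `c_test`.
#' @param variant `"auto"` uses the observer as given; `"bayesian"` strips
#'   the front end; `"combined"` requires one.
#' @param bracket search interval for the test speed, deg/s.
#' @return the predicted PSE in deg/s.
#' @export
predict_pse <- function(observer, condition,
                        variant = c("auto", "bayesian", "combined"),
                        bracket = c(0.05, 40)) {
  variant <- match.arg(variant)
  if (variant == "bayesian" && !is.null(observer$ratio)) {
    observer$ratio <- NULL
  }
  if (variant == "combined" && is.null(observer$ratio)) {
    stop("combined variant requires an observer with a ratio front end")
  }
  cond <- as.list(condition)
  target <- posterior_mean(observer, cond$v_ref, cond$c_ref)
  f <- function(v2) posterior_mean(observer, v2, cond$c_test) - target
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop(sprintf(
      "no PSE in [%g, %g] for condition v_ref=%g c_ref=%g c_test=%g (non-identifiable)",
      bracket[1], bracket[2], cond$v_ref, cond$c_ref, cond$c_test))
  }
  stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi, tol = 1e-9)$root
}

#' Predicted across-staircase PSE variance for one condition
#'
#' `alpha * (sigma1^2 + sigma2^2) / N`, with `sigma1` the likelihood width at
#' the reference grating and `sigma2` at the predicted PSE and the test
#' contrast; N is the number of trials in one staircase. With the calibrated
#' `alpha = 6.6` and N = 40 this is the classic "(sigma1^2+sigma2^2)/6" rule.
#'
#' @param observer an [observer_spec()].
#' @param condition list or one-row data frame with `v_ref`, `c_ref`,
#'   `c_test`.
#' @param config a [fit_config()] supplying `alpha` and `n_trials`.
#' @param pse optionally, a precomputed predicted PSE.
#' @return predicted variance in (deg/s)^2.
#' @export
predict_pse_var <- function(observer, condition, config = fit_config(),
                            pse = NULL) {
  cond <- as.list(condition)
  if (is.null(pse)) pse <- predict_pse(observer, cond, bracket = config$bracket)
  s1sq <- likelihood_sigma(observer$likelihood, cond$v_ref, cond$c_ref)^2
  s2sq <- likelihood_sigma(observer$likelihood, pse, cond$c_test)^2
  config$alpha * (s1sq + s2sq) / config$n_trials
}

# stacked residual vector: mean-PSE residuals in deg/s, variance residuals
# as differences of log variances (scale-free), weighted.
fast_residuals <- function(th, table, config, ratio = NULL) {
  obs <- params_to_observer(th, config, ratio)
  n <- nrow(table)
  r <- numeric(2 * n)
  for (i in seq_len(n)) {
    cond <- table[i, ]
    pse_hat <- tryCatch(
      predict_pse(obs, cond, bracket = config$bracket),
      error = function(e) NA_real_
    )
    if (!is.finite(pse_hat)) {
      r[i] <- 1e3
      r[n + i] <- 1e3
      next
    }
    var_hat <- predict_pse_var(obs, cond, config, pse = pse_hat)
    r[i] <- table$mean_pse[i] - pse_hat
    r[n + i] <- config$variance_weight *
      (log(max(table$pse_var[i], 1e-8)) - log(var_hat))
  }
  r
}

# seeded multistart around neutral initials, clamped into bounds
make_starts <- function(config) {
  nk <- length(config$knot_speeds)
  neutral <- c(rep(-0.1, nk), rep(1, nk), 2, 0.1)
  b <- param_bounds(config)
  set.seed(config$master_seed)
  starts <- vector("list", config$n_multistart)
  starts[[1]] <- neutral
  if (config$n_multistart > 1) {
    for (j in 2:config$n_multistart) {
      th <- neutral * stats::runif(length(neutral), 0.5, 1.5)
      starts[[j]] <- pmin(pmax(th, b$lower), b$upper)
    }
  }
  starts
}

check_table <- function(table, min_conditions = 0) {
  if (!inherits(table, "pse_table")) {
    stop("input must be a pse_table (see pse_summary / read_pse_table)")
  }
  if (nrow(table) < min_conditions) {
    stop("at least ", min_conditions,
         " conditions are needed for identifiability")
  }
  invisible(table)
}

build_fit_result <- function(th, table, config, ratio, deviance, converged,
                             best_start, extra = list()) {
  obs <- params_to_observer(th, config, ratio)
  n <- nrow(table)
  pred_pse <- vapply(seq_len(n), function(i) {
    predict_pse(obs, table[i, ], bracket = config$bracket)
  }, numeric(1))
  pred_var <- vapply(seq_len(n), function(i) {
    predict_pse_var(obs, table[i, ], config, pse = pred_pse[i])
  }, numeric(1))
  residual_table <- data.frame(
    condition_id = table$condition_id, v_ref = table$v_ref,
    c_ref = table$c_ref, c_test = table$c_test,
    observed_pse = table$mean_pse, predicted_pse = pred_pse,
    observed_var = table$pse_var, predicted_var = pred_var,
    stringsAsFactors = FALSE
  )
  gof <- cdb_gof(table$mean_pse / table$v_ref, pred_pse / table$v_ref)
  out <- list(observer = obs, params = th, ratio = ratio,
              sse = gof$sse, r2 = gof$r2, deviance = deviance,
              residual_table = residual_table, converged = converged,
              best_start = best_start, config = config)
  structure(c(out, extra), class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat("<speed_fit>\n")
  cat(sprintf("  variant   : %s\n",
              if (is.null(x$ratio)) "bayesian" else "combined"))
  cat(sprintf("  CDB fit   : SSE = %.4g, R^2 = %.3f\n", x$sse, x$r2))
  cat(sprintf("  slopes    : %s\n",
              paste(signif(x$observer$prior$knot_slopes, 3), collapse = ", ")))
  cat(sprintf("  g(v)      : %s\n",
              paste(signif(x$observer$likelihood$knot_g, 3), collapse = ", ")))
  cat(sprintf("  h(c)      : q = %.3g, c50 = %.3g\n",
              x$observer$likelihood$contrast$q, x$observer$likelihood$contrast$c50))
  cat(sprintf("  converged : %s (best start %d)\n", x$converged, x$best_start))
  invisible(x)
}

#' Fit the Bayesian observer to a PSE table (fast method)
#'
#' Minimizes the stacked squared residuals of per-condition (observed -
#' predicted) mean PSE and (log observed - log predicted) PSE variance over
#' the 10 free parameters (4 prior slopes, 4 likelihood widths, q, c50),
#' using bounded nonlinear least squares with seeded multistart. This uses
#' only 1/N of the information of the trial-level fit but is much cheaper.
#'
#' @param table a `pse_table` (from [pse_summary()] or [read_pse_table()]).
#' @param config a [fit_config()].
#' @param ratio optional fixed [ratio_params()] front end (used by the
#'   nested combined fit; `NULL` fits the plain Bayesian model).
#' @return a `speed_fit`: fitted observer, parameter vector, CDB-space SSE
#'   and R^2, residual table, convergence diagnostics.
#' @export
fit_model <- function(table, config = fit_config(), ratio = NULL) {
  check_table(table, min_conditions = 10)
  b <- param_bounds(config)
  starts <- make_starts(config)
  best <- NULL
  n_ok <- 0L
  for (j in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[j]], lower = b$lower, upper = b$upper,
        fn = fast_residuals, table = table, config = config, ratio = ratio,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$start_index <- j
    }
  }
  if (is.null(best)) stop("all optimizer starts failed; check the input table")
  build_fit_result(best$par, table, config, ratio,
                   deviance = best$deviance,
                   converged = best$info %in% 1:4,
                   best_start = best$start_index)
}

#' Nested fit of the combined (ratio + Bayesian) model
#'
#' Outer search over the shared ratio-model parameters — semi-saturation
#' `s = s_p = s_m`, gain `k`, and a common scale on the literature time
#' constants (0.0072, 0.0043 s) — with a full [fit_model()] run (the same 10
#' free parameters as the plain Bayesian fit) at each candidate. The ratio
#' parameters are shared across all tables when several subjects' tables are
#' given. A coarse grid is scanned first and the best point is refined by
#' Nelder-Mead.
#'
#' @param table a `pse_table`, or a list of them (one per subject).
#' @param config a [fit_config()]; `outer_grid`, `outer_refine`,
#'   `outer_maxit` control the outer search.
#' @param ratio optional fixed [ratio_params()]: skip the outer search and
#'   fit with this front end (e.g. [ratio_identity()] to check nesting).
#' @return a `speed_fit` (single table) or a list with `$fits` and `$ratio`
#'   (multiple tables); the selected front end is in `$ratio`, the outer
#'   search trace in `$outer`.
#' @export
fit_combined <- function(table, config = fit_config(variant = "combined"),
                         ratio = NULL) {
  tables <- if (inherits(table, "pse_table")) list(table) else table
  lapply(tables, check_table)

  inner <- function(rt) lapply(tables, function(tb) fit_model(tb, config, ratio = rt))
  total_dev <- function(fits) sum(vapply(fits, `[[`, numeric(1), "deviance"))

  if (is.null(ratio)) {
    make_ratio <- function(s, k, tau_scale) {
      ratio_params(tau1 = 0.0072 * tau_scale, tau2 = 0.0043 * tau_scale,
                   k = k, s_p = s, s_m = s)
    }
    grid <- expand.grid(s = config$outer_grid$s, k = config$outer_grid$k,
                        tau_scale = config$outer_grid$tau_scale)
    grid$deviance <- NA_real_
    best_dev <- Inf; best_phi <- NULL
    for (i in seq_len(nrow(grid))) {
      rt <- make_ratio(grid$s[i], grid$k[i], grid$tau_scale[i])
      dev <- tryCatch(total_dev(inner(rt)), error = function(e) Inf)
      grid$deviance[i] <- dev
      if (dev < best_dev) {
        best_dev <- dev
        best_phi <- c(grid$s[i], grid$k[i], grid$tau_scale[i])
      }
    }
    if (!is.finite(best_dev)) stop("combined-model outer search failed everywhere")
    trace <- grid
    if (config$outer_refine) {
      lb <- c(0.1, 0.1, 1); ub <- c(2, 2, 10)
      obj <- function(lphi) {
        phi <- pmin(pmax(exp(lphi), lb), ub)
        tryCatch(total_dev(inner(make_ratio(phi[1], phi[2], phi[3]))),
                 error = function(e) Inf)
      }
      opt <- stats::optim(log(best_phi), obj, method = "Nelder-Mead",
                          control = list(maxit = config$outer_maxit))
      if (is.finite(opt$value) && opt$value < best_dev) {
        best_phi <- pmin(pmax(exp(opt$par), lb), ub)
        best_dev <- opt$value
      }
    }
    ratio <- make_ratio(best_phi[1], best_phi[2], best_phi[3])
    outer <- list(trace = trace, s = best_phi[1], k = best_phi[2],
                  tau_scale = best_phi[3], deviance = best_dev)
  } else {
    outer <- list(fixed = TRUE)
  }

  fits <- inner(ratio)
  for (i in seq_along(fits)) {
    fits[[i]]$outer <- outer
  }
  if (length(fits) == 1) fits[[1]] else
    structure(list(fits = fits, ratio = ratio, outer = outer),
              class = "combined_fit")
}

#' Trial-level maximum-likelihood fit (reference method)
#'
#' Maximizes the Bernoulli log-likelihood of every recorded response under
#' [choice_probability()] over the same 10 free parameters as [fit_model()].
#' This is the reference method the fast PSE-variance fit is compared to:
#' it uses every trial instead of per-condition summaries.
#'
#' @param trials a trial-log data frame (see [trial_log()]) with columns
#'   `v_ref`, `c_ref`, `v_test`, `c_test`, `response_test_faster`.
#' @param config a [fit_config()].
#' @param ratio optional fixed [ratio_params()] front end.
#' @param table optional `pse_table` for the same data; when given, the
#'   residual table and CDB goodness of fit are evaluated against it.
#' @return a `speed_fit` with an extra `logLik` element.
#' @export
fit_full_likelihood <- function(trials, config = fit_config(), ratio = NULL,
                                table = NULL) {
  needed <- c("v_ref", "c_ref", "v_test", "c_test", "response_test_faster")
  if (!all(needed %in% names(trials))) {
    stop("trials must have columns: ", paste(needed, collapse = ", "))
  }
  resp <- as.logical(trials$response_test_faster)
  nll <- function(th) {
    obs <- params_to_observer(th, config, ratio)
    p <- choice_probability(obs, trials$v_ref, trials$c_ref,
                            trials$v_test, trials$c_test)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(log(ifelse(resp, p, 1 - p)))
  }
  b <- param_bounds(config)
  starts <- make_starts(config)
  best <- NULL
  for (j in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[j]], nll, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start_index <- j
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")

  if (is.null(table)) {
    obs <- params_to_observer(best$par, config, ratio)
    return(structure(
      list(observer = obs, params = best$par, ratio = ratio,
           sse = NA_real_, r2 = NA_real_, deviance = NA_real_,
           residual_table = NULL, converged = best$convergence == 0,
           best_start = best$start_index, config = config,
           logLik = -best$value),
      class = "speed_fit"
    ))
  }
  build_fit_result(best$par, table, config, ratio, deviance = NA_real_,
                   converged = best$convergence == 0,
                   best_start = best$start_index,
                   extra = list(logLik = -best$value))
}

#' Reconstruct the (unnormalized) prior from fitted local slopes
#'
#' Cumulative trapezoidal integration of the interpolated slope function over
#' the speed grid: `p(v) = exp(integral of a(v) dv)`, with the density fixed
#' to 1 at the lowest grid point (the integration constant absorbs the
#' prior's intercept).
#'
#' @param prior a [prior_model()] (e.g. `fit$observer$prior`).
#' @param grid increasing positive speed grid in deg/s.
#' @return numeric vector of unnormalized densities over `grid`.
#' @export
reconstruct_prior <- function(prior, grid = seq(0.5, 14, by = 0.05)) {
  if (length(grid) == 0) stop("empty speed grid")
  if (any(grid <= 0) || any(diff(grid) <= 0)) {
    stop("grid must be positive and strictly increasing")
  }
  # integrate on the union of the requested grid and the slope knots: the
  # integrand is piecewise linear, so trapezoidal integration on a grid
  # containing its kinks is exact
  knots <- prior$knot_speeds
  full <- sort(unique(c(grid, knots[knots > min(grid) & knots < max(grid)])))
  a <- slope_at(prior, full)
  logp <- as.vector(pracma::cumtrapz(full, a))
  dens <- exp(logp - logp[1])
  dens[match(grid, full)]
}

#' Calibrate the PSE-variance proportionality constant by simulation
#'
#' The constant `alpha` in `var(PSE) = alpha * (sigma1^2 + sigma2^2) / N`
#' depends on the staircase procedure (kernel shape, grid, trial count), so
#' it is calibrated against data whose generating observer is known: the
#' per-condition ratio of the observed across-staircase PSE variance to
#' `(sigma1^2 + sigma2^2) / N` under the true observer. The published value
#' (6.6) was calibrated the same way against an independent human dataset;
#' for synthetic data the calibration uses the simulated staircases
#' themselves.
#'
#' @param dataset a `speed_dataset` (carries its ground-truth observer), or
#'   a `pse_table` if `observer` is given.
#' @param observer the generating [observer_spec()] (defaults to the
#'   dataset's).
#' @param n_trials trials per staircase (defaults to the dataset design's).
#' @return the median per-condition ratio: the calibrated `alpha`.
#' @export
calibrate_alpha <- function(dataset, observer = NULL, n_trials = NULL) {
  if (inherits(dataset, "speed_dataset")) {
    observer <- observer %||% dataset$observer
    n_trials <- n_trials %||% dataset$design$trials_per_staircase
    table <- pse_summary(dataset)
  } else {
    table <- dataset
    if (is.null(observer) || is.null(n_trials)) {
      stop("observer and n_trials are required when passing a pse_table")
    }
  }
  ratios <- vapply(seq_len(nrow(table)), function(i) {
    cond <- table[i, ]
    pse <- predict_pse(observer, cond)
    s12 <- likelihood_sigma(observer$likelihood, cond$v_ref, cond$c_ref)^2 +
      likelihood_sigma(observer$likelihood, pse, cond$c_test)^2
    table$pse_var[i] / (s12 / n_trials)
  }, numeric(1))
  stats::median(ratios)
}

cdb_gof <- function(observed_cdb, predicted_cdb) {
  sse <- sum((observed_cdb - predicted_cdb)^2)
  tss <- sum((observed_cdb - mean(observed_cdb))^2)
  list(sse = sse, r2 = 1 - sse / tss)
}

#' Goodness of fit in contrast-dependent-bias space
#'
#' Residuals are taken on the dimensionless CDB ratio (PSE / reference
#' speed) per condition; `r2 = 1 - SSE / total sum of squares` about the
#' observed mean CDB.
#'
#' @param fit a `speed_fit` (or an [observer_spec()]).
#' @param table the `pse_table` the fit is evaluated against.
#' @return a list with `sse` and `r2`.
#' @export
goodness_of_fit <- function(fit, table) {
  check_table(table)
  observer <- if (inherits(fit, "speed_fit")) fit$observer else fit
  stopifnot(inherits(observer, "observer_spec"))
  pred <- vapply(seq_len(nrow(table)), function(i) {
    predict_pse(observer, table[i, ])
  }, numeric(1))
  cdb_gof(table$mean_pse / table$v_ref, pred / table$v_ref)
}
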