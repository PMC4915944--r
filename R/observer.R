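# Bayesian ideal observer for speed perception: semi-parametric slow-speed
# prior (local log-prior slopes at knot speeds), separable likelihood width
# sigma(v, c) = g(v) h(c), and Gaussian posterior over perceived speed.

#' Semi-parametric slow-speed prior
#'
#' The prior over speed is locally log-linear, `p(v) ~ exp(a(v) * v)`, with the
#' local log-slope `a(v)` specified at a small set of knot speeds and linearly
#' interpolated in between. Outside the knot range the slope is held constant
#' at the nearest knot value (the extracted slope profiles flatten at the
#' extremes, and staircases routinely visit test speeds outside the knot
#' range). Negative slopes encode a preference for slow speeds; the prior's
#' intercept is not represented here — it is absorbed into the normalization
#' convention of [reconstruct_prior()].
#'
#' @param knot_slopes numeric vector of local log-prior slopes, one per knot,
#'   in 1/(deg/s). Negative values bias perceived speed downward.
#' @param knot_speeds strictly increasing positive knot speeds in deg/s.
#'   Defaults to the four reference speeds of the standard design.
#' @return an object of class `prior_model`.
#' @seealso [slope_at()], [reconstruct_prior()]
#' @export
#' @examples
#' pr <- prior_model(c(-0.3, -0.15, -0.08, -0.05))
#' slope_at(pr, c(1, 2.5, 20))
prior_model <- function(knot_slopes, knot_speeds = c(1, 4, 8, 12)) {
  stopifnot(is.numeric(knot_speeds), is.numeric(knot_slopes))
  if (any(knot_speeds <= 0)) stop("knot_speeds must be positive")
  if (any(diff(knot_speeds) <= 0)) stop("knot_speeds must be strictly increasing")
  if (length(knot_slopes) != length(knot_speeds)) {
    stop("need one slope per knot speed")
  }
  structure(
    list(knot_speeds = as.numeric(knot_speeds),
         knot_slopes = as.numeric(knot_slopes)),
    class = "prior_model"
  )
}

#' Local log-prior slope at arbitrary speeds
#'
#' Piecewise-linear interpolation of the knot slopes; constant extrapolation
#' (clamped to the nearest knot) outside the knot range.
#'
#' @param prior a [prior_model()].
#' @param v speeds in deg/s (vectorized); must be positive.
#' @return slopes in 1/(deg/s), same length as `v`.
#' @export
slope_at <- function(prior, v) {
  stopifnot(inherits(prior, "prior_model"))
  if (any(v <= 0)) stop("speed must be positive")
  stats::approx(prior$knot_speeds, prior$knot_slopes, xout = v, rule = 2)$y
}

#' Contrast response parameters of the likelihood width
#'
#' The contrast dependence of the likelihood width follows the reciprocal of a
#' hyperbolic-ratio (Naka-Rushton) contrast response:
#' `h(c) = 1 / (r_max * c^q / (c^q + c50^q) + r_base)`.
#' High contrast drives the response towards `r_max + r_base`, so the width
#' multiplier falls from `1/r_base` at zero contrast to
#' `1/(r_max + r_base)` at saturation. `r_max` and `r_base` are fixed at
#' 1 and 0.2 by convention, leaving the exponent `q` and semi-saturation
#' contrast `c50` as the two free parameters.
#'
#' @param q response exponent, dimensionless, > 0.
#' @param c50 semi-saturation contrast as a fraction in (0, 1).
#' @param r_max,r_base maximum and baseline response rates; fixed by convention.
#' @return an object of class `contrast_response`.
#' @export
contrast_response <- function(q, c50, r_max = 1, r_base = 0.2) {
  stopifnot(length(q) == 1, length(c50) == 1)
  if (q <= 0) stop("q must be > 0")
  if (c50 <= 0 || c50 >= 1) stop("c50 must lie in (0, 1)")
  if (r_max <= 0 || r_base <= 0) stop("r_max and r_base must be positive")
  structure(list(q = q, c50 = c50, r_max = r_max, r_base = r_base),
            class = "contrast_response")
}

#' Contrast gain h(c) of the likelihood width
#'
#' @param cr a [contrast_response()].
#' @param c Michelson contrast as a fraction in \[0, 1\] (vectorized).
#' @return gain values; strictly decreasing in `c`, bounded in
#'   `(1/(r_max + r_base), 1/r_base]`.
#' @export
contrast_gain <- function(cr, c) {
  stopifnot(inherits(cr, "contrast_response"))
  if (any(c < 0)) stop("contrast must be non-negative")
  resp <- cr$r_max * c^cr$q / (c^cr$q + cr$c50^cr$q) + cr$r_base
  resp[c == 0] <- cr$r_base  # 0^q/0^q guard
  1 / resp
}

#' Likelihood width model sigma(v, c) = g(v) h(c)
#'
#' The sensory measurement of speed is Gaussian around the (possibly
#' transformed) stimulus speed with standard deviation separable into a
#' speed factor `g(v)` — knot values interpolated with the same rule as the
#' prior slopes — and the contrast gain `h(c)`.
#'
#' @param knot_g positive width values `g(v)` in deg/s at the knot speeds.
#' @param contrast a [contrast_response()].
#' @param knot_speeds as in [prior_model()].
#' @return an object of class `likelihood_model`.
#' @export
likelihood_model <- function(knot_g, contrast, knot_speeds = c(1, 4, 8, 12)) {
  stopifnot(inherits(contrast, "contrast_response"))
  if (any(knot_g <= 0)) stop("knot_g must be strictly positive")
  if (length(knot_g) != length(knot_speeds)) stop("need one g per knot speed")
  if (any(knot_speeds <= 0) || any(diff(knot_speeds) <= 0)) {
    stop("knot_speeds must be positive and strictly increasing")
  }
  structure(
    list(knot_speeds = as.numeric(knot_speeds), knot_g = as.numeric(knot_g),
         contrast = contrast),
    class = "likelihood_model"
  )
}

#' Likelihood width at given speed and contrast
#'
#' @param lik a [likelihood_model()].
#' @param v speeds in deg/s, positive (vectorized).
#' @param c contrasts as fractions (vectorized, recycled against `v`).
#' @return widths in deg/s.
#' @export
likelihood_sigma <- function(lik, v, c) {
  stopifnot(inherits(lik, "likelihood_model"))
  if (any(v <= 0)) stop("speed must be positive")
  g <- stats::approx(lik$knot_speeds, lik$knot_g, xout = v, rule = 2)$y
  g * contrast_gain(lik$contrast, c)
}

#' Temporal-filter ratio model parameters
#'
#' Front-end nonlinearity in which perceived speed is the ratio of a
#' contrast-saturating band-pass to a contrast-saturating low-pass temporal
#' filter. The filters operate on temporal frequency `w = v * sf` (Hz):
#' `pbar(w) = sqrt(a^2 + b^2)` with `a = ((2*pi*w*tau1)^2 + 1)^(-9/2)`,
#' `b = ((2*pi*w*tau2)^2 + 1)^(-5)`, and `mbar(w) = k * w * pbar(w)`.
#' Contrast saturation gives `p = pbar*c / (pbar*c + s_p)` and
#' `m = mbar*c / (mbar*c + s_m)`; the output is `m / p`, which tends to
#' `k * w` when the filters are far from saturation and produces a mild
#' decrease of perceived speed with contrast at low speeds.
#'
#' @param tau1,tau2 filter time constants in seconds.
#' @param k dimensionless gain; `k = 1/sf` makes the unsaturated output
#'   veridical.
#' @param s_p,s_m semi-saturation constants of the low-pass and band-pass
#'   stages. `Inf` is accepted and yields the saturation-free limit `k * w`
#'   exactly (used as the identity front end when `k = 1/sf`).
#' @return an object of class `ratio_params`.
#' @export
ratio_params <- function(tau1 = 0.0353, tau2 = 0.0211, k = 0.55,
                         s_p = 0.5, s_m = 0.5) {
  vals <- c(tau1 = tau1, tau2 = tau2, k = k, s_p = s_p, s_m = s_m)
  if (any(vals <= 0)) stop("all ratio-model parameters must be strictly positive")
  structure(as.list(vals), class = "ratio_params")
}

#' Identity ratio front end
#'
#' A [ratio_params()] whose output equals the stimulus speed exactly at every
#' contrast (saturation-free limit with gain `1/sf`). Useful for checking that
#' the combined model nests the plain Bayesian model.
#'
#' @param sf spatial frequency in cycles/deg.
#' @export
ratio_identity <- function(sf = 2) {
  ratio_params(k = 1 / sf, s_p = Inf, s_m = Inf)
}

#' Ratio-model output (perceived speed before Bayesian inference)
#'
#' @param params a [ratio_params()].
#' @param v stimulus speeds in deg/s (vectorized).
#' @param c contrast fraction in (0, 1\] (vectorized, recycled).
#' @param sf spatial frequency in cycles/deg; temporal frequency is `v * sf`.
#' @return perceived speeds in deg/s.
#' @export
ratio_output <- function(params, v, c, sf = 2) {
  stopifnot(inherits(params, "ratio_params"))
  if (any(v <= 0)) stop("speed must be positive")
  if (any(c <= 0)) stop("ratio model is undefined at zero contrast")
  if (sf <= 0) stop("spatial frequency must be positive")
  w <- v * sf
  a <- ((2 * pi * w * params$tau1)^2 + 1)^(-9 / 2)
  b <- ((2 * pi * w * params$tau2)^2 + 1)^(-10 / 2)
  pbar <- sqrt(a^2 + b^2)
  mbar <- params$k * w * pbar
  # m/p written via terms divided by s so that s = Inf gives k*w exactly
  num <- mbar * (pbar * c / params$s_p + 1)
  den <- pbar * (mbar * c / params$s_m + 1)
  num / den
}

#' Largest speed with a contrast effect larger than a tolerance
#'
#' Scans a speed grid and returns the largest speed at which the ratio-model
#' output at the higher contrast falls below its output at the lower contrast
#' by more than `rel_tol` (relatively). Above this speed the front end is
#' contrast-invariant to within the tolerance; below it, raising contrast
#' lowers the output (the model's low-speed regime).
#'
#' @param params a [ratio_params()].
#' @param sf spatial frequency in cycles/deg.
#' @param contrasts length-2 vector `c(low, high)` of contrast fractions.
#' @param rel_tol relative tolerance defining "falls below".
#' @param grid speed grid in deg/s to scan.
#' @return the largest grid speed with `output(high) < (1 - rel_tol) *
#'   output(low)`, or `NA` if there is none.
#' @export
ratio_crossover_speed <- function(params, sf = 2, contrasts = c(0.03, 0.95),
                                  rel_tol = 0.01,
                                  grid = seq(0.1, 12, by = 0.01)) {
  stopifnot(length(contrasts) == 2, contrasts[1] < contrasts[2])
  lo <- ratio_output(params, grid, contrasts[1], sf)
  hi <- ratio_output(params, grid, contrasts[2], sf)
  idx <- which(hi < (1 - rel_tol) * lo)
  if (length(idx) == 0) return(NA_real_)
  max(grid[idx])
}

#' Full generative observer specification
#'
#' Bundles the prior, the likelihood model, an optional ratio-model front end
#' and the stimulus spatial frequency into the generative model of one
#' subject. Perceived speed is the mode (= mean) of the Gaussian posterior:
#' `E = f(v, c) + a(v) * sigma^2(v, c)`, where `f` is the stimulus speed
#' itself for the plain Bayesian observer or the ratio-model output when a
#' front end is present; `Var = sigma^2(v, c)`.
#'
#' @param prior a [prior_model()].
#' @param likelihood a [likelihood_model()].
#' @param ratio a [ratio_params()] or `NULL` for the plain Bayesian observer.
#' @param spatial_frequency grating spatial frequency in cycles/deg.
#' @return an object of class `observer_spec`.
#' @export
observer_spec <- function(prior, likelihood, ratio = NULL,
                          spatial_frequency = 2) {
  stopifnot(inherits(prior, "prior_model"),
            inherits(likelihood, "likelihood_model"))
  if (!is.null(ratio)) stopifnot(inherits(ratio, "ratio_params"))
  if (spatial_frequency <= 0) stop("spatial_frequency must be positive")
  structure(
    list(prior = prior, likelihood = likelihood, ratio = ratio,
         spatial_frequency = spatial_frequency),
    class = "observer_spec"
  )
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("<observer_spec>\n")
  cat("  knots (deg/s):", paste(x$prior$knot_speeds, collapse = ", "), "\n")
  cat("  prior slopes :", paste(signif(x$prior$knot_slopes, 3), collapse = ", "), "\n")
  cat("  g(v)         :", paste(signif(x$likelihood$knot_g, 3), collapse = ", "), "\n")
  cat(sprintf("  h(c)         : q = %.3g, c50 = %.3g\n",
              x$likelihood$contrast$q, x$likelihood$contrast$c50))
  cat(sprintf("  front end    : %s\n",
              if (is.null(x$ratio)) "none (plain Bayesian)" else
                sprintf("ratio model (tau1 = %.4g, tau2 = %.4g, k = %.3g, s_p = %.3g, s_m = %.3g)",
                        x$ratio$tau1, x$ratio$tau2, x$ratio$k, x$ratio$s_p, x$ratio$s_m)))
  cat(sprintf("  spatial freq : %g cycles/deg\n", x$spatial_frequency))
  invisible(x)
}

#' Posterior mean of perceived speed
#'
#' @param observer an [observer_spec()].
#' @param v stimulus speeds in deg/s (vectorized).
#' @param c contrast fractions in (0, 1\] (vectorized, recycled).
#' @return expected perceived speeds in deg/s.
#' @export
posterior_mean <- function(observer, v, c) {
  stopifnot(inherits(observer, "observer_spec"))
  f <- if (is.null(observer$ratio)) v else {
    ratio_output(observer$ratio, v, c, observer$spatial_frequency)
  }
  s2 <- likelihood_sigma(observer$likelihood, v, c)^2
  f + slope_at(observer$prior, v) * s2
}

#' Posterior variance of perceived speed
#'
#' Equals the squared likelihood width; the prior contributes bias to the
#' mean but, to first order in the local log-linear approximation, does not
#' narrow the posterior.
#'
#' @inheritParams posterior_mean
#' @return variances in (deg/s)^2.
#' @export
posterior_var <- function(observer, v, c) {
  stopifnot(inherits(observer, "observer_spec"))
  likelihood_sigma(observer$likelihood, v, c)^2
}

#' Probability of judging stimulus 2 faster than stimulus 1
#'
#' The observer draws one sample from each stimulus's Gaussian posterior and
#' chooses the larger. The probability that the sample for stimulus 2 exceeds
#' that for stimulus 1 is the standard normal CDF of
#' `(E2 - E1) / sqrt(Var1 + Var2)`.
#'
#' @param observer an [observer_spec()].
#' @param v1,c1 speed and contrast of stimulus 1 (vectorized).
#' @param v2,c2 speed and contrast of stimulus 2 (vectorized).
#' @return probabilities in (0, 1).
#' @export
choice_probability <- function(observer, v1, c1, v2, c2) {
  e1 <- posterior_mean(observer, v1, c1)
  e2 <- posterior_mean(observer, v2, c2)
  s2 <- posterior_var(observer, v1, c1) + posterior_var(observer, v2, c2)
  stats::pnorm((e2 - e1) / sqrt(s2))
}

#' Default synthetic observer
#'
#' The reference generative observer used throughout the synthetic
#' experiments: a slow-speed prior whose log-slope magnitude decays with
#' speed (-0.3, -0.15, -0.08, -0.05 at 1, 4, 8, 12 deg/s), likelihood widths
#' that grow with speed (g = 0.2, 0.5, 0.9, 1.4 deg/s), and a contrast
#' response with q = 2, c50 = 0.1. These magnitudes produce
#' contrast-dependent biases in the 0.85-0.97 range and low-contrast
#' high-speed widths of a few deg/s, typical of speed-matching data.
#'
#' @param ratio optional [ratio_params()] front end.
#' @param spatial_frequency cycles/deg.
#' @export
default_observer <- function(ratio = NULL, spatial_frequency = 2) {
  observer_spec(
    prior = prior_model(c(-0.3, -0.15, -0.08, -0.05)),
    likelihood = likelihood_model(
      knot_g = c(0.2, 0.5, 0.9, 1.4),
      contrast = contrast_response(q = 2, c50 = 0.1)
    ),
    ratio = ratio,
    spatial_frequency = spatial_frequency
  )
}
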