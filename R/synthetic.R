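# Seeded synthetic-data generators.
#
# Each generator produces an input with exactly the structure the matching
# fit assumes: the noiseless part comes from the package's own forward
# models, noise is additive Gaussian (no noise model is implied by the data
# the generators emulate; Gaussian is the least-assumption default), and a
# seed makes the output reproducible without disturbing the caller's RNG
# state. Zero-noise generation composed with the matching fit is the
# identity on parameters.

#' Synthetic Fe2+ depletion series
#'
#' Noiseless trajectory from [simulate_growth()] plus Gaussian noise on the
#' concentration, clipped to `[0, p0]`.
#'
#' @param params A [growth_params()] object.
#' @param times Ordered, non-negative sampling times.
#' @param sd Noise standard deviation (g/L), >= 0.
#' @param seed Optional integer seed; the same seed gives identical output.
#' @return A `growth_series` data frame (see [simulate_growth()]); `p`
#'   carries the noise, `eta`/`cl_over_y` are recomputed from the noisy `p`.
#' @examples
#' pars <- growth_params(0.0497, 0.328, 1.0838)
#' gen_growth_series(pars, seq(0, 100, 5), sd = 0.05, seed = 1)
#' @export
gen_growth_series <- function(params, times, sd = 0, seed = NULL) {
  check_number(sd, "sd", lower = 0)
  out <- simulate_growth(params, times)
  if (sd > 0) {
    noise <- local_seed(seed, stats::rnorm(nrow(out), 0, sd))
    out$p <- pmin(pmax(out$p + noise, 0), params$p0)
    out$cl_over_y <- params$cl0_over_y + (params$p0 - out$p)
    out$eta <- 100 * (params$p0 - out$p) / params$p0
    if (!is.null(params$Y)) out$cl <- params$Y * out$cl_over_y
  }
  out
}

#' Synthetic conversion-time series
#'
#' Times from the integrated shrinking-core law [sc_time()] plus Gaussian
#' noise. Draws that break the strict monotonicity of `t` along `x` are
#' resampled (up to 100 attempts).
#'
#' @param coeffs [sc_coefficients()] with `t(x)` increasing on the grid.
#' @param x Conversion grid in `(0, 1)`, strictly increasing.
#' @param sd Noise standard deviation on `t`, >= 0.
#' @param seed Optional integer seed.
#' @return A data frame of class `conversion_series` with columns `t`, `x`.
#' @examples
#' gen_conversion_series(sc_coefficients(10, 40, 5),
#'                       seq(0.05, 0.95, 0.05), sd = 0.1, seed = 1)
#' @export
gen_conversion_series <- function(coeffs, x, sd = 0, seed = NULL) {
  check_number(sd, "sd", lower = 0)
  x <- as.numeric(x)
  if (is.unsorted(x, strictly = TRUE) || any(x <= 0) || any(x >= 1))
    stop_domain("`x` must be strictly increasing within (0, 1)")
  base <- sc_time(coeffs, x)
  if (any(diff(base) <= 0))
    stop_domain("t(x) is not increasing on this grid for these coefficients")
  t_obs <- local_seed(seed, {
    ok <- FALSE
    for (attempt in 1:100) {
      cand <- base + if (sd > 0) stats::rnorm(length(x), 0, sd) else 0
      if (all(diff(cand) > 0) && cand[1] >= 0) { ok <- TRUE; break }
    }
    if (!ok)
      stop_domain("could not draw a monotone series in 100 attempts; reduce sd")
    cand
  })
  out <- data.frame(t = t_obs, x = x)
  class(out) <- c("conversion_series", "data.frame")
  out
}

#' Synthetic thermogravimetric conversion curve
#'
#' Conversion solving the chosen linearized rate law exactly at each grid
#' temperature, with optional Gaussian noise on the transformed ordinate,
#' then mapped back and clipped to the open interval (0, 1).
#'
#' @param E Activation energy (J/mol), > 0.
#' @param A_pre Pre-exponential factor, > 0.
#' @param temperatures Increasing absolute-temperature grid (K).
#' @param alpha Heating rate (K per time unit), default 10.
#' @param sd Ordinate noise standard deviation, >= 0.
#' @param seed Optional integer seed.
#' @param convention `"direct"` (default) or `"coats-redfern"` — see
#'   [fit_activation_energy()].
#' @return A data frame with columns `temperature`, `x`.
#' @examples
#' gen_tg_conversion(E = 20000, A_pre = 1e3,
#'                   temperatures = seq(450, 700, 10))
#' @export
gen_tg_conversion <- function(E, A_pre, temperatures, alpha = 10, sd = 0,
                              seed = NULL,
                              convention = c("direct", "coats-redfern")) {
  convention <- match.arg(convention)
  check_number(E, "E", lower = 0, strict_lower = TRUE)
  check_number(A_pre, "A_pre", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(sd, "sd", lower = 0)
  Tk <- as.numeric(temperatures)
  if (is.unsorted(Tk, strictly = TRUE) || any(Tk <= 0))
    stop_domain("`temperatures` must be strictly increasing and positive")
  y <- if (convention == "direct") {
    log(A_pre * E / (alpha * .R_GAS)) - .CR_INTERCEPT_SHIFT -
      .CR_SLOPE_FACTOR * E / Tk
  } else {
    log(A_pre * .R_GAS / (alpha * E)) - E / (.R_GAS * Tk) + 2 * log(Tk)
  }
  if (sd > 0) y <- y + local_seed(seed, stats::rnorm(length(Tk), 0, sd))
  x <- 1 - exp(-exp(y))
  eps <- 1e-12
  data.frame(temperature = Tk, x = pmin(pmax(x, eps), 1 - eps))
}

#' Synthetic L16 response table
#'
#' Responses from an additive factor-effect model on the L16(4^4) array:
#' `response(run) = grand_mean + sum over factors of effect[level] + noise`.
#' Balance of the design is preserved by construction.
#'
#' @param grand_mean Baseline response (per cent).
#' @param effects Named list `A`-`D` of per-level effect vectors (length 4
#'   each, per cent); missing factors default to zero effect.
#' @param sd Gaussian noise standard deviation, >= 0.
#' @param seed Optional integer seed.
#' @return An `l16_design` with all 16 responses set.
#' @examples
#' gen_design_responses(55, list(A = c(-6, 0, 9, -2)), sd = 1, seed = 3)
#' @export
gen_design_responses <- function(grand_mean, effects = list(), sd = 0,
                                 seed = NULL) {
  check_number(grand_mean, "grand_mean")
  check_number(sd, "sd", lower = 0)
  eff <- list(A = numeric(4), B = numeric(4), C = numeric(4), D = numeric(4))
  for (f in names(effects)) {
    if (!f %in% names(eff))
      stop_domain("unknown factor `%s` in `effects`", f)
    if (length(effects[[f]]) != 4L || any(!is.finite(effects[[f]])))
      stop_domain("effects for factor %s must be 4 finite values", f)
    eff[[f]] <- as.numeric(effects[[f]])
  }
  y <- grand_mean +
    eff$A[.l16_layout[, "A"]] + eff$B[.l16_layout[, "B"]] +
    eff$C[.l16_layout[, "C"]] + eff$D[.l16_layout[, "D"]]
  if (sd > 0) y <- y + local_seed(seed, stats::rnorm(16L, 0, sd))
  if (any(y < 0))
    stop_domain("generated responses fall below 0; raise grand_mean or shrink effects/sd")
  l16_design(responses = y)
}
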