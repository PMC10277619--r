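# Monod-type growth of the iron-oxidizing bacterium on Fe2+.
#
# Model: biomass grows at specific rate u_m * p / (K + p) on the limiting
# substrate p (Fe2+, g/L), with a constant yield Y linking biomass to
# substrate consumed:  C_l = C_l0 + Y * (p0 - p).  Eliminating C_l gives a
# single autonomous ODE for the substrate,
#
#   dp/dt = -u_m * p * (C_l0/Y + p0 - p) / (K + p),
#
# whose dynamics depend on (u_m, K, C_l0/Y, p0) only: absolute biomass and Y
# are not identifiable from substrate data alone, so the ratio C_l0/Y is the
# fitted quantity. The time unit is whatever the input series uses; the
# rate constant u_m is per that same unit.

#' Growth-model parameters
#'
#' @param u_m Maximum specific growth rate (1/time), >= 0.
#' @param K Half-saturation (growth kinetic) parameter (g/L), > 0.
#' @param cl0_over_y Ratio of initial microbial concentration to yield
#'   coefficient, `C_l0 / Y` (g/L), >= 0. Only this ratio enters the
#'   substrate dynamics.
#' @param p0 Initial Fe2+ concentration (g/L), > 0. Defaults to the Fe2+
#'   content of 9 K medium, `fe2_from_heptahydrate(44.2)` = 8.88 g/L.
#' @param Y Optional yield coefficient (biomass per g Fe2+), > 0; supply it
#'   (with `cl0`) only when absolute biomass output is wanted.
#' @param cl0 Optional initial microbial concentration; must satisfy
#'   `cl0 / Y == cl0_over_y` when both are given.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(u_m = 0.0497, K = 0.328, cl0_over_y = 1.0838)
#' @export
growth_params <- function(u_m, K, cl0_over_y,
                          p0 = fe2_from_heptahydrate(44.2),
                          Y = NULL, cl0 = NULL) {
  check_number(u_m, "u_m", lower = 0)
  check_number(K, "K", lower = 0, strict_lower = TRUE)
  check_number(cl0_over_y, "cl0_over_y", lower = 0)
  check_number(p0, "p0", lower = 0, strict_lower = TRUE)
  if (!is.null(Y)) {
    check_number(Y, "Y", lower = 0, strict_lower = TRUE)
    if (!is.null(cl0) && abs(cl0 / Y - cl0_over_y) > 1e-8 * (1 + cl0_over_y))
      stop_domain("cl0 / Y = %g contradicts cl0_over_y = %g",
                  cl0 / Y, cl0_over_y)
    if (is.null(cl0)) cl0 <- cl0_over_y * Y
  }
  structure(list(u_m = u_m, K = K, cl0_over_y = cl0_over_y, p0 = p0,
                 Y = Y, cl0 = cl0),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Monod growth parameters: u_m = %g /time, K = %g g/L, C_l0/Y = %g g/L, p0 = %g g/L\n",
    x$u_m, x$K, x$cl0_over_y, x$p0))
  if (!is.null(x$Y))
    cat(sprintf("  absolute scale: Y = %g, C_l0 = %g\n", x$Y, x$cl0))
  invisible(x)
}

#' Substrate consumption rate
#'
#' Right-hand side of the substrate ODE:
#' `dp/dt = -u_m * p * (C_l0/Y + p0 - p) / (K + p)`, always <= 0.
#'
#' @param p Fe2+ concentration (g/L), in `[0, p0]`; may be a vector.
#' @param params A [growth_params()] object.
#' @return dp/dt (g/L per time unit).
#' @export
growth_rate <- function(p, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > params$p0 * (1 + 1e-12)))
    stop_domain("`p` must lie in [0, p0]")
  -params$u_m * p * (params$cl0_over_y + params$p0 - p) / (params$K + p)
}

#' Simulate the growth / Fe2+-depletion trajectory
#'
#' Integrates the substrate ODE from `p(0) = p0` and reconstructs the
#' biomass from the yield balance.
#'
#' @param params A [growth_params()] object.
#' @param times Ordered, non-negative output times.
#' @param rtol,atol Solver tolerances (deSolve::lsoda).
#' @return A data frame of class `growth_series` with columns `time`, `p`
#'   (Fe2+ g/L), `cl_over_y` (`C_l/Y`, g/L), `eta` (Fe2+ conversion, %), and
#'   `cl` when the absolute scale is known. The parameters ride along in the
#'   `"params"` attribute.
#' @examples
#' pars <- growth_params(0.0497, 0.328, 1.0838)
#' head(simulate_growth(pars, 0:10))
#' @export
simulate_growth <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "growth_params"))
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = FALSE) ||
      times[1] < 0)
    stop_domain("`times` must be ordered and non-negative")
  grid <- unique(c(0, times))
  rhs <- function(t, y, parms) {
    p <- min(max(y[1], 0), params$p0)
    list(-params$u_m * p * (params$cl0_over_y + params$p0 - p) /
           (params$K + p))
  }
  sol <- deSolve::lsoda(c(p = params$p0), grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_domain("substrate ODE integration failed (lsoda istate %d)",
                attr(sol, "istate")[1])
  p <- pmin(pmax(sol[match(times, grid), "p"], 0), params$p0)
  out <- data.frame(
    time = times,
    p = p,
    cl_over_y = params$cl0_over_y + (params$p0 - p),
    eta = 100 * (params$p0 - p) / params$p0
  )
  if (!is.null(params$Y)) out$cl <- params$Y * out$cl_over_y
  attr(out, "params") <- params
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Time to reach a target Fe2+ concentration
#'
#' Inverts the trajectory by adaptive quadrature of the separated ODE:
#' `t(p*) = integral from p* to p0 of (K + p) / (u_m p (C_l0/Y + p0 - p)) dp`.
#'
#' @param params A [growth_params()] object with `u_m > 0`.
#' @param p_target Target concentration (g/L), in `(0, p0]`.
#' @return Time at which the trajectory crosses `p_target`.
#' @examples
#' pars <- growth_params(0.0497, 0.328, 1.0838)
#' time_to_concentration(pars, pars$p0 / 2)
#' @export
time_to_concentration <- function(params, p_target) {
  stopifnot(inherits(params, "growth_params"))
  if (params$u_m <= 0)
    stop_domain("u_m = 0: the substrate never moves, target unreachable")
  if (!is.finite(p_target) || p_target <= 0)
    stop_domain("p_target must be > 0 (time diverges as p -> 0)")
  if (p_target > params$p0 * (1 + 1e-12))
    stop_domain("p_target exceeds p0")
  if (p_target >= params$p0) return(0)
  integrand <- function(p)
    (params$K + p) /
    (params$u_m * p * (params$cl0_over_y + params$p0 - p))
  stats::integrate(integrand, p_target, params$p0,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

#' Fit the growth model to an Fe2+ depletion series
#'
#' Least-squares estimation of `(u_m, K, C_l0/Y)` from observed `(t, p)`
#' pairs by Levenberg-Marquardt on the simulated trajectory, with a coarse
#' multi-start grid as fallback when the supplied starting point stalls.
#'
#' @param times Observation times (>= 6 points).
#' @param p Observed Fe2+ concentrations (g/L), in `[0, p0]` (exhausted
#'   samples may read 0).
#' @param p0 Initial Fe2+ concentration (g/L); default 9 K medium content.
#' @param init Optional [growth_params()] starting point.
#' @return A list of class `growth_fit`: `params` (fitted
#'   [growth_params()]), `rss`, `converged`, `degenerate` (TRUE when the
#'   series carries no depletion signal and `u_m` sits at the zero
#'   boundary), `fitted` (model curve at `times`), `residuals`.
#' @examples
#' pars <- growth_params(0.0497, 0.328, 1.0838)
#' obs <- simulate_growth(pars, seq(0, 100, length.out = 20))
#' fit_growth(obs$time, obs$p)$params
#' @export
fit_growth <- function(times, p, p0 = fe2_from_heptahydrate(44.2),
                       init = NULL) {
  times <- as.numeric(times); p <- as.numeric(p)
  if (length(times) != length(p) || length(times) < 6L)
    stop_domain("need >= 6 paired (time, p) observations")
  if (any(!is.finite(p)) || any(p < 0) || any(p > p0 * (1 + 1e-9)))
    stop_domain("observed p must lie in [0, p0]")
  if (max(p) <= 0)
    stop_domain("all observations are zero: nothing to fit")
  p <- pmin(p, p0)

  scale <- stats::sd(p)
  if (!is.finite(scale) || scale < 1e-12 * p0) {
    # flat series: no depletion, u_m pinned at its boundary
    pars <- growth_params(0, if (!is.null(init)) init$K else 0.5,
                          if (!is.null(init)) init$cl0_over_y else 1, p0)
    warning("constant series: u_m estimated at the 0 boundary (degenerate)",
            call. = FALSE)
    return(structure(list(params = pars, rss = sum((p - mean(p))^2),
                          converged = TRUE, degenerate = TRUE,
                          fitted = rep(p0, length(p)), residuals = p - p0),
                     class = "growth_fit"))
  }

  resid_fun <- function(theta) {
    pr <- growth_params(theta[1], theta[2], theta[3], p0)
    sim <- try(simulate_growth(pr, times, rtol = 1e-9, atol = 1e-11),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(p)))
    sim$p - p
  }
  run_lm <- function(start) {
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fun,
      lower = c(1e-10, 1e-8, 1e-8), upper = c(10, 100, 1000),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                           ptol = 1e-13)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  starts <- list(if (!is.null(init))
    c(init$u_m, init$K, init$cl0_over_y) else c(0.05, 0.5, 1))
  best <- NULL
  for (s in starts) {
    f <- run_lm(s)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
  }
  # multi-start fallback when the first attempt fails or explains little
  # of the depletion signal
  if (is.null(best) || !best$info %in% 1:4 ||
      best$deviance > 0.1 * sum((p - mean(p))^2)) {
    grid <- expand.grid(u = c(0.005, 0.02, 0.05, 0.2, 1),
                        K = c(0.05, 0.3, 1, 5),
                        r = c(0.2, 1, 5, 20))
    for (i in seq_len(nrow(grid))) {
      f <- run_lm(as.numeric(grid[i, ]))
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
        best <- f
      if (!is.null(best) &&
          best$deviance <= 1e-9 * sum((p - mean(p))^2) + 1e-14) break
    }
  }
  if (is.null(best))
    stop_domain("growth fit failed to converge from every starting point")

  theta <- best$par
  pars <- growth_params(theta[1], theta[2], theta[3], p0)
  fitted <- simulate_growth(pars, times)$p
  structure(list(params = pars, rss = best$deviance,
                 converged = best$info %in% 1:4, degenerate = FALSE,
                 fitted = fitted, residuals = fitted - p,
                 info = best$message),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Monod growth fit (Levenberg-Marquardt on the ODE trajectory)\n")
  print(x$params)
  cat(sprintf("  RSS = %.4g; converged: %s%s\n", x$rss, x$converged,
              if (x$degenerate) " (degenerate: flat series)" else ""))
  invisible(x)
}
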