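# Three-resistance shrinking-core model of microbial sulfur removal.
#
# A spherical coal particle reacts at the surface of an unreacted core of
# radius r_c = r_s * (1 - x)^(1/3) while a solid product layer (jarosite
# etc.) grows around it. At steady state the external (liquid-film)
# diffusion, internal (product-layer) diffusion and interfacial chemical
# reaction rates are equal, and integrating the combined rate law gives
#
#   t = A1 * x + A2 * [1 - (2/3) x - (1-x)^(2/3)] + A3 * [1 - (1-x)^(1/3)],
#
# one lumped time coefficient per resistance. Regressing observed t on the
# three basis functions recovers (A1, A2, A3); the per-term correlations
# with t rank the controlling step.

.SC_EPS <- 1e-9  # x is clipped to <= 1 - .SC_EPS wherever (1-x)^(-k) appears

.sc_mechanisms <- c("external", "internal", "chemical")

#' Shrinking-core basis functions
#'
#' The three conversion functions multiplying the lumped coefficients:
#' `g1 = x` (external diffusion), `g2 = 1 - (2/3) x - (1-x)^(2/3)` (internal
#' diffusion), `g3 = 1 - (1-x)^(1/3)` (chemical reaction).
#'
#' @param x Conversion fraction(s) in `[0, 1]`.
#' @return A matrix with columns `g1`, `g2`, `g3`, one row per `x`.
#' @examples
#' sc_basis(c(0, 0.5, 1))
#' @export
sc_basis <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_domain("conversion `x` must lie in [0, 1]")
  cbind(g1 = x,
        g2 = 1 - (2 / 3) * x - (1 - x)^(2 / 3),
        g3 = 1 - (1 - x)^(1 / 3))
}

#' Lumped kinetic coefficients
#'
#' @param A1,A2,A3 Time-unit coefficients of the external-diffusion,
#'   internal-diffusion and chemical-reaction terms. Signs are not
#'   constrained (unconstrained regressions can return negative values).
#' @return A named numeric vector of class `sc_coefficients`.
#' @export
sc_coefficients <- function(A1, A2, A3) {
  out <- c(A1 = A1, A2 = A2, A3 = A3)
  if (any(!is.finite(out))) stop_domain("coefficients must be finite")
  class(out) <- "sc_coefficients"
  out
}

#' @noRd
as_sc_coefficients <- function(coeffs) {
  if (inherits(coeffs, "sc_coefficients")) return(coeffs)
  if (is.numeric(coeffs) && length(coeffs) == 3L)
    return(sc_coefficients(coeffs[[1]], coeffs[[2]], coeffs[[3]]))
  stop_domain("`coeffs` must be an sc_coefficients object or 3 numbers")
}

#' Physical parameters of the shrinking-core particle system
#'
#' @param gamma Stoichiometric coefficient (dimensionless).
#' @param delta Liquid-film (diffusion-layer) thickness (m).
#' @param rho Coal density (kg/m^3).
#' @param M Molecular weight of the reactant in coal (kg/mol).
#' @param r_s Coal particle radius (m).
#' @param C_l Microbial concentration in solution (per L).
#' @param D1 Diffusion coefficient in solution (m^2/time).
#' @param D2 Diffusion coefficient through the product layer (m^2/time).
#' @param k Interfacial desulfurization rate constant (m/time).
#' @return A list of class `sc_physical`. All entries must be > 0.
#' @export
sc_physical <- function(gamma, delta, rho, M, r_s, C_l, D1, D2, k) {
  vals <- list(gamma = gamma, delta = delta, rho = rho, M = M, r_s = r_s,
               C_l = C_l, D1 = D1, D2 = D2, k = k)
  for (nm in names(vals)) check_number(vals[[nm]], nm, lower = 0,
                                       strict_lower = TRUE)
  structure(vals, class = "sc_physical")
}

#' Lumped coefficients from physical parameters
#'
#' `A1 = gamma delta rho r_s / (3 M C_l D1)`,
#' `A2 = gamma rho r_s^2 / (2 M C_l D2)`,
#' `A3 = rho r_s / (M C_l k)`. The internal-diffusion coefficient uses the
#' initial particle radius `r_s` (the coefficient is a constant of the
#' integrated law, while the core radius shrinks). All three scale as
#' `1 / C_l`.
#'
#' @param params An [sc_physical()] parameter set.
#' @return An [sc_coefficients()] vector, all entries positive.
#' @examples
#' ph <- sc_physical(gamma = 1, delta = 1e-5, rho = 1300, M = 0.120,
#'                   r_s = 6.3e-5, C_l = 1, D1 = 1e-9, D2 = 1e-11, k = 1e-6)
#' sc_from_physical(ph)
#' @export
sc_from_physical <- function(params) {
  stopifnot(inherits(params, "sc_physical"))
  with(params, sc_coefficients(
    A1 = gamma * delta * rho * r_s / (3 * M * C_l * D1),
    A2 = gamma * rho * r_s^2 / (2 * M * C_l * D2),
    A3 = rho * r_s / (M * C_l * k)))
}

#' Time at a given conversion
#'
#' Evaluates the integrated shrinking-core law
#' `t(x) = A1 g1(x) + A2 g2(x) + A3 g3(x)`.
#'
#' @param coeffs An [sc_coefficients()] vector (or 3 numbers).
#' @param x Conversion fraction(s) in `[0, 1)`.
#' @return Time(s), in the coefficients' time unit.
#' @examples
#' sc_time(sc_coefficients(10, 40, 5), 0.5)
#' @export
sc_time <- function(coeffs, x) {
  coeffs <- as_sc_coefficients(coeffs)
  drop(sc_basis(x) %*% as.numeric(coeffs))
}

#' Conversion at a given time
#'
#' Inverts `t(x)` by bisection on `[0, 1 - 1e-9]` to absolute tolerance
#' 1e-10. Requires `t(x)` to be increasing on the bracket for the supplied
#' coefficients; a non-monotone profile is reported with the offending
#' interval.
#'
#' @param coeffs An [sc_coefficients()] vector.
#' @param t Time(s), >= 0.
#' @return Conversion fraction(s).
#' @examples
#' cf <- sc_coefficients(10, 40, 5)
#' sc_conversion(cf, sc_time(cf, 0.63))  # 0.63
#' @export
sc_conversion <- function(coeffs, t) {
  coeffs <- as_sc_coefficients(coeffs)
  if (any(!is.finite(t)) || any(t < 0))
    stop_domain("`t` must be finite and non-negative")
  hi <- 1 - .SC_EPS
  probe <- seq(0, hi, length.out = 129L)
  tp <- sc_time(coeffs, probe)
  dec <- which(diff(tp) < 0)
  if (length(dec))
    stop_domain(
      "t(x) is not increasing on [%.4f, %.4f]: cannot invert these coefficients",
      probe[dec[1]], probe[dec[1] + 1L])
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    if (tt >= tp[length(tp)]) return(hi)
    lo <- 0; up <- hi
    while (up - lo > 1e-10) {
      mid <- (lo + up) / 2
      if (sc_time(coeffs, mid) < tt) lo <- mid else up <- mid
    }
    (lo + up) / 2
  }, numeric(1))
}

#' Conversion rate
#'
#' `dx/dt` as the reciprocal of `dt/dx` from the integrated law:
#' `dt/dx = A1 + A2 (2/3) [(1-x)^(-1/3) - 1] + A3 (1/3) (1-x)^(-2/3)`.
#'
#' @param coeffs An [sc_coefficients()] vector.
#' @param x Conversion fraction(s) in `[0, 1)`; clipped to `1 - 1e-9`.
#' @return `dx/dt`, positive wherever `t(x)` is increasing.
#' @examples
#' sc_rate(sc_coefficients(0, 0, 5), 0.3)  # 3 (1-x)^(2/3) / A3
#' @export
sc_rate <- function(coeffs, x) {
  coeffs <- as_sc_coefficients(coeffs)
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1))
    stop_domain("conversion `x` must lie in [0, 1)")
  x <- pmin(x, 1 - .SC_EPS)
  dtdx <- coeffs[["A1"]] +
    coeffs[["A2"]] * (2 / 3) * ((1 - x)^(-1 / 3) - 1) +
    coeffs[["A3"]] * (1 / 3) * (1 - x)^(-2 / 3)
  if (any(dtdx <= 0))
    stop_domain("non-physical rate: dt/dx <= 0 at x = %g",
                x[which(dtdx <= 0)[1]])
  1 / dtdx
}

#' Microbial concentrations at the core surface and in the film
#'
#' At steady state the molar consumption rate `dn/dt` (<= 0) fixes the
#' concentration at the reaction interface, `C_ls = -(dn/dt)/(4 pi r_c^2 k)`,
#' and across the product layer,
#' `C_s = C_ls + (-(dn/dt)) gamma (r_s - r_c) / (4 pi r_s r_c D2)`.
#'
#' @param params An [sc_physical()] parameter set.
#' @param x Conversion fraction in `[0, 1)`.
#' @param molar_rate `dn/dt` in mol/time, <= 0 (consumption).
#' @return Named vector `c(C_s, C_ls)`, both >= 0 with `C_s >= C_ls`.
#' @export
sc_intermediates <- function(params, x, molar_rate) {
  stopifnot(inherits(params, "sc_physical"))
  check_number(x, "x", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(molar_rate, "molar_rate", upper = 0)
  r_c <- params$r_s * (1 - x)^(1 / 3)
  if (r_c <= 0)
    stop_domain("core radius vanished (x -> 1): concentrations are singular")
  consumption <- -molar_rate
  C_ls <- consumption / (4 * pi * r_c^2 * params$k)
  C_s <- C_ls + consumption * params$gamma * (params$r_s - r_c) /
    (4 * pi * params$r_s * r_c * params$D2)
  c(C_s = C_s, C_ls = C_ls)
}

#' Fit the lumped coefficients to a conversion-time series
#'
#' Ordinary least squares of observed time on the three basis functions
#' (no intercept: `t(0) = 0` by construction), with per-term Pearson
#' correlations against `t` and the controlling-step ranking they imply.
#'
#' @param t Observation times, >= 0.
#' @param x Conversion fractions in `(0, 1)`, same length (>= 4 points).
#' @param nonneg If `TRUE`, constrain all coefficients to be >= 0
#'   (non-negative least squares) for strictly physical fits.
#' @return A list of class `sc_fit`:
#'   \describe{
#'     \item{coefficients}{[sc_coefficients()] estimates.}
#'     \item{r}{Named correlations `r_A1`, `r_A2`, `r_A3` of each basis term
#'       with observed `t`.}
#'     \item{R}{Correlation between fitted and observed `t`; `R2` its
#'       square.}
#'     \item{controlling_step}{The three mechanisms ranked by descending
#'       absolute per-term correlation.}
#'     \item{fitted, residuals, rss}{Regression output.}
#'   }
#' @examples
#' xx <- seq(0.05, 0.95, by = 0.05)
#' tt <- sc_time(sc_coefficients(10, 40, 5), xx)
#' fit_sc(tt, xx)$coefficients
#' @export
fit_sc <- function(t, x, nonneg = FALSE) {
  t <- as.numeric(t); x <- as.numeric(x)
  if (length(t) != length(x) || length(t) < 4L)
    stop_domain("need >= 4 paired (t, x) observations")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop_domain("conversions must lie strictly in (0, 1)")
  G <- sc_basis(x)
  if (qr(G)$rank < 3L)
    stop_domain("singular design: the basis functions are collinear at these x")
  if (nonneg) {
    nn <- pracma::lsqnonneg(G, t)
    beta <- nn$x
    fitted <- drop(G %*% beta)
  } else {
    fit <- stats::lm.fit(G, t)
    beta <- fit$coefficients
    fitted <- drop(G %*% beta)
  }
  r <- vapply(1:3, function(i)
    suppressWarnings(stats::cor(G[, i], t)), numeric(1))
  r[!is.finite(r)] <- 0
  names(r) <- c("r_A1", "r_A2", "r_A3")
  Rcor <- suppressWarnings(stats::cor(fitted, t))
  if (!is.finite(Rcor)) Rcor <- 0
  ranking <- .sc_mechanisms[order(-abs(r))]
  structure(list(
    coefficients = sc_coefficients(beta[[1]], beta[[2]], beta[[3]]),
    r = r, R = Rcor, R2 = Rcor^2,
    controlling_step = ranking,
    fitted = fitted, residuals = t - fitted,
    rss = sum((t - fitted)^2), nonneg = nonneg),
    class = "sc_fit")
}

#' @export
print.sc_fit <- function(x, ...) {
  cat("Shrinking-core coefficient regression",
      if (x$nonneg) "(non-negative)" else "(unconstrained)", "\n")
  cat(sprintf("  A1 = %.6g, A2 = %.6g, A3 = %.6g\n",
              x$coefficients[["A1"]], x$coefficients[["A2"]],
              x$coefficients[["A3"]]))
  cat(sprintf("  r(A1) = %.4f, r(A2) = %.4f, r(A3) = %.4f;  R = %.4f (R^2 = %.4f)\n",
              x$r[["r_A1"]], x$r[["r_A2"]], x$r[["r_A3"]], x$R, x$R2))
  cat("  controlling step ranking:",
      paste(x$controlling_step, collapse = " > "), "\n")
  invisible(x)
}

#' Conversion trajectory under growing microbial concentration
#'
#' Couples the shrinking-core rate to the Monod growth model: since every
#' lumped coefficient scales as `1 / C_l`, the instantaneous conversion rate
#' is the fixed-coefficient rate multiplied by `C_l(t) / C_l(0)`, with
#' `C_l(t)/C_l(0) = 1 + (p0 - p(t)) / (C_l0/Y)` supplied by the substrate
#' trajectory. The substrate and conversion ODEs are integrated jointly.
#'
#' @param growth A [growth_params()] object with `cl0_over_y > 0`.
#' @param coeffs [sc_coefficients()] measured at the initial microbial
#'   concentration `C_l(0)`.
#' @param times Ordered, non-negative output times.
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `conversion_series` with columns `time`,
#'   `x` (non-decreasing, capped below 1), `p` and `cl_ratio`
#'   (`C_l(t)/C_l(0)`).
#' @examples
#' gp <- growth_params(0.0497, 0.328, 1.0838)
#' head(simulate_coupled(gp, sc_coefficients(10, 40, 5), 0:10))
#' @export
simulate_coupled <- function(growth, coeffs, times, rtol = 1e-10,
                             atol = 1e-12) {
  stopifnot(inherits(growth, "growth_params"))
  coeffs <- as_sc_coefficients(coeffs)
  if (growth$cl0_over_y <= 0)
    stop_domain("cl0_over_y must be > 0: C_l(t)/C_l(0) is undefined otherwise")
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times) || times[1] < 0)
    stop_domain("`times` must be ordered and non-negative")
  grid <- unique(c(0, times))
  cap <- 1 - .SC_EPS
  rhs <- function(t, y, parms) {
    p <- min(max(y[1], 0), growth$p0)
    x <- min(max(y[2], 0), cap)
    dp <- -growth$u_m * p * (growth$cl0_over_y + growth$p0 - p) /
      (growth$K + p)
    ratio <- 1 + (growth$p0 - p) / growth$cl0_over_y
    dx <- if (y[2] >= cap) 0 else ratio * sc_rate(coeffs, x)
    list(c(dp, dx))
  }
  sol <- deSolve::lsoda(c(p = growth$p0, x = 0), grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_domain("coupled ODE integration failed (lsoda istate %d)",
                attr(sol, "istate")[1])
  idx <- match(times, grid)
  p <- pmin(pmax(sol[idx, "p"], 0), growth$p0)
  out <- data.frame(
    time = times,
    x = pmin(pmax(cummax(sol[idx, "x"]), 0), cap),
    p = p,
    cl_ratio = 1 + (growth$p0 - p) / growth$cl0_over_y
  )
  class(out) <- c("conversion_series", "data.frame")
  out
}
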