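# Activation-energy estimation from thermogravimetric conversion curves.
#
# Non-isothermal first-order decomposition at constant heating rate alpha
# (K per time) obeys dx/dT = (A/alpha) exp(-E/(R T)) (1 - x). Two
# linearizations of its integral are supported:
#
#   "direct"        ln[-ln(1-x)] = ln(A E / (alpha R)) - 5.314 - 0.1278 E / T
#   "coats-redfern" ln[-ln(1-x) / T^2] = ln(A R / (alpha E)) - E / (R T)
#
# The "direct" form, the default, uses fixed decimal constants in place of
# the exact integration factors; its slope against 1/T is -0.1278 E. The
# textbook Coats-Redfern form is provided for comparison — the two
# conventions give different E from the same data (the decimal constants do
# not equal 1/R = 0.1203 in SI units), which the vignette discusses.

.R_GAS <- 8.314  # J/(mol K)

.CR_SLOPE_FACTOR <- 0.1278   # "direct" convention: slope = -0.1278 * E
.CR_INTERCEPT_SHIFT <- 5.314 # "direct" convention additive constant

#' Arrhenius rate
#'
#' `k = A_pre * exp(-E / (R T))` with `R = 8.314` J/(mol K).
#'
#' @param A_pre Pre-exponential (frequency) factor, >= 0.
#' @param E Activation energy (J/mol).
#' @param temp Absolute temperature (K), > 0; may be a vector.
#' @return Rate constant(s), same unit as `A_pre`.
#' @examples
#' arrhenius_rate(1, 8314, 1000)  # exp(-1)
#' @export
arrhenius_rate <- function(A_pre, E, temp) {
  check_number(A_pre, "A_pre", lower = 0)
  check_number(E, "E")
  if (any(!is.finite(temp)) || any(temp <= 0))
    stop_domain("absolute temperature must be > 0")
  A_pre * exp(-E / (.R_GAS * temp))
}

#' Conversion from a TG mass-loss curve
#'
#' Fractional mass loss between the initial and final masses of the
#' decomposition segment: `x(T) = (m0 - m(T)) / (m0 - mf)`, clipped to
#' `[0, 1]`. When `m0`/`mf` are not supplied they default to the segment
#' extremes (first and minimum mass).
#'
#' @param temperature Temperatures (K), strictly increasing, >= 5 points.
#' @param mass Masses, same length.
#' @param m0,mf Reference initial and final masses, `m0 > mf`.
#' @return A data frame with columns `temperature` and `x`.
#' @export
tg_conversion <- function(temperature, mass, m0 = NULL, mf = NULL) {
  temperature <- as.numeric(temperature); mass <- as.numeric(mass)
  if (length(temperature) < 5L || length(mass) != length(temperature))
    stop_domain("need >= 5 paired (temperature, mass) points")
  if (is.unsorted(temperature, strictly = TRUE))
    stop_domain("temperatures must be strictly increasing")
  if (is.null(m0)) m0 <- mass[1]
  if (is.null(mf)) mf <- min(mass)
  if (m0 <= mf) stop_domain("m0 must exceed mf for a decomposition segment")
  x <- pmin(pmax((m0 - mass) / (m0 - mf), 0), 1)
  data.frame(temperature = temperature, x = x)
}

#' Linearizing transform of a conversion point
#'
#' Maps `(x, T)` to the fitting plane of the chosen convention: abscissa
#' `1/T`, ordinate `ln[-ln(1-x)]` (`"direct"`) or `ln[-ln(1-x)/T^2]`
#' (`"coats-redfern"`). Points with `x <= 0` or `x >= 1` are excluded and
#' counted.
#'
#' @param x Conversion fraction(s).
#' @param temperature Absolute temperature(s) (K), > 0.
#' @param convention `"direct"` (default) or `"coats-redfern"`.
#' @return A data frame with columns `inv_T`, `y` for the usable points; the
#'   number of excluded points is in the `"n_excluded"` attribute.
#' @examples
#' cr_transform(0.5, 600)$y  # log(log(2))
#' @export
cr_transform <- function(x, temperature,
                         convention = c("direct", "coats-redfern")) {
  convention <- match.arg(convention)
  if (length(x) != length(temperature))
    stop_domain("`x` and `temperature` must have equal length")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_domain("absolute temperature must be > 0")
  ok <- is.finite(x) & x > 0 & x < 1
  y <- log(-log(1 - x[ok]))
  if (convention == "coats-redfern") y <- y - 2 * log(temperature[ok])
  out <- data.frame(inv_T = 1 / temperature[ok], y = y)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Fit the activation energy from (T, x) data
#'
#' Ordinary least squares of the transformed ordinate on `1/T`. Under the
#' `"direct"` convention `E = -slope / 0.1278` and
#' `A_pre = (alpha R / E) exp(intercept + 5.314)`; under `"coats-redfern"`,
#' `E = -slope * R` and `A_pre = (alpha E / R) exp(intercept)`.
#'
#' @param temperature Absolute temperatures (K).
#' @param x Conversion fractions; points outside `(0, 1)` are excluded.
#' @param alpha Heating rate (K per time unit); default 10.
#' @param convention `"direct"` (default) or `"coats-redfern"`.
#' @param window Optional `c(Tmin, Tmax)` (K) restricting the fit; default
#'   keeps all points with `0.01 < x < 0.99`.
#' @return A list of class `cr_fit`: `E` (J/mol), `A_pre`, `slope`,
#'   `intercept`, `r2`, `window`, `n_excluded`, `n_used`, `convention`.
#' @examples
#' Tk <- seq(450, 700, by = 10)
#' sim <- gen_tg_conversion(E = 20000, A_pre = 1e3, temperatures = Tk)
#' fit_activation_energy(sim$temperature, sim$x)$E  # 20000
#' @export
fit_activation_energy <- function(temperature, x, alpha = 10,
                                  convention = c("direct", "coats-redfern"),
                                  window = NULL) {
  convention <- match.arg(convention)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  temperature <- as.numeric(temperature); x <- as.numeric(x)
  keep <- is.finite(x) & x > 0.01 & x < 0.99
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- keep & temperature >= window[1] & temperature <= window[2]
  } else {
    window <- if (any(keep)) range(temperature[keep]) else c(NA_real_, NA_real_)
  }
  n_excluded <- sum(!keep)
  pts <- cr_transform(x[keep], temperature[keep], convention)
  n_excluded <- n_excluded + attr(pts, "n_excluded")
  if (nrow(pts) < 3L)
    stop_domain("fewer than 3 usable points after exclusions (%d excluded)",
                n_excluded)
  fit <- stats::lm(y ~ inv_T, data = pts)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # r^2 = 1 is legitimate here
  if (slope >= 0)
    warning("non-negative slope against 1/T: the implied E is <= 0",
            call. = FALSE)
  if (convention == "direct") {
    E <- -slope / .CR_SLOPE_FACTOR
    A_pre <- if (E != 0)
      (alpha * .R_GAS / E) * exp(intercept + .CR_INTERCEPT_SHIFT)
    else NA_real_
  } else {
    E <- -slope * .R_GAS
    A_pre <- if (E != 0) (alpha * E / .R_GAS) * exp(intercept) else NA_real_
  }
  structure(list(E = E, A_pre = A_pre, slope = slope, intercept = intercept,
                 r2 = r2, window = window, n_excluded = n_excluded,
                 n_used = nrow(pts), convention = convention, alpha = alpha),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("Activation-energy fit (%s convention, alpha = %g K/time)\n",
              x$convention, x$alpha))
  cat(sprintf("  E = %.1f J/mol, A_pre = %.4g, slope = %.4f, r^2 = %.5f\n",
              x$E, x$A_pre, x$slope, x$r2))
  cat(sprintf("  window %.1f-%.1f K, %d points used, %d excluded\n",
              x$window[1], x$window[2], x$n_used, x$n_excluded))
  invisible(x)
}
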