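# Shrinking-core model: basis functions, inversion, rates, regression,
# physical mapping, coupled simulation.

test_that("basis functions hit their closed-form anchor values", {
  expect_equal(unname(sc_basis(0)[1, ]), c(0, 0, 0))
  expect_equal(unname(sc_basis(1)[1, ]), c(1, 1 / 3, 1))
  g <- sc_basis(0.5)[1, ]
  expect_equal(unname(g["g2"]), 1 - 1 / 3 - 2^(-2 / 3), tolerance = 1e-12)
  expect_equal(unname(g["g2"]), 0.036707, tolerance = 1e-4)
  expect_equal(unname(g["g3"]), 1 - 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(unname(g["g3"]), 0.206299, tolerance = 1e-5)
  expect_error(sc_basis(1.2), "\\[0, 1\\]")
})

test_that("t(x) is the stated linear combination, including negative fits", {
  expect_equal(sc_time(sc_coefficients(5, -2, 7), 0), 0)
  expect_equal(sc_time(sc_coefficients(1, 0, 0), 0.5), 0.5)
  # coefficients of the reported regression applied at x = 0.5
  cf <- sc_coefficients(-2839.16, -8547.56, 7625.26)
  expect_equal(sc_time(cf, 0.5), -160.2408, tolerance = 1e-4)
})

test_that("time inversion round-trips and flags non-monotone profiles", {
  cf <- sc_coefficients(10, 40, 5)
  expect_equal(sc_conversion(cf, 0), 0)
  expect_equal(sc_conversion(sc_coefficients(1, 0, 0), 0.25), 0.25,
               tolerance = 1e-9)
  expect_equal(sc_conversion(cf, sc_time(cf, 0.63)), 0.63, tolerance = 1e-9)
  for (x in c(0.05, 0.37, 0.91))
    expect_equal(sc_conversion(cf, sc_time(cf, x)), x, tolerance = 1e-9)
  # strongly negative external term makes t(x) dip below zero initially
  expect_error(sc_conversion(sc_coefficients(-50, 1, 1), 3),
               "not increasing")
})

test_that("physical parameters map to positive coefficients with 1/C_l scaling", {
  ph <- sc_physical(gamma = 1, delta = 1e-5, rho = 1300, M = 0.120,
                    r_s = 6.3e-5, C_l = 1, D1 = 1e-9, D2 = 1e-11, k = 1e-6)
  cf <- sc_from_physical(ph)
  expect_true(all(as.numeric(cf) > 0))
  expect_equal(cf[["A1"]], 1e-5 * 1300 * 6.3e-5 / (3 * 0.120 * 1e-9),
               tolerance = 1e-12)
  expect_equal(cf[["A1"]], 2275, tolerance = 1e-3)
  ph2 <- ph; ph2$C_l <- 2
  expect_equal(as.numeric(sc_from_physical(ph2)), as.numeric(cf) / 2)
  ph3 <- ph; ph3$D2 <- 2e-11
  cf3 <- sc_from_physical(ph3)
  expect_equal(cf3[["A2"]], cf[["A2"]] / 2)
  expect_equal(cf3[["A1"]], cf[["A1"]])
  expect_equal(cf3[["A3"]], cf[["A3"]])
  expect_error(sc_physical(1, 1, 1, 1, 1, 0, 1, 1, 1), "C_l")
})

test_that("conversion rate reduces to the single-resistance laws", {
  expect_equal(sc_rate(sc_coefficients(1, 0, 0), c(0.1, 0.5, 0.9)),
               c(1, 1, 1))
  A3 <- 5
  for (x in c(0.1, 0.5, 0.9))
    expect_equal(sc_rate(sc_coefficients(0, 0, A3), x),
                 3 * (1 - x)^(2 / 3) / A3, tolerance = 1e-12)
  expect_error(sc_rate(sc_coefficients(-1, 0, 0), 0.5), "non-physical")
})

test_that("rate and the derivative of t(x) are reciprocal", {
  cf <- sc_coefficients(10, 40, 5)
  h <- 1e-7
  for (x in c(0.1, 0.4, 0.7, 0.95)) {
    dtdx <- (sc_time(cf, x + h) - sc_time(cf, x - h)) / (2 * h)
    expect_equal(sc_rate(cf, x) * dtdx, 1, tolerance = 1e-6)
  }
  # integrating dt/dx = 1/rate from 0 reproduces the closed form at x = 0.9
  t_int <- stats::integrate(function(x) 1 / sc_rate(cf, x), 0, 0.9,
                            rel.tol = 1e-12)$value
  expect_equal(t_int, sc_time(cf, 0.9), tolerance = 1e-8)
})

test_that("single-resistance limits match the classical integrated laws", {
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(sc_time(sc_coefficients(7, 0, 0), xs), 7 * xs)
  expect_equal(sc_time(sc_coefficients(0, 11, 0), xs),
               11 * (1 - 2 / 3 * xs - (1 - xs)^(2 / 3)))
  expect_equal(sc_time(sc_coefficients(0, 0, 3), xs),
               3 * (1 - (1 - xs)^(1 / 3)))
})

test_that("film and interface concentrations behave at the trivial limits", {
  ph <- sc_physical(gamma = 1, delta = 1e-5, rho = 1300, M = 0.120,
                    r_s = 6.3e-5, C_l = 1, D1 = 1e-9, D2 = 1e-11, k = 1e-6)
  expect_equal(unname(sc_intermediates(ph, 0.3, 0)), c(0, 0))
  cc <- sc_intermediates(ph, 0, -1e-12)
  expect_equal(cc[["C_s"]], cc[["C_ls"]])  # no product layer at x = 0
  big_D2 <- ph; big_D2$D2 <- 1e6
  cc2 <- sc_intermediates(big_D2, 0.5, -1e-12)
  expect_equal(cc2[["C_s"]], cc2[["C_ls"]], tolerance = 1e-9)
  cc3 <- sc_intermediates(ph, 0.5, -1e-12)
  expect_gt(cc3[["C_s"]], cc3[["C_ls"]])
  expect_error(sc_intermediates(ph, 0.5, 1), "molar_rate")
})

test_that("coefficient regression is exact on noiseless series", {
  xs <- seq(0.05, 0.95, by = 0.05)
  for (cf in list(c(10, 40, 5), c(3, 0.5, 12), c(100, 2000, 800))) {
    tt <- sc_time(sc_coefficients(cf[1], cf[2], cf[3]), xs)
    fit <- fit_sc(tt, xs)
    expect_equal(as.numeric(fit$coefficients), cf, tolerance = 1e-9)
    expect_equal(fit$R, 1, tolerance = 1e-12)
    expect_equal(fit$R2, 1, tolerance = 1e-12)
  }
})

test_that("an internal-diffusion-dominated series is ranked internal first", {
  xs <- seq(0.05, 0.95, by = 0.05)
  cf <- sc_coefficients(2, 4000, 3)  # A2 >> A1, A3
  s <- gen_conversion_series(cf, xs, sd = 2, seed = 11)
  fit <- fit_sc(s$t, s$x)
  expect_gt(abs(fit$r[["r_A2"]]), abs(fit$r[["r_A1"]]))
  expect_gt(abs(fit$r[["r_A2"]]), abs(fit$r[["r_A3"]]))
  expect_equal(fit$controlling_step[1], "internal")
  expect_setequal(fit$controlling_step, c("external", "internal", "chemical"))
})

test_that("degenerate inputs are handled or rejected cleanly", {
  # duplicated x with different t: residual splits, no crash
  fit <- fit_sc(c(1, 2, 3, 10, 12), c(0.1, 0.2, 0.3, 0.5, 0.5))
  expect_length(fit$residuals, 5L)
  # both duplicated points get the same fitted value
  expect_equal(fit$fitted[4], fit$fitted[5], tolerance = 1e-12)
  expect_error(fit_sc(c(1, 2, 3, 4), rep(0.4, 4)), "singular")
  expect_error(fit_sc(1:3, c(0.1, 0.2, 0.3)), ">= 4")
  expect_error(fit_sc(1:4, c(0.1, 0.5, 0.9, 1.0)), "strictly")
})

test_that("non-negative regression keeps coefficients physical", {
  xs <- seq(0.05, 0.95, by = 0.05)
  tt <- sc_time(sc_coefficients(10, 40, 5), xs) +
    sin(seq_along(xs)) * 30  # rough perturbation that drives OLS negative
  fit <- fit_sc(tt, xs, nonneg = TRUE)
  expect_true(all(as.numeric(fit$coefficients) >= 0))
})

test_that("coupled simulation reduces to fixed coefficients when growth stops", {
  cf <- sc_coefficients(10, 40, 5)
  gp0 <- growth_params(0, 0.328, 1.0838)
  times <- seq(0, 24, by = 4)
  coupled <- simulate_coupled(gp0, cf, times)
  expect_equal(coupled$x, sc_conversion(cf, times), tolerance = 1e-7)
  expect_equal(coupled$cl_ratio, rep(1, length(times)))
})

test_that("growing biomass accelerates conversion beyond the frozen model", {
  cf <- sc_coefficients(10, 40, 5)
  gp <- ref_growth()
  times <- seq(0, 12, by = 2)  # inside the finite conversion window
  coupled <- simulate_coupled(gp, cf, times)
  fixed <- sc_conversion(cf, times)
  expect_true(all(coupled$x >= fixed - 1e-9))
  expect_gt(coupled$x[length(times)], fixed[length(times)])
  expect_true(all(diff(coupled$x) >= 0))
  expect_true(all(coupled$x < 1))
})

test_that("the coupled path matches a fixed-step RK4 oracle", {
  cf <- sc_coefficients(10, 40, 5)
  gp <- ref_growth()
  dtdx <- function(x) 10 + 40 * (2 / 3) * ((1 - x)^(-1 / 3) - 1) +
    5 * (1 / 3) * (1 - x)^(-2 / 3)
  rhs <- function(t, y) {
    p <- min(max(y[1], 0), gp$p0)
    c(-gp$u_m * p * (gp$cl0_over_y + gp$p0 - p) / (gp$K + p),
      (1 + (gp$p0 - p) / gp$cl0_over_y) / dtdx(min(y[2], 1 - 1e-9)))
  }
  # t = 10 keeps the conversion safely inside (0, 1) for these coefficients
  oracle <- rk4_path(rhs, c(gp$p0, 0), 10, h = 0.002)
  got <- simulate_coupled(gp, cf, c(0, 10))
  expect_equal(got$x[2], oracle[2], tolerance = 1e-6)
  expect_equal(got$p[2], oracle[1], tolerance = 1e-6)
})
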