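# Independent oracles, deliberately written apart from the package's
# implementation paths.

# Fixed-step classical RK4 for dy/dt = f(t, y) (y scalar or vector).
rk4_path <- function(f, y0, t_end, h) {
  n <- ceiling(t_end / h)
  h <- t_end / n
  y <- y0
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Brute-force factor sum of squares: 4 * sum over levels of
# (level mean - grand mean)^2, straight from the definition.
brute_ss <- function(levels, y) {
  gm <- mean(y)
  means <- tapply(y, levels, mean)
  4 * sum((means - gm)^2)
}

# The 16 shipped responses, for tests that need them without file I/O.
fixture_responses <- c(32.65, 60.15, 58.17, 54.16, 55.26, 57.65, 57.19,
                       60.76, 65.14, 68.22, 66.17, 68.09, 68.15, 51.23,
                       50.15, 51.50)

ref_growth <- function() growth_params(u_m = 0.0497, K = 0.328,
                                       cl0_over_y = 1.0838)
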