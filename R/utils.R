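# Internal helpers shared across modules.

#' @noRd
round_half_up <- function(x, digits = 2) {
  # Display rounding for report tables: 0.5 always rounds away from zero,
  # matching how the source tables were typeset (base round() is banker's).
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
stop_domain <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain("`%s` = %g is outside its admissible range [%s, %s]",
                name, x,
                paste0(if (strict_lower) "(" else "", format(lower)),
                paste0(format(upper), if (strict_upper) ")" else ""))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
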