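# Closed-form process metrics: ferrous-iron conversion, desulfurization rate,
# pyritic-sulfur share, Fe2+ content of 9 K medium. All percentages are on
# the 0-100 scale.

# Fixed molar masses (g/mol), IUPAC 2021.
.M_FE <- 55.845
.M_FESO4_7H2O <- 278.01

#' Ferrous-iron conversion
#'
#' Fraction of the initial Fe2+ oxidized to Fe3+,
#' `eta = 100 * (c0 - c) / c0`, used as a proxy for the growth activity of
#' the iron-oxidizing bacterium.
#'
#' @param c0 Initial Fe2+ concentration (g/L), > 0.
#' @param c Instantaneous Fe2+ concentration (g/L), in `[0, c0]`.
#'   May be a vector.
#' @return Conversion in per cent, in `[0, 100]`.
#' @examples
#' fe2_conversion(8.88, 4.44)  # 50
#' @export
fe2_conversion <- function(c0, c) {
  check_number(c0, "c0", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(c)) || any(c < 0) || any(c > c0))
    stop_domain("`c` must lie in [0, c0]; the reverse reaction is not modelled")
  100 * (c0 - c) / c0
}

#' Desulfurization rate
#'
#' Per cent of inorganic sulfur removed from the coal sample,
#' `w = 100 * (s_before - s_after) / s_before`.
#'
#' @param s_before Inorganic sulfur content before desulfurization (% mass),
#'   > 0.
#' @param s_after Inorganic sulfur content after desulfurization (% mass),
#'   in `[0, s_before]`.
#' @return Desulfurization rate in per cent.
#' @examples
#' desulfurization_rate(1.35, 0.3358)  # 75.13
#' @export
desulfurization_rate <- function(s_before, s_after) {
  check_number(s_before, "s_before", lower = 0, strict_lower = TRUE)
  check_number(s_after, "s_after", lower = 0, upper = s_before)
  100 * (s_before - s_after) / s_before
}

#' Pyritic share of total sulfur
#'
#' @param pyritic Pyritic sulfur content (% mass), in `[0, total]`.
#' @param total Total sulfur content (% mass), > 0.
#' @param digits Display rounding (half-up); `NULL` for full precision.
#' @return Share of total sulfur bound as pyrite, in per cent.
#' @examples
#' pyritic_share(1.35, 2.39)  # 56.49
#' @export
pyritic_share <- function(pyritic, total, digits = 2) {
  check_number(total, "total", lower = 0, strict_lower = TRUE)
  check_number(pyritic, "pyritic", lower = 0, upper = total)
  out <- 100 * pyritic / total
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Fe2+ concentration from ferrous sulfate heptahydrate
#'
#' Converts a FeSO4.7H2O mass concentration to the Fe2+ concentration it
#' supplies, by the molar-mass ratio 55.845 / 278.01. The standard 9 K
#' medium carries 44.2 g/L FeSO4.7H2O, i.e. 8.88 g/L Fe2+.
#'
#' @param mass_conc FeSO4.7H2O concentration (g/L), >= 0. May be a vector.
#' @return Fe2+ concentration (g/L).
#' @examples
#' fe2_from_heptahydrate(44.2)  # 8.878634
#' @export
fe2_from_heptahydrate <- function(mass_conc) {
  if (any(!is.finite(mass_conc)) || any(mass_conc < 0))
    stop_domain("`mass_conc` must be finite and non-negative")
  mass_conc * .M_FE / .M_FESO4_7H2O
}
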