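# L16(4^4) orthogonal design: construction, validation, fixture, CSV I/O.

# Fixed level assignment of the 16-run, four-factor, four-level orthogonal
# array used throughout.  Rows are runs, columns are factors A-D, entries are
# level indices 1-4.  Every level of every factor appears exactly four times
# and every pair of factors is orthogonal (each level combination once).
.l16_layout <- matrix(
  c(1, 1, 1, 1,
    1, 2, 2, 2,
    1, 3, 3, 3,
    1, 4, 4, 4,
    2, 2, 3, 4,
    2, 1, 4, 3,
    2, 4, 1, 2,
    2, 3, 2, 1,
    3, 3, 4, 2,
    3, 4, 3, 1,
    3, 1, 2, 4,
    3, 2, 1, 3,
    4, 4, 2, 3,
    4, 3, 1, 4,
    4, 2, 4, 1,
    4, 1, 3, 2),
  nrow = 16, ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("A", "B", "C", "D"))
)

#' Specify one factor of an orthogonal experiment
#'
#' @param factor_id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param name Human-readable factor name, e.g. `"Temperature"`.
#' @param unit Physical unit of the level values.
#' @param levels Numeric vector of exactly four distinct physical level
#'   values (e.g. temperatures in degrees Celsius), in level-index order.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("A", "Temperature", "degC", c(20, 25, 30, 35))
#' @export
factor_spec <- function(factor_id, name, unit, levels) {
  factor_id <- match.arg(factor_id, c("A", "B", "C", "D"))
  if (length(levels) != 4L || anyDuplicated(levels) || any(!is.finite(levels)))
    stop_domain("factor %s needs exactly 4 distinct finite level values",
                factor_id)
  structure(list(factor_id = factor_id, name = name, unit = unit,
                 levels = as.numeric(levels)),
            class = "factor_spec")
}

#' Default factor specifications of the desulfurization screening experiment
#'
#' Temperature (degC), coal particle size (mesh), initial pH and bacterial
#' liquid quantity (mL), each at four levels.
#'
#' @return A named list of four [factor_spec()] objects.
#' @export
desulf_factors <- function() {
  list(
    A = factor_spec("A", "Temperature", "degC", c(20, 25, 30, 35)),
    B = factor_spec("B", "Coal particle size", "mesh", c(60, 80, 100, 120)),
    C = factor_spec("C", "Initial pH", "", c(1.5, 2.0, 2.5, 3.0)),
    D = factor_spec("D", "Bacterial liquid quantity", "mL", c(5, 10, 15, 20))
  )
}

#' Build the L16(4^4) orthogonal design
#'
#' Returns the fixed 16-run level assignment of the L16(4^4) array, optionally
#' with the run-level responses attached.
#'
#' @param factors A list of four [factor_spec()] objects named/identified
#'   A-D (default [desulf_factors()]); used for labelling only, the level
#'   assignment is the canonical array.
#' @param responses Optional numeric vector of 16 responses (per cent), in
#'   run order.
#'
#' @return A data frame of class `l16_design` with columns `run`, `A`-`D`
#'   (level indices) and `response` (`NA` when unset); the factor specs are
#'   kept in the `"factors"` attribute.
#' @examples
#' d <- l16_design()
#' d[5, ]  # run 5 sits at levels (A2, B2, C3, D4)
#' @export
l16_design <- function(factors = desulf_factors(), responses = NULL) {
  if (length(factors) != 4L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop_domain("`factors` must be a list of four factor_spec objects")
  ids <- unname(vapply(factors, `[[`, character(1), "factor_id"))
  if (!identical(sort(ids), c("A", "B", "C", "D")))
    stop_domain("factor ids must be exactly A, B, C, D")
  factors <- factors[order(ids)]
  names(factors) <- sort(ids)
  if (is.null(responses)) {
    responses <- rep(NA_real_, 16L)
  } else {
    if (length(responses) != 16L)
      stop_domain("`responses` must have length 16, got %d", length(responses))
    responses <- as.numeric(responses)
    if (any(!is.finite(responses)) || any(responses < 0))
      stop_domain("responses must be finite and non-negative")
  }
  out <- data.frame(run = 1:16, .l16_layout, response = responses)
  attr(out, "factors") <- factors
  class(out) <- c("l16_design", "data.frame")
  out
}

# Validate an l16_design-shaped data frame (also used on CSV input).
#' @noRd
validate_l16 <- function(design, need_responses = FALSE) {
  cols <- c("run", "A", "B", "C", "D", "response")
  miss <- setdiff(cols, names(design))
  if (length(miss))
    stop_domain("design is missing column(s): %s (expected %s)",
                paste(miss, collapse = ", "), paste(cols, collapse = ","))
  if (nrow(design) != 16L)
    stop_domain("an L16 design has 16 runs, got %d", nrow(design))
  for (f in c("A", "B", "C", "D")) {
    lev <- design[[f]]
    if (!all(lev %in% 1:4) || !all(tabulate(lev, 4L) == 4L))
      stop_domain(
        "factor %s is unbalanced: each level 1-4 must appear exactly 4 times", f)
  }
  if (need_responses) {
    y <- design$response
    if (anyNA(y) || any(!is.finite(y)))
      stop_domain("all 16 responses must be present and finite")
    if (any(y < 0)) stop_domain("responses must be non-negative")
  }
  invisible(design)
}

#' The shipped desulfurization screening dataset
#'
#' The 16-run L16(4^4) microbial coal-desulfurization experiment: factor
#' levels per run together with the observed desulfurization rate (per cent
#' of inorganic sulfur removed) after 10 days.
#'
#' @return An `l16_design` data frame with all 16 responses set.
#' @examples
#' d <- desulf_l16()
#' range_analysis(d)
#' @export
desulf_l16 <- function() {
  path <- system.file("extdata", "l16_desulfurization.csv",
                      package = "biodesulf", mustWork = TRUE)
  read_design_csv(path)
}

#' Read / write an L16 design as CSV
#'
#' The dialect is `run,A,B,C,D,response`: level indices 1-4 as integers,
#' response in per cent (may be empty for unset responses).
#'
#' @param path File path.
#' @param design An `l16_design` data frame (for writing).
#' @return `read_design_csv()` returns a validated `l16_design`;
#'   `write_design_csv()` returns `path` invisibly.
#' @export
read_design_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("run", "A", "B", "C", "D", "response")
  miss <- setdiff(cols, names(raw))
  if (length(miss))
    stop_domain("unrecognized design CSV header: missing %s (expected %s)",
                paste(miss, collapse = ", "), paste(cols, collapse = ","))
  bad <- which(!stats::complete.cases(raw[c("run", "A", "B", "C", "D")]))
  if (length(bad))
    stop_domain("malformed design row(s): %s", paste(bad, collapse = ", "))
  raw <- raw[order(raw$run), cols]
  rownames(raw) <- NULL
  validate_l16(raw)
  attr(raw, "factors") <- desulf_factors()
  class(raw) <- c("l16_design", "data.frame")
  raw
}

#' @rdname read_design_csv
#' @export
write_design_csv <- function(design, path) {
  validate_l16(design)
  utils::write.csv(as.data.frame(design)[c("run", "A", "B", "C", "D",
                                           "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
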