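# L16(4^4) design construction, range analysis and ANOVA.

test_that("the L16 array has the canonical layout and is balanced", {
  d <- l16_design()
  expect_equal(nrow(d), 16L)
  expect_equal(unlist(d[1, c("A", "B", "C", "D")], use.names = FALSE),
               c(1, 1, 1, 1))
  expect_equal(unlist(d[5, c("A", "B", "C", "D")], use.names = FALSE),
               c(2, 2, 3, 4))
  for (f in c("A", "B", "C", "D"))
    expect_equal(tabulate(d[[f]], 4), rep(4L, 4))
  # pairwise orthogonality: every level pair appears exactly once
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
    expect_true(all(table(d[[pair[1]]], d[[pair[2]]]) == 1))
})

test_that("invalid factor specifications are rejected", {
  expect_error(factor_spec("A", "temp", "degC", c(20, 25, 30)), "4 distinct")
  expect_error(factor_spec("A", "temp", "degC", c(20, 20, 30, 35)),
               "4 distinct")
  expect_error(l16_design(factors = desulf_factors()[1:3]), "four")
  expect_error(l16_design(responses = c(1, 2, 3)), "length 16")
  expect_error(l16_design(responses = c(-1, fixture_responses[-1])),
               "non-negative")
})

test_that("range analysis reproduces the shipped dataset's level sums", {
  rs <- range_analysis(desulf_l16())
  expect_equal(rs$K["1", "A"], 205.13, tolerance = 1e-12)
  expect_equal(unname(rs$K[, "A"]), c(205.13, 230.86, 267.62, 221.03))
  expect_equal(rs$K["2", "C"], 255.23, tolerance = 1e-12)
  expect_equal(unname(rs$superior_level), c(3L, 4L, 2L, 3L))
  # K-sum conservation: each factor's level sums add to the grand sum
  for (f in colnames(rs$K))
    expect_equal(sum(rs$K[, f]), rs$grand_sum)
  expect_equal(unname(round(rs$R, 2)[c("C", "D")]), c(11.52, 10.07))
  # the typeset tables rounded means before differencing factor A
  expect_equal(unname(rs$R_rounded_means["A"]), 15.63)
  expect_equal(unname(round(rs$R["A"], 2)), 15.62)
})

test_that("a constant response gives zero ranges and equal level sums", {
  d <- l16_design(responses = rep(50, 16))
  rs <- range_analysis(d)
  expect_equal(unname(rs$R), rep(0, 4))
  expect_true(all(rs$K == 200))
})

test_that("range analysis refuses incomplete responses", {
  expect_error(range_analysis(l16_design()), "present")
})

test_that("ANOVA matches the K-sum formulas, the brute-force oracle and aov", {
  d <- desulf_l16()
  an <- ortho_anova(d)
  ss <- setNames(an$SS, an$source)
  expect_equal(unname(round(ss[c("A", "B", "D", "Error")], 2)),
               c(527.40, 208.84, 209.80, 36.95))
  # factor C's printed value is not reproducible from the run data;
  # recomputation gives 270.95 (and total 1253.93)
  expect_equal(unname(round(ss["C"], 2)), 270.95)
  expect_equal(unname(round(ss["Total"], 2)), 1253.93)
  expect_equal(unname(round(an$F[an$source == "A"], 2)), 14.28)
  # decomposition identity at full precision
  expect_equal(sum(ss[c("A", "B", "C", "D", "Error")]), ss[["Total"]],
               tolerance = 1e-12)
  # brute-force definition of the factor sums of squares
  for (f in c("A", "B", "C", "D"))
    expect_equal(ss[[f]], brute_ss(d[[f]], d$response), tolerance = 1e-9)
  # independent route: base aov on the same model
  av <- summary(stats::aov(response ~ factor(A) + factor(B) + factor(C) +
                             factor(D), data = as.data.frame(d)))[[1]]
  expect_equal(unname(ss[c("A", "B", "C", "D", "Error")]),
               av[["Sum Sq"]], tolerance = 1e-9)
  expect_equal(an$p[1:4],
               unname(stats::pf(an$F[1:4], 3, 3, lower.tail = FALSE)))
})

test_that("constant responses give all-zero sums of squares", {
  d <- l16_design(responses = rep(50, 16))
  expect_warning(an <- ortho_anova(d), "zero error mean square")
  expect_equal(an$SS, rep(0, 6))
})

test_that("run order does not affect range analysis or ANOVA", {
  d <- desulf_l16()
  shuffled <- as.data.frame(d)[sample(16), ]
  class(shuffled) <- class(d)
  expect_equal(range_analysis(shuffled)$K, range_analysis(d)$K)
  expect_equal(ortho_anova(shuffled)$SS, ortho_anova(d)$SS)
})

test_that("factors are ordered by descending F with label tie-breaks", {
  an <- ortho_anova(desulf_l16())
  expect_equal(significance_order(an), c("A", "C", "D", "B"))

  fake <- function(Fv) {
    out <- data.frame(source = c("A", "B", "C", "D", "Error", "Total"),
                      df = c(3, 3, 3, 3, 3, 15),
                      SS = c(Fv, NA, NA), MS = NA, F = c(Fv, NA, NA),
                      p = NA, signif = "")
    class(out) <- c("ortho_anova", "data.frame")
    out
  }
  expect_equal(significance_order(fake(c(1, 2, 3, 4))),
               c("D", "C", "B", "A"))
  expect_warning(ord <- significance_order(fake(c(2, 2, 2, 2))), "tie")
  expect_equal(ord, c("A", "B", "C", "D"))
})

test_that("an injected dominant factor effect is detected as largest F", {
  eff <- list(A = c(-6.5, -0.1, 9.1, -2.5))
  hits <- 0L
  for (s in 1:100) {
    d <- gen_design_responses(57.8, eff, sd = 3.5, seed = s)
    an <- ortho_anova(d)
    ss <- setNames(an$SS, an$source)
    if (which.max(ss[c("A", "B", "C", "D")]) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the audit flags exactly the known inconsistent summary entries", {
  chk <- check_reported()
  expect_s3_class(chk, "reported_check")
  expect_setequal(chk$quantity[!chk$agrees],
                  c("K_4D", "SS_C", "SS_Total", "F_C"))
})

test_that("design CSV round-trips and malformed input is reported", {
  d <- desulf_l16()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  back <- read_design_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(d),
               ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("run,A,B,C,response\n1,1,1,1,10", bad)
  expect_error(read_design_csv(bad), "missing D")

  gap <- as.data.frame(d)
  gap$A[3] <- NA
  gap_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(gap, gap_path, row.names = FALSE)
  expect_error(read_design_csv(gap_path), "row")
})
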