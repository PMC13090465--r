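test_that("unidimensionality rule counts its three-member menu", {
  ## two of three met (TLI/CFI jointly fail)
  v <- evaluate_unidimensionality(list(RMSEA = 0.05, SRMR = 0.07, CFI = 0.96, TLI = 0.94))
  expect_true(v$pass); expect_equal(v$n_met, 2)
  ## the failing autism-screener pattern: only RMSEA acceptable
  v2 <- evaluate_unidimensionality(list(RMSEA = 0.06, TLI = 0.90, CFI = 0.90, SRMR = 0.09))
  expect_false(v2$pass); expect_equal(v2$n_met, 1)
  ## perfect fit
  v3 <- evaluate_unidimensionality(list(RMSEA = 0, SRMR = 0, CFI = 1, TLI = 1))
  expect_true(v3$pass); expect_equal(v3$n_met, 3)
  ## RMSEA in (0.06, 0.08] counts but is flagged acceptable
  v4 <- evaluate_unidimensionality(list(RMSEA = 0.07, SRMR = 0.07, CFI = 0.9, TLI = 0.9))
  expect_true(v4$pass); expect_true(v4$rmsea_acceptable)
  ## missing member is skipped, logged, and cannot silently pass
  v5 <- evaluate_unidimensionality(list(RMSEA = 0.05, SRMR = NA, CFI = 1, TLI = 1))
  expect_true(v5$pass)
  expect_match(v5$notes, "SRMR")
})

test_that("local independence passes on either branch and always lists flags", {
  mk_rc <- function(vals, J = 5) {
    R <- diag(J); R[upper.tri(R)] <- vals; R[lower.tri(R)] <- t(R)[lower.tri(R)]
    ut <- upper.tri(R)
    pairs <- which(ut & abs(R) >= 0.2, arr.ind = TRUE)
    structure(list(matrix = R, q3 = unname(quantile(R[ut], 0.75)),
                   flagged = data.frame(item_a = pairs[, 1], item_b = pairs[, 2],
                                        r = R[pairs])),
              class = "residual_correlations")
  }
  expect_true(evaluate_local_independence(mk_rc(rep(0.1, 10)))$pass)
  ## one pair at 0.35 with a low quartile: pass with the pair flagged
  v <- evaluate_local_independence(mk_rc(c(0.35, rep(0.05, 9))))
  expect_true(v$pass); expect_equal(nrow(v$flagged), 1)
  ## both branches violated
  expect_false(evaluate_local_independence(mk_rc(c(rep(0.5, 5), rep(0.1, 5))))$pass)
})

test_that("monotonicity rule combines scalability and criticality bands", {
  mk_k <- function(H_i) structure(list(H = mean(H_i), H_i = H_i),
                                  class = "mokken_report")
  mk_v <- function(crit) structure(list(crit = crit,
                                        violations = data.frame()[seq_along(crit), ]),
                                   class = "monotonicity_report")
  H_ok <- stats::setNames(seq(0.41, 0.57, length.out = 7), paste0("i", 1:7))
  ## one small-crit violation: pass
  v <- evaluate_monotonicity(mk_k(H_ok), mk_v(stats::setNames(c(6, rep(0, 6)), paste0("i", 1:7))))
  expect_true(v$pass)
  ## 8 of 20 items below threshold: fail
  H_bad <- stats::setNames(c(rep(0.15, 8), rep(0.45, 12)), paste0("i", 1:20))
  v2 <- evaluate_monotonicity(mk_k(H_bad), NULL)
  expect_false(v2$pass); expect_equal(v2$n_low, 8)
  ## crit above 90 fails even with good scalability
  v3 <- evaluate_monotonicity(mk_k(H_ok), mk_v(stats::setNames(c(95, rep(0, 6)), paste0("i", 1:7))))
  expect_false(v3$pass)
  ## crit in [40, 90] is annotated acceptable and passes
  v4 <- evaluate_monotonicity(mk_k(H_ok), mk_v(stats::setNames(c(55, rep(0, 6)), paste0("i", 1:7))))
  expect_true(v4$pass); expect_equal(v4$acceptable_violation_items, "i1")
  ## boundary: H_i exactly 0.3 is not above the threshold
  H_edge <- stats::setNames(c(0.3, 0.45), c("a", "b"))
  expect_false(evaluate_monotonicity(mk_k(H_edge), NULL)$pass)
  expect_true(evaluate_monotonicity(mk_k(H_edge), NULL, graph_override = TRUE)$pass)
})

test_that("global fit requires unidimensionality and in-range infits", {
  uni_pass <- list(pass = TRUE); uni_fail <- list(pass = FALSE)
  inf_ok <- list(item = stats::setNames(seq(0.8, 0.9, length.out = 5), paste0("i", 1:5)))
  expect_true(evaluate_global_fit(uni_pass, inf_ok)$pass)
  expect_false(evaluate_global_fit(uni_fail, inf_ok)$pass)
  inf_bad <- list(item = stats::setNames(c(0.4, rep(1, 4)), paste0("i", 1:5)))
  v <- evaluate_global_fit(uni_pass, inf_bad)
  expect_false(v$pass); expect_equal(v$out_of_range_items, "i1")
  ## boundaries 0.5 and 1.5 are inclusive
  inf_edge <- list(item = c(a = 0.5, b = 1.5))
  expect_true(evaluate_global_fit(uni_pass, inf_edge)$pass)
})

test_that("loading flags use the 0.3/0.5 cut points", {
  fl <- loading_flags(c(i1 = 0.18, i2 = 0.45, i3 = 0.94, i4 = 0.3, i5 = 0.5))
  expect_equal(unname(fl), c("below", "positive", "very_positive", "below", "positive"))
})

test_that("compiled verdicts are total and carry reason codes", {
  ok <- list(pass = TRUE)
  rel <- list(alpha = 0.9, omega_total = 0.91, rating = "excellent")
  v <- compile_verdict(ok, ok, ok, ok, rel)
  expect_equal(v$overall, "supported"); expect_length(v$reasons, 0)
  v2 <- compile_verdict(ok, ok, list(pass = FALSE), ok, rel)
  expect_equal(v2$overall, "not_supported")
  expect_equal(v2$reasons, "fail:monotonicity")
  ## missing component: incomplete, never a silent pass
  v3 <- compile_verdict(NULL, ok, ok, ok, rel)
  expect_equal(v3$overall, "incomplete")
  expect_match(v3$reasons, "unidimensionality")
  ## reliability requirement is configurable
  rel_bad <- list(rating = "inadequate")
  expect_equal(compile_verdict(ok, ok, ok, ok, rel_bad)$overall, "not_supported")
  expect_equal(compile_verdict(ok, ok, ok, ok, rel_bad,
                               require_reliability = FALSE)$overall, "supported")
})

test_that("verdicts are pure functions of their inputs", {
  fix_stats <- list(RMSEA = 0.041, SRMR = 0.03, CFI = 0.99, TLI = 0.985)
  expect_identical(evaluate_unidimensionality(fix_stats),
                   evaluate_unidimensionality(fix_stats))
})
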