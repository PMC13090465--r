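test_that("loading conversion follows the normal-ogive link", {
  p1 <- list(x = grm_item_params("x", a = 1.702, b = 0))
  expect_equal(irt_to_loadings(p1)$loading, 1 / sqrt(2), tolerance = 1e-12)
  ## lambda -> 1 monotonically as a grows; tiny a gives tiny lambda
  avals <- c(1e-6, 0.5, 1, 2, 5, 50)
  l <- vapply(avals, function(a)
    irt_to_loadings(list(x = grm_item_params("x", a, 0)))$loading, 0)
  expect_true(!is.unsorted(l))
  expect_lt(l[1], 1e-6)
  expect_lt(max(l), 1)
  ls <- irt_to_loadings(list(x = grm_item_params("x", 1.3, 0)))
  expect_equal(ls$loading^2 + ls$uniqueness, 1)
})

test_that("fit indices from an M2 statistic follow the closed forms", {
  fi <- fit_indices_from_m2(M2 = 120, df = 100, n = 1001, M2_b = 2100, df_b = 120)
  expect_equal(fi$RMSEA, sqrt(20 / 1e5), tolerance = 1e-12)
  expect_equal(fi$CFI, 1 - 20 / 1980, tolerance = 1e-12)
  ## exact fit: zero error of approximation, incremental indices capped at 1
  fi0 <- fit_indices_from_m2(M2 = 100, df = 100, n = 500, M2_b = 900, df_b = 120)
  expect_equal(fi0$RMSEA, 0)
  expect_equal(fi0$CFI, 1)
  expect_equal(fi0$TLI, 1)
  fi_neg <- fit_indices_from_m2(M2 = 80, df = 100, n = 500, M2_b = 900, df_b = 120)
  expect_equal(fi_neg$RMSEA, 0)
  expect_error(fit_indices_from_m2(10, 5, 100, 20, 1), "baseline")
})

test_that("the M2-type statistic is calibrated under the model and powered against misfit", {
  pars <- tiny_params(6, K = 3)
  m <- simulate_tiny(pars, n = 2000, seed = 101)
  cal <- fit_grm(m, names(pars))
  m2 <- m2_statistic(m, cal)
  expect_equal(m2$df, m2$s - m2$q)
  expect_equal(m2$df, (6 * 2 + 15) - 6 * 3)   # ind cats + pairs - params
  expect_gte(m2$M2, 0)
  expect_gt(m2$p_value, 0.001)                # no spurious rejection here

  ## two independent traits, one-factor fit: strong rejection
  ids <- paste0("t", 1:6)
  thA <- scalenorm:::withr_seed(7, stats::rnorm(2000))
  thB <- scalenorm:::withr_seed(8, stats::rnorm(2000))
  pA <- tiny_params(3, K = 3, ids = ids[1:3])
  pB <- tiny_params(3, K = 3, ids = ids[4:6])
  mA <- simulate_responses(thA, pA, seed = 9)
  mB <- simulate_responses(thB, pB, seed = 10)
  spec <- tiny_spec(6, 3)
  m2f <- response_matrix(cbind(mA$responses, mB$responses), spec)
  cal2 <- fit_grm(m2f, ids)
  expect_lt(m2_statistic(m2f, cal2)$p_value, 0.01)

  ## df guard: too few items
  pars3 <- tiny_params(3, K = 3)
  m3 <- simulate_tiny(pars3, n = 400, seed = 11)
  cal3 <- fit_grm(m3, names(pars3))
  expect_error(m2_statistic(m3, cal3), "degrees of freedom")
})

test_that("SRMR is small under the model and invariant to item order", {
  pars <- tiny_params(5, K = 3)
  m <- simulate_tiny(pars, n = 2000, seed = 111)
  cal <- fit_grm(m, names(pars))
  s1 <- srmr(m, cal)
  expect_lt(s1, 0.05)
  cal_perm <- fit_grm(m, rev(names(pars)))
  expect_equal(srmr(m, cal_perm), s1, tolerance = 2e-3)
})

test_that("residual correlations flag injected local dependence", {
  pars <- tiny_params(5, K = 3)
  m <- simulate_tiny(pars, n = 2000, seed = 121)
  ## duplicate an item: maximal residual dependence for that pair
  spec <- tiny_spec(6, 3)
  dup <- cbind(m$responses, t6 = m$responses[, "t5"])
  md <- response_matrix(dup, spec)
  cald <- fit_grm(md, paste0("t", 1:6))
  rc <- residual_correlations(md, cald)
  expect_true(nrow(rc$flagged) >= 1)
  top <- rc$flagged[1, ]
  expect_setequal(unlist(top[c("item_a", "item_b")]), c("t5", "t6"))
  expect_equal(max(abs(rc$matrix[upper.tri(rc$matrix)])), abs(top$r))

  ## clean data: nothing flagged, matrix symmetric
  cal <- fit_grm(m, names(pars))
  rc0 <- residual_correlations(m, cal)
  expect_equal(nrow(rc0$flagged), 0)
  expect_equal(rc0$matrix, t(rc0$matrix))
})
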