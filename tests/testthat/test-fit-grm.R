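test_that("EM recovers generating parameters and never decreases the log-likelihood", {
  pars <- tiny_params(5, K = 3)
  m <- simulate_tiny(pars, n = 1500, seed = 21)
  cal <- fit_grm(m, names(pars))
  expect_true(cal$converged)
  expect_true(all(diff(cal$loglik_trace) > -1e-8))
  ahat <- vapply(cal$params, `[[`, 0, "a")
  atru <- vapply(pars, `[[`, 0, "a")
  expect_lt(sqrt(mean((ahat - atru)^2)), 0.3)
  bhat <- unlist(lapply(cal$params, `[[`, "b"))
  btru <- unlist(lapply(pars, `[[`, "b"))
  expect_lt(sqrt(mean((bhat - btru)^2)), 0.15)
  ## ML optimality: fitted parameters dominate the truth on the same data/grid
  expect_gte(cal$log_marginal_likelihood, grm_loglik(m, pars, cal$grid))
})

test_that("degenerate items are rejected with the item named", {
  pars <- tiny_params(3, K = 3)
  m <- simulate_tiny(pars, n = 200, seed = 5)
  m$responses[, "t2"] <- 1L
  expect_error(fit_grm(m, names(pars)), "t2",
               class = "scalenorm_calibration_error")
})

test_that("binary items run through the same path as a two-parameter logistic model", {
  pars <- tiny_params(4, K = 2, a = c(1, 1.5, 2, 2.5))
  m <- simulate_tiny(pars, n = 1500, seed = 31)
  cal <- fit_grm(m, names(pars))
  expect_true(cal$converged)
  ## K = 2 category probabilities are the 2PL item response function
  p <- grm_category_probs(0.7, cal$params$t3)
  expect_equal(p[1, 2], stats::plogis(cal$params$t3$a * (0.7 - cal$params$t3$b)))
  expect_lt(sqrt(mean((vapply(cal$params, `[[`, 0, "a") -
                         vapply(pars, `[[`, 0, "a"))^2)), 0.35)
})

test_that("GRSM is a constrained GRM and nests correctly", {
  ## generate from a shared-step structure
  t_steps <- c(-0.4, 0.8)
  d <- c(0, 0.4, -0.3, 0.7)
  ids <- paste0("t", 1:4)
  pars <- lapply(1:4, function(j)
    grm_item_params(ids[j], a = 1.2 + 0.3 * j, b = d[j] + t_steps))
  names(pars) <- ids
  m <- simulate_tiny(pars, n = 1200, seed = 41)
  cal_g <- fit_grm(m, ids, model = "grm")
  cal_r <- fit_grm(m, ids, model = "grsm")
  expect_true(cal_r$converged)
  ## same-K structure: shared steps plus location reproduce the thresholds
  expect_equal(length(cal_r$grsm_par$t), 2)
  ## nesting: the free model cannot have lower marginal likelihood
  expect_gte(cal_g$log_marginal_likelihood,
             cal_r$log_marginal_likelihood - 1e-6)
  ## on GRSM-generated data the constrained fit is close to the free fit
  expect_lt((cal_g$log_marginal_likelihood - cal_r$log_marginal_likelihood) /
              abs(cal_g$log_marginal_likelihood), 0.005)
  ## and recovers the generating discriminations
  expect_lt(max(abs(vapply(cal_r$params, `[[`, 0, "a") -
                      vapply(pars, `[[`, 0, "a"))), 0.35)
  expect_error(fit_grm(psc_fixture()$responses,
                       c("item1", "item2"), model = "grsm"), NA)
})

test_that("pattern collapsing leaves results identical to per-person EM", {
  ## duplicated persons double the log-likelihood exactly
  pars <- tiny_params(3, K = 3)
  m1 <- simulate_tiny(pars, n = 300, seed = 51)
  spec <- tiny_spec(3, 3)
  m2 <- response_matrix(rbind(m1$responses, m1$responses), spec)
  cal1 <- fit_grm(m1, names(pars))
  cal2 <- fit_grm(m2, names(pars))
  expect_equal(2 * cal1$log_marginal_likelihood, cal2$log_marginal_likelihood,
               tolerance = 1e-6)
  expect_equal(vapply(cal1$params, `[[`, 0, "a"),
               vapply(cal2$params, `[[`, 0, "a"), tolerance = 1e-3)
})
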