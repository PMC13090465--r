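test_that("latent traits are reproducible and match the design moments", {
  strata <- data.frame(age_group = c("6-9", "6-9"), gender = c("f", "m"),
                       n = c(50000L, 50000L), trait_shift = c(0, 0.5))
  des <- simulation_design(strata, tiny_params(3), seed = 11)
  th1 <- simulate_theta(des)
  th2 <- simulate_theta(des)
  expect_identical(th1, th2)
  f <- th1$theta[th1$gender == "f"]
  m <- th1$theta[th1$gender == "m"]
  ## CLT bounds at n = 5e4 per stratum
  expect_lt(abs(mean(f)), 0.02)
  expect_lt(abs(stats::sd(f) - 1), 0.02)
  expect_lt(abs(mean(m) - 0.5), 0.02)
})

test_that("simulated category frequencies match the GRM probabilities", {
  it <- grm_item_params("t1", a = 2, b = c(-1, 1))
  n <- 1e5
  m <- simulate_responses(rep(0, n), list(t1 = it), seed = 3)
  freq <- tabulate(m$responses[, 1] + 1L, 3) / n
  expect_equal(freq, c(0.1192, 0.7616, 0.1192), tolerance = 0.01)
  ## extreme trait loads the top category
  m2 <- simulate_responses(rep(6, 1e4), list(t1 = grm_item_params("t1", 1, c(-1, 0, 1))),
                           seed = 4)
  expect_gt(mean(m2$responses[, 1] == 3), 0.99)
  ## determinism
  m3 <- simulate_responses(rep(0, 100), list(t1 = it), seed = 3)
  m4 <- simulate_responses(rep(0, 100), list(t1 = it), seed = 3)
  expect_identical(m3$responses, m4$responses)
  expect_error(simulate_responses(0, list(t1 = list(item_id = "t1", a = 1, b = c(1, 0)))),
               "unordered|increasing")
})

test_that("adding an item does not perturb earlier items' draws", {
  p2 <- tiny_params(2)
  p3 <- c(p2, tiny_params(1, ids = "t3"))
  m2 <- simulate_responses(rep(0.3, 500), p2, seed = 9)
  m3 <- simulate_responses(rep(0.3, 500), p3, seed = 9)
  expect_identical(m2$responses[, c("t1", "t2")], m3$responses[, c("t1", "t2")])
})

test_that("fixture presets reproduce the study cohort shapes", {
  fix <- psc_fixture()
  expect_equal(dim(fix$responses), c(1356L, 17L))
  tab <- table(fix$responses$age_group)
  expect_equal(as.integer(tab[c("6-9", "10-13", "14-18")]), c(416L, 415L, 525L))
  expect_setequal(names(fix$truth), c("externalizing", "internalizing", "attention"))
  ## strata counts exactly match the design
  expect_equal(sum(fix$responses$gender == "female"), 636L)

  cats <- make_fixture_cohort("cats2-self-like", seed = 2)
  expect_equal(dim(cats$responses), c(137L, 20L))

  mc <- make_fixture_cohort("mchat-like", seed = 2)
  expect_equal(dim(mc$responses), c(200L, 20L))
  expect_true(all(mc$responses$responses %in% 0:1))
  expect_error(make_fixture_cohort("nope"), "arg")
})

test_that("a preset rerun with the same seed gives a byte-identical CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(make_fixture_cohort("mchat-like", seed = 5)$responses, f1)
  write_responses(make_fixture_cohort("mchat-like", seed = 5)$responses, f2)
  expect_identical(readLines(f1), readLines(f2))
})
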