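test_that("all six bundled instrument specs load with the published structures", {
  keys <- names(bundled_instruments())
  expect_setequal(keys, c("psc17", "rcads25", "snap_iv", "mchat_rf", "cast", "cats2"))

  psc <- bundled_instruments("psc17")
  expect_equal(nrow(psc$items), 17)
  expect_equal(lengths(psc$subscales),
               c(externalizing = 7L, internalizing = 5L, attention = 5L))
  expect_equal(psc$subscales$externalizing,
               paste0("item", c(4, 5, 8, 10, 12, 14, 16)))
  expect_equal(psc$subscales$internalizing, paste0("item", c(2, 6, 9, 11, 15)))
  expect_equal(psc$subscales$attention, paste0("item", c(1, 3, 7, 13, 17)))
  expect_true(all(psc$items$n_categories == 3))

  snap <- bundled_instruments("snap_iv")
  expect_equal(nrow(snap$items), 26)
  expect_equal(unname(lengths(snap$subscales)), c(9L, 5L, 4L, 8L))

  cast <- bundled_instruments("cast")
  expect_equal(nrow(cast$items), 28)
  expect_equal(lengths(cast$subscales),
               c(social_contact = 16L, inflexible_repetitive = 12L))
  expect_true("item37" %in% cast$items$item_id)  # original numbering kept
  expect_true(all(cast$items$n_categories == 2))

  expect_equal(nrow(bundled_instruments("mchat_rf")$items), 20)
  expect_equal(nrow(bundled_instruments("rcads25")$items), 25)
  cats <- bundled_instruments("cats2")
  expect_equal(nrow(cats$items), 20)
  expect_true(all(cats$items$n_categories == 4))
})

test_that("spec validation rejects structural errors", {
  items <- data.frame(item_id = c("a", "b", "c"), n_categories = 3)
  expect_error(instrument_spec("x", items, list(s = c("a", "99"))),
               "unknown item")
  expect_error(instrument_spec("x", items, list(s = c("a", "a"))), "repeats")
  expect_error(instrument_spec("x", items, list(s = "a")), "fewer than 2")
  expect_error(
    instrument_spec("x", data.frame(item_id = c("a", "a"), n_categories = 3),
                    list(s = c("a", "a"))), "duplicated")
  ## malformed file names the offending field
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("name: broken\nitems: [a, b]", f)
  expect_error(load_instrument_spec(f), "subscales")
})

test_that("responses round-trip through CSV exactly, with covariates", {
  spec <- bundled_instruments("psc17")
  set.seed(42)
  m <- matrix(sample(0:2, 5 * 17, replace = TRUE), 5,
              dimnames = list(NULL, spec$items$item_id))
  rm1 <- response_matrix(m, spec, age_group = c("6-9", "6-9", "10-13", "14-18", "14-18"),
                         gender = c("f", "m", "f", "m", "f"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm1, f)
  rm2 <- read_responses(f, spec)
  expect_identical(rm2$responses, rm1$responses)
  expect_identical(rm2$age_group, rm1$age_group)
  expect_identical(rm2$gender, rm1$gender)
  expect_identical(dim(rm2), c(5L, 17L))
})

test_that("out-of-range, missing and origin-shifted input are handled", {
  spec <- tiny_spec(3, K = 3)
  df <- data.frame(t1 = c(0, 1), t2 = c(2, 3), t3 = c(1, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_responses(f, spec), "range.*t2|t2.*range",
               class = "scalenorm_range_error")

  ## 1-based source coding shifted at ingest
  df14 <- data.frame(t1 = c(1, 3), t2 = c(2, 1), t3 = c(3, 2))
  utils::write.csv(df14, f, row.names = FALSE)
  expect_message(m <- read_responses(f, spec, origin = 1), "shifted")
  expect_equal(unname(m$responses[1, ]), c(0L, 1L, 2L))

  ## blank cell: hard reject by default, listwise on request
  writeLines("t1,t2,t3\n0,1,2\n1,,0\n2,2,2\n0,0,0\n1,2,0", f)
  expect_error(read_responses(f, spec), class = "scalenorm_missing_error")
  expect_message(m2 <- read_responses(f, spec, missing = "listwise"),
                 "listwise-deleted 1 person")
  expect_equal(nrow(m2$responses), 4)
})

test_that("sum_scores is exact, permutation-invariant and additive", {
  spec <- bundled_instruments("psc17")
  int <- spec$subscales$internalizing
  m0 <- response_matrix(matrix(0L, 3, 17,
                               dimnames = list(NULL, spec$items$item_id)), spec)
  expect_equal(sum_scores(m0, int), c(0L, 0L, 0L))
  mmax <- response_matrix(matrix(2L, 3, 17,
                                 dimnames = list(NULL, spec$items$item_id)), spec)
  expect_equal(sum_scores(mmax, int), c(10L, 10L, 10L))  # 5 items, K=3

  set.seed(7)
  mr <- response_matrix(matrix(sample(0:2, 6 * 17, TRUE), 6,
                               dimnames = list(NULL, spec$items$item_id)), spec)
  expect_equal(sum_scores(mr, int), sum_scores(mr, rev(int)))
  expect_equal(sum_scores(mr, spec$items$item_id),
               sum_scores(mr, spec$subscales$externalizing) +
                 sum_scores(mr, int) + sum_scores(mr, spec$subscales$attention))
  ## worked arithmetic example
  m1 <- response_matrix(matrix(c(1L, 0L, 2L, 1L, 1L), 1,
                               dimnames = list(NULL, int)), spec)
  expect_equal(sum_scores(m1, int), 5L)
  expect_error(sum_scores(mr, character(0)), "empty")
})
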