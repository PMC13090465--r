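test_that("standardization anchors T at the group mean and sd", {
  th <- c(-1, 0, 1, 2, 0.5, -0.5)
  z <- suppressWarnings(standardize_scores(th, rep("g", 6)))
  expect_equal(mean(z$T), 50)
  expect_equal(stats::sd(z$T), 10)
  ## a trait one group-sd above the group mean maps to T = 60
  th2 <- rep(c(-1, 1), 20)
  z2 <- standardize_scores(th2, rep("g", 40))
  expect_equal(z2$T, 50 + 10 * (th2 - mean(th2)) / stats::sd(th2))
  expect_equal(max(z2$Z) - min(z2$Z) > 0, TRUE)
  expect_error(standardize_scores(c(1), "solo"), "fewer than 2")
  expect_error(suppressWarnings(standardize_scores(c(1, 1, 1), rep("g", 3))),
               "zero trait")
  expect_warning(standardize_scores(rnorm(10), rep("g", 10)), "unstable")
})

test_that("severity bands partition the T line at the printed boundaries", {
  expect_equal(promis_band(54.9), "minimal")
  expect_equal(promis_band(55), "mild")
  expect_equal(promis_band(59), "mild")
  expect_equal(promis_band(60), "moderate")
  expect_equal(promis_band(69), "moderate")
  expect_equal(promis_band(70), "severe")
  ## every T maps to exactly one band
  Ts <- seq(10, 110, by = 0.1)
  expect_true(all(promis_band(Ts) %in% c("minimal", "mild", "moderate", "severe")))
})

test_that("display rescaling truncates within bands without changing membership", {
  br <- band_rescale(c(120, 55, 54.9, 10, 69.5))
  expect_equal(br$band, c("severe", "mild", "minimal", "minimal", "moderate"))
  expect_equal(br$T_display, c(80, 55, 54.9, 20, 69.5))
  ## monotone: rescaling preserves (weak) rank order
  Ts <- sort(stats::runif(50, 5, 115))
  expect_true(!is.unsorted(band_rescale(Ts)$T_display))
})

test_that("crude-score linking is monotone and centered on the cohort", {
  fix <- psc_fixture()
  sub <- fix$spec$subscales$internalizing
  m <- fix$responses
  cal <- fit_grm(m, sub)
  sc <- eap_scores(m, cal)
  link <- link_summed_scores(cal, sc$theta_eap, sum_scores(m, sub))
  expect_equal(link$crude, 0:10)        # 5 items, K = 3
  expect_true(!is.unsorted(link$T))
  expect_true(!is.unsorted(link$percentile))
  expect_true(all(link$percentile >= 0 & link$percentile <= 100))
  ## the median crude score sits near the center of the T scale
  med <- link$T[link$crude == stats::median(sum_scores(m, sub))]
  expect_lt(abs(med - 50), 4)
})

test_that("norm tables cover every crude score per group and flag instability", {
  fix <- psc_fixture()
  sub <- fix$spec$subscales$internalizing
  m <- fix$responses
  cal <- fit_grm(m, sub)
  nt <- build_norm_table(m, cal)
  expect_s3_class(nt, "norm_table")
  expect_equal(sort(unique(nt$crude)), 0:10)
  expect_equal(length(unique(nt$group)), 6)   # 3 age bands x 2 genders
  for (g in unique(nt$group)) {
    rows <- nt[nt$group == g, ]
    expect_equal(rows$crude, 0:10)
    expect_true(!is.unsorted(rows$T))
    expect_true(!is.unsorted(rows$T_display))
  }
  expect_true(all(!nt$unstable))
  ## small-cell pooling kicks in on a tiny cohort
  small <- make_fixture_cohort("cats2-self-like", seed = 3)
  cal_s <- fit_grm(small$responses, small$spec$subscales$ptsd_symptoms)
  expect_message(nt_s <- suppressWarnings(build_norm_table(small$responses, cal_s)),
                 "pooling across gender")
  expect_true(any(grepl("pooled", unique(nt_s$group))))
  expect_true(any(nt_s$unstable))   # pooled 6-9 cell is still below 30
})
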