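## Null-calibration / parameter-recovery battery: 20 cohorts of n = 2000
## drawn from the cats2-self-like generating parameters (20 four-category
## items), each refitted with the same model. Computed once and cached for
## the acceptance blocks.

battery_params <- function() make_fixture_cohort("cats2-self-like", seed = 1)$truth$ptsd_symptoms$params

run_battery <- function(n = 2000L, seeds = 1000L + 1:20) {
  pars <- battery_params()
  spec <- bundled_instruments("cats2")
  atru <- vapply(pars, `[[`, 0, "a")
  btru <- unlist(lapply(pars, `[[`, "b"))
  res <- lapply(seeds, function(s) {
    th <- simulate_theta(simulation_design(
      data.frame(age_group = "all", gender = "all", n = n), pars, seed = s))
    m <- simulate_responses(th, pars, seed = s, spec = spec)
    cal <- fit_grm(m, names(pars))
    sc <- eap_scores(m, cal)
    inf <- infit_mean_squares(m, cal, sc)
    rc <- residual_correlations(m, cal, sc)
    mono <- monotonicity_check(m, names(pars))
    m2 <- m2_statistic(m, cal)
    list(a_err = vapply(cal$params, `[[`, 0, "a") - atru,
         b_err = unlist(lapply(cal$params, `[[`, "b")) - btru,
         loglik_monotone = all(diff(cal$loglik_trace) > -1e-8),
         converged = cal$converged,
         p_value = m2$p_value,
         infit_range = range(inf$item),
         resid_max = max(abs(rc$matrix[upper.tri(rc$matrix)])),
         n_violations = nrow(mono$violations))
  })
  res
}

battery <- function() cached("battery", run_battery())
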