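## shared fixtures, computed once per test run

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

psc_fixture <- function() cached("psc17", make_fixture_cohort("psc17-like", seed = 1))

## small instrument spec for targeted tests
tiny_spec <- function(J = 5, K = 3, name = "tiny") {
  instrument_spec(name,
                  items = data.frame(item_id = paste0("t", seq_len(J)),
                                     n_categories = K),
                  subscales = if (J >= 2) list(all = paste0("t", seq_len(J)))
                              else list())
}

## simple strong item set
tiny_params <- function(J = 5, K = 3, a = NULL, ids = paste0("t", seq_len(J))) {
  a <- a %||% seq(1.2, 2.2, length.out = J)
  lapply(seq_len(J), function(j) {
    b1 <- -0.8 + 1.4 * (j - 1) / max(J - 1, 1)
    grm_item_params(ids[j], a = a[j], b = b1 + 0.9 * (seq_len(K - 1) - 1))
  }) |> stats::setNames(ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## calibration object wrapper around known parameters (for oracle tests)
cal_from_params <- function(params, grid = quadrature_grid()) {
  structure(list(params = params, item_ids = names(params), model = "grm",
                 grid = grid, converged = TRUE, n_persons = NA_integer_),
            class = "grm_calibration")
}

simulate_tiny <- function(params, n, seed, spec = NULL, theta = NULL) {
  theta <- theta %||% scalenorm:::withr_seed(seed * 7 + 1, stats::rnorm(n))
  simulate_responses(theta, params, seed = seed, spec = spec)
}
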