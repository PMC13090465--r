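#' Simulation design for a synthetic cohort
#'
#' Describes the strata (age group x gender counts, optional latent-trait
#' mean shifts) and the generating item parameters of a synthetic cohort.
#'
#' @param strata data.frame with columns `age_group`, `gender`, `n`
#'   (counts >= 0) and optionally `trait_shift` (default 0).
#' @param item_params named list of [grm_item_params()].
#' @param seed root integer seed; per-stage substreams are derived from it
#'   so that e.g. adding items does not perturb earlier draws.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(strata, item_params, seed = 1L) {
  stopifnot(is.data.frame(strata), all(c("age_group", "gender", "n") %in% names(strata)))
  if (any(strata$n < 0)) abort("stratum counts must be >= 0")
  if (is.null(strata$trait_shift)) strata$trait_shift <- 0
  for (p in item_params)
    if (is.unsorted(p$b, strictly = TRUE)) abort("unordered thresholds for item ", p$item_id)
  if (is.null(names(item_params)))
    names(item_params) <- vapply(item_params, `[[`, "", "item_id")
  structure(list(strata = strata, item_params = item_params,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate latent traits for a design
#'
#' Draws each stratum's traits from N(shift, 1). Reproducible: the same
#' design (including seed) always yields the same vector, and each stratum
#' has its own substream.
#'
#' @param design a [simulation_design()].
#' @return data.frame with `person_id`, `age_group`, `gender`, `theta`.
#' @export
simulate_theta <- function(design) {
  out <- vector("list", nrow(design$strata))
  for (i in seq_len(nrow(design$strata))) {
    s <- design$strata[i, ]
    seed_i <- substream_seed(design$seed, paste("theta", s$age_group, s$gender))
    th <- withr_seed(seed_i, stats::rnorm(s$n, mean = s$trait_shift, sd = 1))
    out[[i]] <- data.frame(age_group = rep(s$age_group, s$n),
                           gender = rep(s$gender, s$n), theta = th)
  }
  df <- do.call(rbind, out)
  df <- cbind(person_id = paste0("p", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  df
}

## run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate GRM responses at given trait values
#'
#' Each response is sampled from the graded-response category distribution
#' at the person's theta. Item draws use per-item substreams of the root
#' seed.
#'
#' @param theta numeric vector of latent traits (or the data.frame from
#'   [simulate_theta()]).
#' @param params named list of [grm_item_params()].
#' @param seed root integer seed.
#' @param spec optional [instrument_spec()]; if omitted a minimal synthetic
#'   spec covering the simulated items is built.
#' @param age_group,gender per-person labels; taken from `theta` when it is
#'   a [simulate_theta()] data.frame.
#' @return A [response_matrix()] with no missing cells.
#' @export
simulate_responses <- function(theta, params, seed = 1L, spec = NULL,
                               age_group = "all", gender = "all") {
  if (is.data.frame(theta)) {
    age_group <- theta$age_group; gender <- theta$gender; theta <- theta$theta
  }
  if (is.null(names(params)))
    names(params) <- vapply(params, `[[`, "", "item_id")
  n <- length(theta)
  m <- matrix(0L, n, length(params), dimnames = list(NULL, names(params)))
  for (j in seq_along(params)) {
    p <- params[[j]]
    if (is.unsorted(p$b, strictly = TRUE)) abort("unordered thresholds for item ", p$item_id)
    cum <- grm_boundary_probs(theta, p$a, p$b)            # n x K-1, P(X >= k)
    u <- withr_seed(substream_seed(seed, paste("resp", p$item_id)),
                    stats::runif(n))
    m[, j] <- as.integer(rowSums(u < cum))
  }
  spec <- spec %||% instrument_spec(
    "synthetic",
    items = data.frame(item_id = names(params),
                       n_categories = vapply(params, `[[`, 0L, "n_categories")),
    subscales = if (length(params) >= 2) list(all = names(params)) else list())
  response_matrix(m, spec, age_group = age_group, gender = gender)
}

## deterministic "realistic symptom scale" parameter sets, frozen per preset.
## Discriminations sit in ranges that convert to factor loadings around
## 0.55-0.93; thresholds are right-shifted, as community symptom data are.
preset_params <- function(item_ids, K, weak_idx = integer(0), seed_const,
                          a_range = c(1.4, 2.4)) {
  J <- length(item_ids)
  draw <- withr_seed(seed_const, {
    a <- stats::runif(J, a_range[1], a_range[2])
    weak <- seq_len(J) %in% weak_idx
    if (any(weak)) a[weak] <- stats::runif(sum(weak), 0.1, 0.4)
    b1 <- stats::runif(J, -0.5, 0.6)
    b1[weak] <- stats::runif(sum(weak), -2.5, 2.5)  # weak items also extreme
    steps <- matrix(stats::runif(J * (K - 2), 0.6, 0.95), J)
    list(a = a, b1 = b1, steps = steps)
  })
  out <- lapply(seq_len(J), function(j) {
    b <- draw$b1[j] + c(0, cumsum(draw$steps[j, ]))
    grm_item_params(item_ids[j], a = draw$a[j], b = b)
  })
  names(out) <- item_ids
  out
}

#' Preset synthetic fixture cohorts
#'
#' Builds a cohort with the statistical structure of the study samples,
#' together with its generating parameters for recovery tests:
#'
#' * `"psc17-like"`: 1,356 persons x 17 three-category items in the PSC-17
#'   subscale layout, age strata 6-9/10-13/14-18 crossed with gender.
#'   Each subscale's trait loads 0.8 on a common factor, so subscales are
#'   correlated but each is unidimensional.
#' * `"mchat-like"`: 200 toddlers x 20 binary items, 12 well-discriminating
#'   and 8 weak/extreme items (emulating a screener administered to an
#'   asymptomatic community sample).
#' * `"cats2-self-like"`: 137 persons x 20 four-category items,
#'   unidimensional.
#'
#' @param preset preset name (see above).
#' @param seed root seed for trait and response sampling; the generating
#'   item parameters are fixed properties of the preset and do not depend
#'   on it.
#' @return list with `responses` (a [response_matrix()]), `truth` (named
#'   list of generating [grm_item_params()] per subscale plus the latent
#'   traits) and `spec` (the matching [instrument_spec()]).
#' @export
make_fixture_cohort <- function(preset = c("psc17-like", "mchat-like",
                                           "cats2-self-like"),
                                seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "psc17-like") {
    spec <- bundled_instruments("psc17")
    strata <- data.frame(
      age_group = rep(c("6-9", "10-13", "14-18"), each = 2),
      gender = rep(c("female", "male"), 3),
      n = c(195L, 221L, 195L, 220L, 246L, 279L))
    design <- simulation_design(strata, list(), seed = seed)
    th <- simulate_theta(design)
    g <- th$theta
    subs <- spec$subscales
    truth <- list(); cols <- list()
    for (s in names(subs)) {
      pars <- preset_params(subs[[s]], K = 3,
                            seed_const = substream_seed(990001, s))
      e <- withr_seed(substream_seed(seed, paste("factor", s)),
                      stats::rnorm(length(g)))
      theta_s <- 0.8 * g + 0.6 * e
      r <- simulate_responses(theta_s, pars, seed = substream_seed(seed, s),
                              spec = spec, age_group = th$age_group,
                              gender = th$gender)
      truth[[s]] <- list(params = pars, theta = theta_s)
      cols[[s]] <- r$responses
    }
    m <- do.call(cbind, cols)[, spec$items$item_id]
    resp <- response_matrix(m, spec, age_group = th$age_group,
                            gender = th$gender, person_ids = th$person_id)
    return(list(responses = resp, truth = truth, spec = spec))
  }
  if (preset == "mchat-like") {
    spec <- bundled_instruments("mchat_rf")
    strata <- data.frame(age_group = "toddler", gender = c("female", "male"),
                         n = c(100L, 100L))
    pars <- preset_params(spec$items$item_id, K = 2,
                          weak_idx = c(1, 2, 3, 5, 12, 14, 17, 19),
                          seed_const = 990101, a_range = c(2.2, 3.6))
  } else {
    spec <- bundled_instruments("cats2")
    strata <- data.frame(age_group = rep(c("6-9", "10-13", "14-18"), each = 2),
                         gender = rep(c("female", "male"), 3),
                         n = c(9L, 10L, 26L, 26L, 30L, 36L))
    pars <- preset_params(spec$items$item_id, K = 4, seed_const = 990201)
  }
  design <- simulation_design(strata, pars, seed = seed)
  th <- simulate_theta(design)
  resp <- simulate_responses(th, pars, seed = seed, spec = spec)
  sub <- names(spec$subscales)[1]
  list(responses = resp,
       truth = stats::setNames(list(list(params = pars, theta = th$theta)), sub),
       spec = spec)
}
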