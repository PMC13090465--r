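#' EAP trait scores
#'
#' Expected a posteriori latent-trait estimate (posterior mean and sd of
#' theta under the standard-normal prior) for every person, integrated on
#' the calibration grid.
#'
#' @param m a [response_matrix()] containing the calibrated items.
#' @param cal a [fit_grm()] calibration.
#' @return data.frame with `person_id`, `theta_eap`, `theta_sd`.
#' @export
eap_scores <- function(m, cal) {
  resp <- m$responses[, cal$item_ids, drop = FALSE]
  check_response_range(resp, cal)
  nodes <- cal$grid$nodes; w <- cal$grid$weights
  ll <- grm_pattern_loglik(resp, cal$params, nodes)
  mx <- apply(ll, 1, max)
  lw <- sweep(exp(ll - mx), 2, w, `*`)
  post <- lw / rowSums(lw)
  eap <- drop(post %*% nodes)
  psd <- sqrt(pmax(drop(post %*% nodes^2) - eap^2, 1e-12))
  data.frame(person_id = m$person_ids, theta_eap = eap, theta_sd = psd)
}

check_response_range <- function(resp, cal) {
  for (j in seq_along(cal$params)) {
    K <- cal$params[[j]]$n_categories
    if (any(resp[, j] < 0 | resp[, j] > K - 1))
      abort("response out of range [0, ", K - 1, "] for item ",
            cal$item_ids[j], class = "scalenorm_range_error")
  }
}

#' Test information curve
#'
#' Sum of the item information functions of a calibration, evaluated on a
#' trait grid.
#'
#' @param cal a [fit_grm()] calibration.
#' @param theta_grid numeric vector of trait values (default: the
#'   calibration grid nodes).
#' @return data.frame with `theta` and `information` (nonnegative).
#' @export
test_information <- function(cal, theta_grid = NULL) {
  theta_grid <- theta_grid %||% cal$grid$nodes
  info <- rowSums(vapply(cal$params,
                         function(p) grm_item_information(theta_grid, p),
                         numeric(length(theta_grid))))
  data.frame(theta = theta_grid, information = info)
}

#' Infit mean squares
#'
#' Information-weighted mean-square residuals: for item j,
#' `infit_j = sum_n (x_nj - E_nj)^2 / sum_n W_nj`, with `E` and `W` the
#' model mean and variance of the item score at the person's EAP trait
#' estimate; person infit is the analogous ratio over items. Values near 1
#' indicate model-consistent residual variation.
#'
#' @param m a [response_matrix()].
#' @param cal a [fit_grm()] calibration.
#' @param scores EAP scores from [eap_scores()] (computed if omitted).
#' @return list with `item` (named numeric) and `person` (numeric) infit
#'   mean squares.
#' @export
infit_mean_squares <- function(m, cal, scores = NULL) {
  scores <- scores %||% eap_scores(m, cal)
  resp <- m$responses[, cal$item_ids, drop = FALSE]
  th <- scores$theta_eap
  E <- V <- matrix(0, nrow(resp), ncol(resp))
  for (j in seq_along(cal$params)) {
    mo <- grm_item_moments(th, cal$params[[j]])
    E[, j] <- mo$mean; V[, j] <- mo$var
  }
  R2 <- (resp - E)^2
  if (sum(V) <= 0) abort("zero model variance; degenerate calibration")
  item <- colSums(R2) / pmax(colSums(V), 1e-12)
  names(item) <- cal$item_ids
  person <- rowSums(R2) / pmax(rowSums(V), 1e-12)
  list(item = item, person = person)
}

#' Summed-score distribution and posterior trait means
#'
#' Lord-Wingersky recursion: at each quadrature node the distribution of
#' the crude summed score is built by convolving item category
#' probabilities; prior-weighting across nodes then gives the marginal
#' score distribution `P(S = s)` and the posterior trait summaries
#' `E[theta | S = s]`, `sd(theta | S = s)` used for crude-score linking.
#'
#' @param cal a [fit_grm()] calibration.
#' @return data.frame with `sum`, `prob` (summing to 1), `theta_eap`,
#'   `theta_sd`, one row per attainable crude score `0..sum(K_j - 1)`.
#' @export
summed_score_posterior <- function(cal) {
  nodes <- cal$grid$nodes; w <- cal$grid$weights; Q <- length(nodes)
  smax <- sum(vapply(cal$params, function(p) p$n_categories - 1L, 0L))
  FF <- matrix(0, 1, Q); FF[1, ] <- 1          # P(S = s | theta_q), rows s
  for (p in cal$params) {
    P <- t(grm_category_probs(nodes, p))       # K x Q
    K <- nrow(P)
    Fnew <- matrix(0, nrow(FF) + K - 1, Q)
    for (k in seq_len(K))
      Fnew[(k - 1) + seq_len(nrow(FF)), ] <- Fnew[(k - 1) + seq_len(nrow(FF)), ] +
        FF * matrix(P[k, ], nrow(FF), Q, byrow = TRUE)
    FF <- Fnew
  }
  pw <- sweep(FF, 2, w, `*`)
  prob <- rowSums(pw)
  m1 <- drop(pw %*% nodes) / prob
  m2 <- drop(pw %*% nodes^2) / prob
  data.frame(sum = 0:smax, prob = prob, theta_eap = m1,
             theta_sd = sqrt(pmax(m2 - m1^2, 0)))
}
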