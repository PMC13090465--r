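#' Graded response model item parameters
#'
#' Container for one item's discrimination and ordered boundary thresholds
#' on the logistic metric (no 1.702 scaling constant inside the model; the
#' constant enters only when converting discriminations to standardized
#' factor loadings, see [irt_to_loadings()]).
#'
#' @param item_id item identifier.
#' @param a discrimination, a single positive number.
#' @param b ordered boundary thresholds `b_1 < ... < b_{K-1}` (trait units);
#'   length K-1 for an item with K response categories.
#' @return An object of class `grm_item_params`.
#' @examples
#' grm_item_params("item1", a = 1.8, b = c(-0.5, 1.2))
#' @export
grm_item_params <- function(item_id, a, b) {
  if (!is_scalar_number(a) || a <= 0) abort("discrimination `a` must be a positive number for item ", item_id)
  b <- as.numeric(b)
  if (length(b) < 1 || anyNA(b) || any(!is.finite(b)))
    abort("thresholds `b` must be finite for item ", item_id)
  if (is.unsorted(b, strictly = TRUE))
    abort("thresholds must be strictly increasing for item ", item_id,
          " (got ", paste(signif(b, 4), collapse = ", "), ")")
  structure(list(item_id = as.character(item_id), a = a, b = b,
                 n_categories = length(b) + 1L),
            class = "grm_item_params")
}

#' @export
print.grm_item_params <- function(x, ...) {
  cat(sprintf("<grm_item_params> %s: a = %.3f, b = (%s)\n", x$item_id, x$a,
              paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

## cumulative boundary probabilities P(X >= k | theta), k = 1..K-1,
## as a length(theta) x (K-1) matrix
grm_boundary_probs <- function(theta, a, b) {
  stats::plogis(outer(theta, b, function(t, bk) a * (t - bk)))
}

#' GRM category probabilities
#'
#' Category response probabilities of the graded response model,
#' `P(X = k | theta) = sigma(a(theta - b_k)) - sigma(a(theta - b_{k+1}))`
#' with `sigma` the logistic function and boundary conventions
#' `P(X >= 0) = 1`, `P(X >= K) = 0`. Categories are 0-based.
#'
#' @param theta numeric vector of latent-trait values.
#' @param item a [grm_item_params()] object (or a list with `a` and `b`).
#' @return Matrix `length(theta) x K`; each row sums to one.
#' @examples
#' it <- grm_item_params("x", a = 2, b = c(-1, 1))
#' grm_category_probs(0, it)  # (0.1192, 0.7616, 0.1192)
#' @export
grm_category_probs <- function(theta, item) {
  a <- item$a; b <- item$b
  if (is.unsorted(b, strictly = TRUE)) abort("thresholds must be strictly increasing")
  cum <- cbind(1, grm_boundary_probs(theta, a, b), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  ## guard tiny negative round-off
  p[p < 0] <- 0
  p
}

## conditional moments of the item score at each theta:
## E[X|theta], E[X^2|theta], Var[X|theta]
grm_item_moments <- function(theta, item) {
  p <- grm_category_probs(theta, item)
  k <- seq_len(ncol(p)) - 1
  m1 <- drop(p %*% k)
  m2 <- drop(p %*% k^2)
  list(mean = m1, var = pmax(m2 - m1^2, 0), m2 = m2)
}

#' GRM item information function
#'
#' Fisher information of one graded item at each trait value, computed from
#' the category probabilities and their derivatives:
#' `I_j(theta) = sum_k (dP_k/dtheta)^2 / P_k`.
#'
#' @inheritParams grm_category_probs
#' @return numeric vector, nonnegative.
#' @export
grm_item_information <- function(theta, item) {
  a <- item$a; b <- item$b
  cumP <- cbind(1, grm_boundary_probs(theta, a, b), 0)
  ## derivative of each boundary curve: a * P* (1 - P*); boundaries 0 and K fixed
  dcum <- a * cumP * (1 - cumP)
  dcum[, 1] <- 0; dcum[, ncol(dcum)] <- 0
  p <- cumP[, -ncol(cumP), drop = FALSE] - cumP[, -1, drop = FALSE]
  dp <- dcum[, -ncol(dcum), drop = FALSE] - dcum[, -1, drop = FALSE]
  info <- rowSums(ifelse(p > 1e-12, dp^2 / pmax(p, 1e-12), 0))
  pmax(info, 0)
}

## log-likelihood matrix of observed responses at grid nodes:
## returns n_patterns x Q matrix of log prod_j P(x_j | theta_q).
## `resp` is an integer matrix (0-based categories), items in columns,
## `params` a list of grm_item_params aligned with columns.
grm_pattern_loglik <- function(resp, params, nodes) {
  n <- nrow(resp); Q <- length(nodes)
  ll <- matrix(0, n, Q)
  for (j in seq_along(params)) {
    pj <- grm_category_probs(nodes, params[[j]])        # Q x K
    pj <- log(pmax(pj, 1e-300))
    ll <- ll + t(pj[, resp[, j] + 1L, drop = FALSE])    # n x Q
  }
  ll
}
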