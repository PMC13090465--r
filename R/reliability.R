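#' Cronbach's alpha
#'
#' `alpha = p/(p-1) * (1 - sum(var_item) / var_total)` on raw integer item
#' scores, with unbiased (n-1 denominator) sample variances.
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of >= 2 item ids.
#' @return scalar alpha (<= 1; can be negative for inconsistent items).
#' @export
cronbach_alpha <- function(m, subscale) {
  subscale <- as.character(subscale)
  if (length(subscale) < 2) abort("alpha needs at least 2 items")
  x <- m$responses[, subscale, drop = FALSE]
  vt <- stats::var(rowSums(x))
  if (vt <= 0) abort("zero total-score variance")
  p <- ncol(x)
  p / (p - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' McDonald's omega total
#'
#' `omega_t = (sum lambda)^2 / ((sum lambda)^2 + sum psi)` on the
#' standardized one-factor solution. Loadings come from the subscale's IRT
#' calibration via the normal-ogive conversion ([irt_to_loadings()]);
#' supply `cal` to reuse an existing fit, otherwise one is fitted.
#' Heywood-type uniquenesses are floored at `psi_floor` with a warning.
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of item ids.
#' @param cal optional [fit_grm()] calibration for the subscale.
#' @param psi_floor lower bound applied to uniquenesses (default 1e-3).
#' @return scalar omega total in `[0, 1]` for proper solutions.
#' @export
mcdonald_omega_total <- function(m, subscale, cal = NULL, psi_floor = 1e-3) {
  cal <- cal %||% fit_grm(m, subscale)
  l <- irt_to_loadings(cal)
  omega_from_loadings(l$loading, l$uniqueness, psi_floor)
}

#' Omega total from loadings and uniquenesses
#'
#' @param lambda standardized loadings.
#' @param psi uniquenesses (default `1 - lambda^2`).
#' @param psi_floor floor applied to non-positive uniquenesses (flagged
#'   with a warning: Heywood case).
#' @return scalar omega total.
#' @export
omega_from_loadings <- function(lambda, psi = 1 - lambda^2, psi_floor = 1e-3) {
  if (any(psi <= 0)) {
    warning("Heywood case: ", plural(sum(psi <= 0), "uniqueness"),
            " at or below zero", if (any(psi < 0)) paste("; negatives floored at", psi_floor))
    psi[psi < 0] <- psi_floor   # exact zeros (perfect indicators) stay zero
  }
  sum(lambda)^2 / (sum(lambda)^2 + sum(psi))
}

#' Rate internal consistency
#'
#' Thresholds follow the evaluation rubric: the best available coefficient
#' must strictly exceed 0.7 for a positive rating, 0.8 for good, 0.9 for
#' excellent; boundary values (exactly 0.7/0.8/0.9) fall in the lower
#' class.
#'
#' @param alpha,omega_total coefficient values (either may be `NULL`).
#' @return character rating: `"inadequate"`, `"positive"`, `"good"` or
#'   `"excellent"`.
#' @export
reliability_rating <- function(alpha = NULL, omega_total = NULL) {
  vals <- c(alpha, omega_total)
  if (!length(vals)) abort("need alpha or omega_total")
  best <- max(vals)
  if (best > 0.9) "excellent"
  else if (best > 0.8) "good"
  else if (best > 0.7) "positive"
  else "inadequate"
}

#' Reliability report for a subscale
#'
#' @inheritParams mcdonald_omega_total
#' @return list with `alpha`, `omega_total`, `rating`.
#' @export
reliability_report <- function(m, subscale, cal = NULL) {
  a <- cronbach_alpha(m, subscale)
  o <- mcdonald_omega_total(m, subscale, cal = cal)
  list(alpha = a, omega_total = o, rating = reliability_rating(a, o))
}
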