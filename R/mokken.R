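#' Loevinger scalability coefficients
#'
#' Item and scale scalability via the covariance formulation of the
#' Guttman-error ratio: for an item pair,
#' `H_ij = cov(X_i, X_j) / cov_max(X_i, X_j)` where `cov_max` is the
#' covariance of the comonotone coupling of the two observed marginals
#' (the maximum attainable with those marginals, i.e. zero Guttman
#' errors). Item coefficients pool numerators and denominators over the
#' item's pairs, the scale coefficient over all pairs, so
#' `H = 1 - observed / expected-under-perfect-scalability` errors and
#' `H = 1` exactly on error-free Guttman data.
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of >= 2 item ids.
#' @return list of class `mokken_report`: `H` (scale), `H_i` (named
#'   per-item), `H_ij` (pair matrix). Items with degenerate marginals
#'   (zero maximal covariance with every partner) are reported as `NA`
#'   with a warning.
#' @export
scalability_coefficients <- function(m, subscale) {
  subscale <- as.character(subscale)
  if (length(subscale) < 2) abort("need >= 2 items")
  x <- m$responses[, subscale, drop = FALSE]
  J <- ncol(x); n <- nrow(x)
  cv <- stats::cov(x) * (n - 1) / n
  cmax <- matrix(0, J, J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    cmax[i, j] <- cmax[j, i] <- comonotone_cov(x[, i], x[, j])
  }
  Hij <- matrix(NA_real_, J, J, dimnames = list(subscale, subscale))
  ok <- cmax > 1e-12
  Hij[ok] <- cv[ok] / cmax[ok]
  num_i <- vapply(seq_len(J), function(i) sum(cv[i, ok[i, ]]), 0)
  den_i <- vapply(seq_len(J), function(i) sum(cmax[i, ok[i, ]]), 0)
  H_i <- ifelse(den_i > 0, num_i / den_i, NA_real_)
  names(H_i) <- subscale
  if (anyNA(H_i))
    warning("degenerate marginals: no scalability for ",
            paste(subscale[is.na(H_i)], collapse = ", "))
  ut <- upper.tri(cmax)
  H <- sum(cv[ut][cmax[ut] > 1e-12]) / sum(cmax[ut][cmax[ut] > 1e-12])
  structure(list(H = H, H_i = H_i, H_ij = Hij, items = subscale),
            class = "mokken_report")
}

## covariance of the Frechet upper (comonotone) coupling of two empirical
## marginals: E[XY] maximal given the margins, minus E[X]E[Y]
comonotone_cov <- function(x, y) {
  n <- length(x)
  px <- tabulate(x + 1L, max(x) + 1L) / n
  py <- tabulate(y + 1L, max(y) + 1L) / n
  cx <- cumsum(px); cy <- cumsum(py)
  grid <- sort(unique(c(0, cx, cy)))
  seg <- diff(grid)
  mid <- grid[-length(grid)] + seg / 2
  xv <- findInterval(mid, cx) # value of X on each uniform segment
  yv <- findInterval(mid, cy)
  exy <- sum(seg * xv * yv)
  exy - mean(x) * mean(y)
}

#' @export
print.mokken_report <- function(x, ...) {
  cat(sprintf("<mokken_report> scale H = %.3f\n", x$H))
  print(round(x$H_i, 3))
  invisible(x)
}

#' Monotonicity check by rest-score groups
#'
#' For each item, persons are grouped by their rest score (the summed
#' score over the other items) into ordered groups of at least `minsize`
#' members (adjacent rest scores merged until the minimum is reached).
#' Every item-step probability `P(X_j >= k)` must be nondecreasing across
#' the ordered groups. Every ordered group pair whose estimated step
#' probability drops by more than `minvi` is a candidate; a candidate is
#' recorded as a violation when its one-sided two-proportion z statistic
#' is significant after controlling for the number of comparisons the
#' item undergoes (per-item critical value
#' `qnorm(1 - alpha / n_comparisons)`, the multiplicity-corrected screen
#' of the method's reference practice), separating sampling wobble from
#' real reversals. All candidates are kept in the report for inspection.
#' An item's criticality score aggregates its violations as
#' `crit = round(50 * sum(magnitudes) + 10 * sum(z - z_critical))`, a
#' deterministic weighting of count, magnitude and significance: a single
#' borderline drop scores in single digits, values of 40-90 indicate a
#' borderline item, systematic reversals score in the hundreds.
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of >= 2 item ids.
#' @param minsize minimum rest-score group size. Default: `n/10` (at
#'   least 50) when `n >= 500`, else `n/5` (at least 10).
#' @param minvi minimum probability drop considered (default 0.03).
#' @param alpha familywise level of the per-item significance screen
#'   (default 0.05).
#' @param zcrit optional fixed one-sided z threshold overriding the
#'   multiplicity-corrected default.
#' @return list of class `monotonicity_report`: `violations` (data.frame
#'   with `item_id`, `group_lo`, `group_hi`, `step`, `magnitude`, `z`),
#'   `candidates` (all drops above `minvi`), `crit` (named per-item
#'   criticality), `z_critical` (per item), `minsize`, `minvi`.
#' @export
monotonicity_check <- function(m, subscale, minsize = NULL, minvi = 0.03,
                               alpha = 0.05, zcrit = NULL) {
  subscale <- as.character(subscale)
  x <- m$responses[, subscale, drop = FALSE]
  n <- nrow(x)
  minsize <- minsize %||% if (n >= 500) max(floor(n / 10), 50) else max(floor(n / 5), 10)
  if (n < 2 * minsize)
    abort("too few persons (", n, ") to form two rest-score groups of ", minsize)
  J <- ncol(x)
  viol <- list()
  crit <- stats::setNames(numeric(J), subscale)
  ncmp <- stats::setNames(integer(J), subscale)
  for (j in seq_len(J)) {
    rest <- rowSums(x[, -j, drop = FALSE])
    grp <- group_rest_scores(rest, minsize)
    G <- max(grp)
    K <- max(x[, j]) + 1L
    ng <- tabulate(grp, G)
    ncmp[j] <- choose(G, 2) * (K - 1)
    for (k in seq_len(K - 1)) {
      p <- vapply(seq_len(G), function(g) mean(x[grp == g, j] >= k), 0)
      for (g in seq_len(G - 1)) for (h in (g + 1):G) {
        drop_gh <- p[g] - p[h]
        if (drop_gh > minvi) {
          pool <- (p[g] * ng[g] + p[h] * ng[h]) / (ng[g] + ng[h])
          se <- sqrt(pool * (1 - pool) * (1 / ng[g] + 1 / ng[h]))
          z <- if (se > 0) drop_gh / se else 0
          viol[[length(viol) + 1]] <- data.frame(
            item_id = subscale[j], group_lo = g, group_hi = h, step = k,
            magnitude = drop_gh, z = z)
        }
      }
    }
  }
  cand <- if (length(viol)) do.call(rbind, viol)
  else data.frame(item_id = character(), group_lo = integer(),
                  group_hi = integer(), step = integer(),
                  magnitude = numeric(), z = numeric())
  z_critical <- if (!is.null(zcrit)) stats::setNames(rep(zcrit, J), subscale)
  else stats::setNames(stats::qnorm(1 - alpha / pmax(ncmp, 1L)), subscale)
  keep <- cand$z > z_critical[cand$item_id]
  viol <- cand[keep, , drop = FALSE]
  for (j in subscale) {
    v <- viol[viol$item_id == j, , drop = FALSE]
    crit[j] <- round(50 * sum(v$magnitude) + 10 * sum(v$z - z_critical[j]))
  }
  structure(list(violations = viol, candidates = cand, crit = crit,
                 z_critical = z_critical, minsize = minsize, minvi = minvi,
                 items = subscale),
            class = "monotonicity_report")
}

## merge adjacent rest scores (ascending) into groups of >= minsize;
## a trailing small group is folded into its neighbour
group_rest_scores <- function(rest, minsize) {
  lev <- sort(unique(rest))
  counts <- vapply(lev, function(l) sum(rest == l), 0)
  gid <- integer(length(lev))
  g <- 1L; acc <- 0
  for (i in seq_along(lev)) {
    gid[i] <- g
    acc <- acc + counts[i]
    if (acc >= minsize && i < length(lev)) { g <- g + 1L; acc <- 0 }
  }
  if (acc < minsize && g > 1) gid[gid == g] <- g - 1L
  grp <- gid[match(rest, lev)]
  match(grp, sort(unique(grp)))
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat(sprintf("<monotonicity_report> %s across %s (minsize %d, minvi %.2f)\n",
              plural(nrow(x$violations), "violation"),
              plural(length(x$items), "item"), x$minsize, x$minvi))
  if (nrow(x$violations)) {
    print(x$violations, row.names = FALSE)
    cat("  crit:\n"); print(x$crit[x$crit > 0])
  }
  invisible(x)
}
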