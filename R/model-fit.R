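#' Convert IRT discriminations to standardized factor loadings
#'
#' Normal-ogive conversion `lambda_j = a*_j / sqrt(1 + a*_j^2)` with
#' `a*_j = a_j / 1.702` (the logistic-to-probit constant enters only
#' here, never inside the response model), and `psi_j = 1 - lambda_j^2`.
#'
#' @param cal a [fit_grm()] calibration (or a named list of
#'   [grm_item_params()]).
#' @return data.frame with `item_id`, `loading`, `uniqueness`.
#' @export
irt_to_loadings <- function(cal) {
  params <- if (inherits(cal, "grm_calibration")) cal$params else cal
  astar <- vapply(params, `[[`, 0, "a") / 1.702
  lambda <- astar / sqrt(1 + astar^2)
  data.frame(item_id = vapply(params, `[[`, "", "item_id"),
             loading = lambda, uniqueness = 1 - lambda^2,
             row.names = NULL)
}

## ---- limited-information moment machinery ------------------------------
##
## Statistics: for each item the category-indicator proportions
## P(X_j = k), k = 1..K_j-1, and for each item pair the cross-product
## moment E[X_i X_j] (the collapsed bivariate margin used for ordinal
## items; for binary items this is the classical univariate + bivariate
## margin set). The M2-type statistic is the Maydeu-Olivares/Joe
## residual quadratic form  N * e' C e  with
## C = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1,
## which is asymptotically chi-square with df = s - q for any consistent
## estimator of the item parameters.

## statistic bookkeeping: data.frame(kind, i, j, cat)
moment_stats <- function(n_cat) {
  J <- length(n_cat)
  uni <- do.call(rbind, lapply(seq_len(J), function(j)
    data.frame(kind = "ind", i = j, j = NA_integer_,
               cat = seq_len(n_cat[j] - 1))))
  pairs <- if (J > 1) t(utils::combn(J, 2)) else matrix(numeric(0), 0, 2)
  biv <- data.frame(kind = rep("cross", nrow(pairs)), i = pairs[, 1],
                    j = pairs[, 2], cat = NA_integer_)
  rbind(uni, biv)
}

## per-item conditional blocks at the integration nodes:
## P (Q x K), E1, E2 (length Q)
item_blocks_grm <- function(params, nodes) {
  lapply(params, function(p) {
    P <- grm_category_probs(nodes, p)
    k <- seq_len(ncol(P)) - 1
    list(P = P, E1 = drop(P %*% k), E2 = drop(P %*% k^2))
  })
}

## implied moments under the (conditionally independent) model
implied_moments <- function(stats, blocks, w) {
  vapply(seq_len(nrow(stats)), function(t) {
    s <- stats[t, ]
    if (s$kind == "ind") sum(w * blocks[[s$i]]$P[, s$cat + 1])
    else sum(w * blocks[[s$i]]$E1 * blocks[[s$j]]$E1)
  }, 0)
}

## observed sample moments
observed_moments <- function(stats, resp) {
  vapply(seq_len(nrow(stats)), function(t) {
    s <- stats[t, ]
    if (s$kind == "ind") mean(resp[, s$i] == s$cat)
    else mean(resp[, s$i] * resp[, s$j])
  }, 0)
}

## conditional expectation (per node) of the product of the per-item
## factors two statistics contribute to one item
cond_item_product <- function(block, terms) {
  if (nrow(terms) == 1) {
    if (terms$kind[1] == "ind") return(block$P[, terms$cat[1] + 1])
    return(block$E1)
  }
  ## two factors on the same item
  k1 <- terms$kind[1]; k2 <- terms$kind[2]
  if (k1 == "ind" && k2 == "ind") {
    if (terms$cat[1] == terms$cat[2]) return(block$P[, terms$cat[1] + 1])
    return(rep(0, nrow(block$P)))
  }
  if (k1 == "ind" || k2 == "ind") {
    cat <- if (k1 == "ind") terms$cat[1] else terms$cat[2]
    return(cat * block$P[, cat + 1])
  }
  block$E2
}

## model-implied covariance matrix of the per-person statistic vector.
## Statistic pairs touching disjoint item sets factorize across items, so
## the bulk is one crossproduct of conditional profiles; only pairs that
## share an item need the merged conditional expectation.
moment_cov <- function(stats, blocks, w, mu) {
  s <- nrow(stats); Q <- length(w)
  fac <- lapply(seq_len(s), function(t) {
    st <- stats[t, ]
    if (st$kind == "ind") data.frame(item = st$i, kind = "ind", cat = st$cat)
    else data.frame(item = c(st$i, st$j), kind = "lin", cat = NA)
  })
  prof <- vapply(seq_len(s), function(t) {
    st <- stats[t, ]
    if (st$kind == "ind") blocks[[st$i]]$P[, st$cat + 1]
    else blocks[[st$i]]$E1 * blocks[[st$j]]$E1
  }, numeric(Q))
  prof <- if (Q == 1) matrix(prof, ncol = 1) else t(prof)
  E <- tcrossprod(sweep(prof, 2, w, `*`), prof)
  ## stat indices per item
  item_stats <- lapply(seq_along(blocks), function(it)
    which(stats$i == it | (!is.na(stats$j) & stats$j == it)))
  merged <- function(t, u) {
    both <- rbind(fac[[t]], fac[[u]])
    prod_q <- rep(1, Q)
    for (it in unique(both$item)) {
      terms <- both[both$item == it, , drop = FALSE]
      prod_q <- prod_q * cond_item_product(blocks[[it]], terms)
    }
    sum(w * prod_q)
  }
  done <- new.env(hash = TRUE)
  for (it in seq_along(blocks)) {
    st <- item_stats[[it]]
    if (length(st) < 2) next
    for (ai in seq_len(length(st) - 1)) for (bi in (ai + 1):length(st)) {
      t <- st[ai]; u <- st[bi]
      key <- paste0(t, "_", u)
      if (!is.null(done[[key]])) next
      done[[key]] <- TRUE
      E[t, u] <- E[u, t] <- merged(t, u)
    }
  }
  for (t in seq_len(s)) E[t, t] <- merged(t, t)
  E - outer(mu, mu)
}

## robust symmetric inverse (tiny ridge if needed)
sym_solve <- function(A, B) {
  tryCatch(solve(A, B), error = function(e) {
    solve(A + diag(1e-10 * max(diag(A)), nrow(A)), B)
  })
}

#' Limited-information global fit statistic (M2 type)
#'
#' Quadratic-form fit statistic on univariate category margins and
#' collapsed bivariate cross-product moments (the ordinal collapsed
#' variant; identical to the classical first/second-order margin
#' construction for binary items), using the orthogonal-complement weight
#' matrix, so the statistic is asymptotically chi-square with
#' `df = s - q` at any consistent parameter estimate. The Jacobian of the
#' implied moments is obtained by central finite differences.
#'
#' @param m a [response_matrix()].
#' @param cal a [fit_grm()] calibration of >= 4 items (df must be
#'   positive: `df = J(J-1)/2 - J` for the GRM).
#' @return list with `M2`, `df`, `p_value`, plus the pieces (`s`, `q`)
#' @export
m2_statistic <- function(m, cal) {
  resp <- m$responses[, cal$item_ids, drop = FALSE]
  n <- nrow(resp)
  n_cat <- vapply(cal$params, `[[`, 0L, "n_categories")
  stats_df <- moment_stats(n_cat)
  s <- nrow(stats_df)
  q <- sum(n_cat)          # a_j plus K_j - 1 thresholds per item
  if (cal$model == "grsm")
    q <- 2 * length(n_cat) - 1 + (n_cat[1] - 1)
  df <- s - q
  if (df <= 0)
    abort("M2 degrees of freedom not positive (", df,
          "); need more items per subscale (>= 4)")
  w <- cal$grid$weights; nodes <- cal$grid$nodes
  blocks <- item_blocks_grm(cal$params, nodes)
  mu <- implied_moments(stats_df, blocks, w)
  obs <- observed_moments(stats_df, resp)
  e <- obs - mu
  Xi <- moment_cov(stats_df, blocks, w, mu)

  ## numeric Jacobian of implied moments wrt free item parameters
  pvec <- unlist(lapply(cal$params, function(p) c(p$a, p$b)))
  moments_at <- function(v) {
    pl <- rebuild_params(v, cal)
    implied_moments(stats_df, item_blocks_grm(pl, nodes), w)
  }
  h <- 1e-4
  D <- vapply(seq_along(pvec), function(i) {
    up <- pvec; up[i] <- up[i] + h
    dn <- pvec; dn[i] <- dn[i] - h
    (moments_at(up) - moments_at(dn)) / (2 * h)
  }, numeric(s))
  if (cal$model == "grsm") D <- D %*% grsm_param_map(cal)

  XiD <- sym_solve(Xi, D)
  Xie <- sym_solve(Xi, e)
  A <- crossprod(D, XiD)
  M2 <- n * (sum(e * Xie) - drop(crossprod(crossprod(XiD, e),
                                           sym_solve(A, crossprod(XiD, e)))))
  M2 <- max(M2, 0)
  list(M2 = M2, df = df, p_value = stats::pchisq(M2, df, lower.tail = FALSE),
       s = s, q = q, n = n)
}

## rebuild a parameter list from the flat (a, b...) vector; thresholds are
## used as-is (finite differences keep them ordered at h = 1e-4)
rebuild_params <- function(v, cal) {
  out <- list(); pos <- 1
  for (p in cal$params) {
    K <- p$n_categories
    out[[p$item_id]] <- structure(
      list(item_id = p$item_id, a = v[pos], b = v[(pos + 1):(pos + K - 1)],
           n_categories = K), class = "grm_item_params")
    pos <- pos + K
  }
  out
}

## chain-rule map from per-item (a_j, b_jk) to GRSM free parameters
## (a_1..a_J, d_2..d_J, t_1..t_{K-1})
grsm_param_map <- function(cal) {
  J <- length(cal$params); K1 <- cal$params[[1]]$n_categories - 1
  qfull <- J * (1 + K1); qfree <- 2 * J - 1 + K1
  Mmap <- matrix(0, qfull, qfree)
  pos <- 1
  for (j in seq_len(J)) {
    Mmap[pos, j] <- 1                       # a_j
    for (k in seq_len(K1)) {
      if (j > 1) Mmap[pos + k, J + j - 1] <- 1     # d_j
      Mmap[pos + k, 2 * J - 1 + k] <- 1            # t_k
    }
    pos <- pos + 1 + K1
  }
  Mmap
}

#' Independence-baseline fit statistic
#'
#' Same moment construction with items independent and univariate margins
#' free (fitted at the observed margins); used as the incremental-fit
#' baseline for CFI/TLI. `df = J(J-1)/2`.
#'
#' @param m a [response_matrix()].
#' @param items item ids.
#' @return list with `M2`, `df`.
#' @export
baseline_m2 <- function(m, items) {
  resp <- m$responses[, items, drop = FALSE]
  n <- nrow(resp)
  n_cat <- apply(resp, 2, max) + 1L
  stats_df <- moment_stats(n_cat)
  s <- nrow(stats_df)
  J <- length(items)
  ## marginal blocks (Q = 1)
  blocks <- lapply(seq_len(J), function(j) {
    p <- vapply(seq_len(n_cat[j]) - 1, function(k) mean(resp[, j] == k), 0)
    k <- seq_len(n_cat[j]) - 1
    list(P = matrix(p, 1), E1 = sum(p * k), E2 = sum(p * k^2))
  })
  w1 <- 1
  mu <- implied_moments(stats_df, blocks, w1)
  obs <- observed_moments(stats_df, resp)
  e <- obs - mu
  Xi <- moment_cov(stats_df, blocks, w1, mu)
  ## analytic Jacobian wrt the free category probabilities p_jk, k>=1
  q <- sum(n_cat - 1)
  D <- matrix(0, s, q)
  colpos <- c(0, cumsum(n_cat - 1))
  means <- vapply(blocks, `[[`, 0, "E1")
  for (t in seq_len(s)) {
    st <- stats_df[t, ]
    if (st$kind == "ind") {
      D[t, colpos[st$i] + st$cat] <- 1
    } else {
      for (k in seq_len(n_cat[st$i] - 1)) D[t, colpos[st$i] + k] <- k * means[st$j]
      for (k in seq_len(n_cat[st$j] - 1)) D[t, colpos[st$j] + k] <- k * means[st$i]
    }
  }
  XiD <- sym_solve(Xi, D)
  Xie <- sym_solve(Xi, e)
  A <- crossprod(D, XiD)
  M2 <- n * (sum(e * Xie) - drop(crossprod(crossprod(XiD, e),
                                           sym_solve(A, crossprod(XiD, e)))))
  list(M2 = max(M2, 0), df = s - q)
}

#' Fit indices from an M2-type statistic
#'
#' `RMSEA = sqrt(max(0, (M2 - df) / (df (n - 1))))`;
#' `CFI = 1 - max(0, M2 - df) / max(M2 - df, M2_b - df_b, 0)`;
#' `TLI = ((M2_b/df_b) - (M2/df)) / ((M2_b/df_b) - 1)`, capped at 1.
#'
#' @param M2,df fitted-model statistic and degrees of freedom.
#' @param n number of persons.
#' @param M2_b,df_b independence-baseline statistic and df (same margins).
#' @return list with `RMSEA`, `CFI`, `TLI`.
#' @export
fit_indices_from_m2 <- function(M2, df, n, M2_b, df_b) {
  if (df_b <= 1) abort("baseline df must exceed 1")
  rmsea <- sqrt(max(0, (M2 - df) / (df * (n - 1))))
  num <- max(0, M2 - df)
  denom <- max(M2 - df, M2_b - df_b, 0)
  cfi <- if (denom == 0) 1 else 1 - num / denom
  tli <- ((M2_b / df_b) - (M2 / df)) / ((M2_b / df_b) - 1)
  list(RMSEA = rmsea, CFI = cfi, TLI = min(tli, 1))
}

#' Standardized root mean-square residual
#'
#' Root mean square of observed minus model-implied inter-item Pearson
#' correlations over unique pairs.
#'
#' @param m a [response_matrix()].
#' @param cal a [fit_grm()] calibration.
#' @return scalar SRMR >= 0.
#' @export
srmr <- function(m, cal) {
  resp <- m$responses[, cal$item_ids, drop = FALSE]
  robs <- stats::cor(resp)
  w <- cal$grid$weights
  blocks <- item_blocks_grm(cal$params, cal$grid$nodes)
  mns <- vapply(blocks, function(b) sum(w * b$E1), 0)
  vars <- vapply(blocks, function(b) sum(w * b$E2), 0) - mns^2
  J <- length(blocks)
  rmod <- diag(J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    cv <- sum(w * blocks[[i]]$E1 * blocks[[j]]$E1) - mns[i] * mns[j]
    rmod[i, j] <- rmod[j, i] <- cv / sqrt(vars[i] * vars[j])
  }
  ut <- upper.tri(robs)
  sqrt(mean((robs[ut] - rmod[ut])^2))
}

#' Full fit-index block for a calibrated subscale
#'
#' Computes the M2-type statistic, its independence baseline, RMSEA, CFI,
#' TLI and SRMR in one call.
#'
#' @inheritParams srmr
#' @return list of class `fit_indices`: `M2`, `df`, `p_value`, `RMSEA`,
#'   `SRMR`, `CFI`, `TLI`.
#' @export
fit_indices <- function(m, cal) {
  m2 <- m2_statistic(m, cal)
  b <- baseline_m2(m, cal$item_ids)
  fi <- fit_indices_from_m2(m2$M2, m2$df, m2$n, b$M2, b$df)
  structure(list(M2 = m2$M2, df = m2$df, p_value = m2$p_value,
                 RMSEA = fi$RMSEA, SRMR = srmr(m, cal), CFI = fi$CFI,
                 TLI = fi$TLI, M2_baseline = b$M2, df_baseline = b$df),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("M2 = %.2f (df = %d, p = %.3g) | RMSEA %.3f  SRMR %.3f  CFI %.3f  TLI %.3f\n",
              x$M2, x$df, x$p_value, x$RMSEA, x$SRMR, x$CFI, x$TLI))
  invisible(x)
}

#' Residual correlations among items
#'
#' Q3-style local-dependence diagnostics: per-person item residuals
#' `x_nj - E[X_j | theta_hat_n]` at the EAP trait estimates, correlated
#' over persons. The default subtracts the average off-diagonal
#' correlation (the Q3* centering), which removes the small systematic
#' shift the shared trait estimate induces, so locally independent data
#' sit near zero; the uncentered matrix is available with
#' `method = "q3"`.
#'
#' @param m a [response_matrix()].
#' @param cal a [fit_grm()] calibration.
#' @param scores optional [eap_scores()] result.
#' @param method `"q3_star"` (centered, default) or `"q3"`.
#' @param flag_at absolute threshold for flagged pairs (default 0.2).
#' @return list of class `residual_correlations`: `matrix`, `q3`
#'   (third quartile of the unique off-diagonal values), `flagged`
#'   (data.frame of pairs with `|r| >= flag_at`), `method`.
#' @export
residual_correlations <- function(m, cal, scores = NULL,
                                  method = c("q3_star", "q3"), flag_at = 0.2) {
  method <- match.arg(method)
  scores <- scores %||% eap_scores(m, cal)
  resp <- m$responses[, cal$item_ids, drop = FALSE]
  E <- vapply(cal$params,
              function(p) grm_item_moments(scores$theta_eap, p)$mean,
              numeric(nrow(resp)))
  R <- stats::cor(resp - E)
  if (method == "q3_star") {
    ut <- upper.tri(R)
    adj <- mean(R[ut])
    R[upper.tri(R) | lower.tri(R)] <- R[upper.tri(R) | lower.tri(R)] - adj
  }
  ut <- upper.tri(R)
  pairs <- which(ut & abs(R) >= flag_at, arr.ind = TRUE)
  flagged <- data.frame(item_a = cal$item_ids[pairs[, 1]],
                        item_b = cal$item_ids[pairs[, 2]],
                        r = R[pairs])
  flagged <- flagged[order(-abs(flagged$r)), , drop = FALSE]
  structure(list(matrix = R,
                 q3 = unname(stats::quantile(R[ut], 0.75)),
                 range = range(R[ut]),
                 flagged = flagged, method = method, flag_at = flag_at),
            class = "residual_correlations")
}

#' @export
print.residual_correlations <- function(x, ...) {
  cat(sprintf("<residual_correlations> (%s) Q3 quartile %.3f, range [%.3f, %.3f]\n",
              x$method, x$q3, x$range[1], x$range[2]))
  if (nrow(x$flagged)) {
    cat("  flagged pairs (|r| >=", x$flag_at, "):\n")
    print(x$flagged, row.names = FALSE)
  } else cat("  no flagged pairs\n")
  invisible(x)
}
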