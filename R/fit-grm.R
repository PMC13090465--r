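#' Fit a graded response / graded rating scale model
#'
#' Marginal maximum likelihood calibration of a unidimensional GRM (or
#' GRSM) for one subscale, by EM with a standard-normal latent prior on a
#' fixed quadrature grid. Identification comes from fixing the trait
#' distribution at mean 0, sd 1. The M-step maximizes the expected
#' complete-data log-likelihood per item (jointly across items for the
#' GRSM, whose items share one step vector plus per-item locations) under
#' a monotone threshold reparameterization `b_k = b_1 + sum(exp(gamma))`,
#' so threshold ordering is preserved by construction. The marginal
#' log-likelihood is recorded every iteration and is nondecreasing.
#'
#' Response patterns are collapsed to unique rows internally; results are
#' identical to the per-person E-step, only faster.
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of item ids (>= 2 items).
#' @param model `"grm"` (default) or `"grsm"` (requires all items to share
#'   one category count).
#' @param grid a [quadrature_grid()].
#' @param tol EM convergence tolerance on the log-likelihood change
#'   (default 1e-5).
#' @param max_iter maximum EM iterations (default 500). Non-convergence is
#'   flagged on the result and warned about, never silent.
#' @return An object of class `grm_calibration`: item parameters, the
#'   log-marginal-likelihood trace, iteration count, convergence flag,
#'   grid and model label.
#' @examples
#' fix <- make_fixture_cohort("psc17-like", seed = 1)
#' cal <- fit_grm(fix$responses, bundled_instruments("psc17")$subscales$internalizing)
#' cal$converged
#' @export
fit_grm <- function(m, subscale, model = c("grm", "grsm"),
                    grid = quadrature_grid(), tol = 1e-5, max_iter = 500L) {
  model <- match.arg(model)
  subscale <- as.character(subscale)
  if (length(subscale) < 2) abort("need at least 2 items to calibrate")
  missing_items <- setdiff(subscale, m$item_ids)
  if (length(missing_items)) abort("items not in data: ",
                                   paste(missing_items, collapse = ", "))
  resp <- m$responses[, subscale, drop = FALSE]
  n_cat <- apply(resp, 2, function(x) max(x)) + 1L
  for (j in seq_along(subscale)) {
    obs <- sort(unique(resp[, j]))
    if (length(obs) < 2)
      abort("item ", subscale[j], " shows a single observed category; ",
            "collapse categories or drop the item",
            class = "scalenorm_calibration_error")
  }
  if (model == "grsm" && length(unique(n_cat)) != 1)
    abort("GRSM requires all items to share one category count")

  ## collapse response patterns
  key <- apply(resp, 1, paste, collapse = "\r")
  tab <- table(key)
  upat <- names(tab)
  counts <- as.numeric(tab)
  pat <- do.call(rbind, strsplit(upat, "\r", fixed = TRUE))
  pat <- matrix(as.integer(pat), nrow = length(upat))
  colnames(pat) <- subscale

  nodes <- grid$nodes; w <- grid$weights; Q <- length(nodes)
  J <- ncol(pat); N <- sum(counts)

  ## start values: a = 1, thresholds from inverse-normal cumulative rates
  params <- vector("list", J); names(params) <- subscale
  for (j in seq_len(J)) {
    K <- n_cat[j]
    ge <- vapply(seq_len(K - 1), function(k) mean(resp[, j] >= k), 0)
    b0 <- stats::qnorm(1 - pmin(pmax(ge, 1 / (2 * N)), 1 - 1 / (2 * N)))
    b0 <- b0 + cumsum(c(0, diff(b0) <= 0) * 1e-2)  # break ties from empty cells
    params[[j]] <- grm_item_params(subscale[j], a = 1, b = b0)
  }
  grsm_par <- NULL
  if (model == "grsm") {
    ## initialize shared steps as the average start thresholds, locations 0
    K <- n_cat[1]
    bmat <- do.call(rbind, lapply(params, `[[`, "b"))
    t0 <- colMeans(bmat)
    d0 <- rowMeans(bmat) - mean(bmat)
    grsm_par <- list(t = t0, d = d0 - d0[1])
    params <- grsm_expand(subscale, exp(0 * d0), grsm_par)  # a=1
  }

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## E-step
    ll <- grm_pattern_loglik(pat, params, nodes)           # pat x Q
    mx <- apply(ll, 1, max)
    L <- exp(ll - mx)
    lw <- sweep(L, 2, w, `*`)
    marg <- rowSums(lw)
    ll_marg <- sum(counts * (log(marg) + mx))
    loglik_trace <- c(loglik_trace, ll_marg)
    post <- lw / marg                                      # P(q | pattern)
    W <- post * counts                                     # expected persons at node

    if (ll_marg - ll_old < tol && iter > 1) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll_marg

    ## M-step
    if (model == "grm") {
      for (j in seq_len(J)) {
        r <- expected_counts(pat[, j], n_cat[j], W)        # K x Q
        params[[j]] <- mstep_grm_item(params[[j]], r, nodes)
      }
    } else {
      rlist <- lapply(seq_len(J), function(j) expected_counts(pat[, j], n_cat[j], W))
      fit <- mstep_grsm(params, grsm_par, rlist, nodes)
      params <- fit$params; grsm_par <- fit$grsm_par
    }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations (last change ", signif(ll_marg - ll_old, 3), ")")

  structure(list(params = params, item_ids = subscale, model = model,
                 grid = grid, log_marginal_likelihood = ll_marg,
                 loglik_trace = loglik_trace, n_iterations = iter,
                 converged = converged, n_persons = N,
                 grsm_par = grsm_par),
            class = "grm_calibration")
}

#' @export
print.grm_calibration <- function(x, ...) {
  cat(sprintf("<grm_calibration> %s, %d items, n = %d\n", toupper(x$model),
              length(x$params), x$n_persons))
  cat(sprintf("  logLik %.3f after %d EM iterations (%s)\n",
              x$log_marginal_likelihood, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  for (p in x$params)
    cat(sprintf("  %-10s a = %5.2f  b = (%s)\n", p$item_id, p$a,
                paste(sprintf("%.2f", p$b), collapse = ", ")))
  invisible(x)
}

## expected category-by-node counts for one item: K x Q
expected_counts <- function(x, K, W) {
  r <- matrix(0, K, ncol(W))
  for (k in 0:(K - 1)) {
    idx <- x == k
    if (any(idx)) r[k + 1, ] <- colSums(W[idx, , drop = FALSE])
  }
  r
}

## (log a, b1, gamma...) <-> item params
pack_item <- function(p) c(log(p$a), p$b[1], if (length(p$b) > 1) log(diff(p$b)))
unpack_item <- function(par, item_id) {
  a <- exp(par[1])
  b1 <- par[2]
  b <- if (length(par) > 2) b1 + c(0, cumsum(exp(par[-(1:2)]))) else b1
  list(item_id = item_id, a = a, b = b, n_categories = length(b) + 1L)
}

## expected complete-data log-likelihood for one item
item_ecll <- function(par, item_id, r, nodes) {
  p <- unpack_item(par, item_id)
  ## finite penalty keeps BFGS away from tied thresholds / runaway slopes
  if (!all(is.finite(p$b)) || !is.finite(p$a) || p$a > 50 ||
      (length(p$b) > 1 && any(diff(p$b) < 1e-7))) return(-1e10)
  P <- grm_category_probs(nodes, p)          # Q x K
  sum(t(r) * log(pmax(P, 1e-300)))
}

## analytic gradient of the expected complete-data log-likelihood in the
## (log a, b_1, gamma) parameterization
item_egrad <- function(par, item_id, r, nodes) {
  p <- unpack_item(par, item_id)
  if (!all(is.finite(p$b)) || !is.finite(p$a) || p$a > 50 ||
      (length(p$b) > 1 && any(diff(p$b) < 1e-7)))
    return(rep(0, length(par)))
  a <- p$a; b <- p$b; K1 <- length(b)
  Pb <- grm_boundary_probs(nodes, a, b)            # Q x K1
  qd <- Pb * (1 - Pb)                              # logistic density factor
  cum <- cbind(1, Pb, 0)
  P <- pmax(cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE], 1e-12)
  ratio <- t(r) / P                                # Q x K
  ## d/da: boundary m feeds category m (+) and category m-1 (-)
  dev <- outer(nodes, b, `-`)                      # Q x K1, theta - b_m
  ga <- sum((ratio[, 2:(K1 + 1), drop = FALSE] - ratio[, 1:K1, drop = FALSE]) *
              qd * dev)
  ## d/db_m: a q_m (ratio_{m-1} - ratio_m) summed over nodes
  gb <- vapply(seq_len(K1), function(m)
    sum(a * qd[, m] * (ratio[, m + 1] - ratio[, m])), 0)
  gb <- -gb  # dP*_m/db_m = -a q_m acting on categories m (+) and m-1 (-)
  g <- numeric(length(par))
  g[1] <- a * ga
  g[2] <- sum(gb)
  if (K1 > 1)
    for (l in seq_len(K1 - 1))
      g[2 + l] <- exp(par[2 + l]) * sum(gb[(l + 1):K1])
  g
}

mstep_grm_item <- function(item, r, nodes) {
  par0 <- pack_item(item)
  f0 <- item_ecll(par0, item$item_id, r, nodes)
  opt <- stats::optim(par0, item_ecll, gr = item_egrad,
                      item_id = item$item_id, r = r,
                      nodes = nodes, method = "BFGS",
                      control = list(fnscale = -1, maxit = 60))
  if (opt$value >= f0) {
    out <- unpack_item(opt$par, item$item_id)
  } else out <- item                         # never decrease the objective
  structure(out, class = "grm_item_params")
}

## GRSM helpers: b_jk = d_j + t_k (d_1 = 0 for identification)
grsm_expand <- function(item_ids, a_vec, grsm_par) {
  out <- lapply(seq_along(item_ids), function(j) {
    structure(list(item_id = item_ids[j], a = a_vec[j],
                   b = grsm_par$d[j] + grsm_par$t,
                   n_categories = length(grsm_par$t) + 1L),
              class = "grm_item_params")
  })
  names(out) <- item_ids
  out
}

mstep_grsm <- function(params, grsm_par, rlist, nodes) {
  J <- length(params); K1 <- length(grsm_par$t)  # K-1 steps
  pack <- function(a_vec, gp) c(log(a_vec), gp$d[-1], gp$t[1],
                                if (K1 > 1) log(diff(gp$t)))
  unpack <- function(par) {
    a_vec <- exp(par[1:J])
    d <- c(0, par[(J + 1):(2 * J - 1)])
    t1 <- par[2 * J]
    t <- if (K1 > 1) t1 + c(0, cumsum(exp(par[(2 * J + 1):(2 * J + K1 - 1)]))) else t1
    list(a = a_vec, gp = list(t = t, d = d))
  }
  obj <- function(par) {
    u <- unpack(par)
    if (!all(is.finite(unlist(u))) || any(u$a > 50) ||
        (K1 > 1 && any(diff(u$gp$t) < 1e-7))) return(-1e10)
    tot <- 0
    for (j in seq_len(J)) {
      p <- list(a = u$a[j], b = u$gp$d[j] + u$gp$t)
      P <- grm_category_probs(nodes, p)
      tot <- tot + sum(t(rlist[[j]]) * log(pmax(P, 1e-300)))
    }
    tot
  }
  a0 <- vapply(params, `[[`, 0, "a")
  par0 <- pack(a0, grsm_par)
  f0 <- obj(par0)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(fnscale = -1, maxit = 80))
  u <- if (opt$value >= f0) unpack(opt$par) else list(a = a0, gp = grsm_par)
  list(params = grsm_expand(names(params), u$a, u$gp), grsm_par = u$gp)
}

#' Log marginal likelihood of a response matrix under given parameters
#'
#' Evaluates the marginal likelihood (standard-normal prior, calibration
#' grid) of a set of item parameters on data; used e.g. to verify that the
#' fitted parameters dominate the generating ones.
#'
#' @param m a [response_matrix()].
#' @param params list of [grm_item_params()] named by item id.
#' @param grid a [quadrature_grid()].
#' @return scalar log-likelihood.
#' @export
grm_loglik <- function(m, params, grid = quadrature_grid()) {
  resp <- m$responses[, names(params), drop = FALSE]
  ll <- grm_pattern_loglik(resp, params, grid$nodes)
  mx <- apply(ll, 1, max)
  sum(log(rowSums(sweep(exp(ll - mx), 2, grid$weights, `*`))) + mx)
}
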