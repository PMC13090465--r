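#' Latent-trait quadrature grid
#'
#' Equally spaced nodes with standard-normal prior weights, renormalized to
#' sum to one. This grid carries every latent-trait integration in the
#' package: the EM E-step, EAP scoring, summed-score posteriors and the
#' model-implied moments behind the fit statistics.
#'
#' @param n_nodes number of nodes (default 61).
#' @param range numeric length-2, grid endpoints in trait units
#'   (default `c(-6, 6)`).
#' @return An object of class `quadrature_grid` with components `nodes`
#'   (ordered numeric vector) and `weights` (nonnegative, summing to 1).
#' @examples
#' g <- quadrature_grid()
#' sum(g$weights)          # 1
#' sum(g$nodes * g$weights) # ~0 (symmetric prior)
#' @export
quadrature_grid <- function(n_nodes = 61L, range = c(-6, 6)) {
  stopifnot(is_scalar_number(n_nodes), n_nodes >= 3, length(range) == 2,
            range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = as.integer(n_nodes))
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature_grid> %d nodes on [%.3g, %.3g], normal prior\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}
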