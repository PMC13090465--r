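#' Plot item category curves
#'
#' Category response probabilities of one calibrated item across the
#' trait range.
#'
#' @param cal a [fit_grm()] calibration.
#' @param item item id.
#' @param theta_range plotting range in trait units.
#' @return invisibly, the matrix of plotted probabilities.
#' @export
plot_icc <- function(cal, item, theta_range = c(-4, 4)) {
  p <- cal$params[[item]]
  if (is.null(p)) abort("item ", item, " not in calibration")
  th <- seq(theta_range[1], theta_range[2], length.out = 201)
  P <- grm_category_probs(th, p)
  graphics::matplot(th, P, type = "l", lty = 1, lwd = 2,
                    col = grDevices::hcl.colors(ncol(P), "Dark 3"),
                    xlab = expression(theta), ylab = "P(X = k)",
                    main = sprintf("%s (a = %.2f)", item, p$a), ylim = c(0, 1))
  graphics::legend("right", legend = paste("k =", seq_len(ncol(P)) - 1),
                   col = grDevices::hcl.colors(ncol(P), "Dark 3"), lty = 1,
                   lwd = 2, bty = "n")
  invisible(P)
}

#' Plot the test information curve
#'
#' @param cal a [fit_grm()] calibration.
#' @param theta_range plotting range in trait units.
#' @return invisibly, the plotted data.frame.
#' @export
plot_information <- function(cal, theta_range = c(-4, 4)) {
  th <- seq(theta_range[1], theta_range[2], length.out = 201)
  ti <- test_information(cal, th)
  graphics::plot(ti$theta, ti$information, type = "l", lwd = 2,
                 xlab = expression(theta), ylab = "Test information",
                 main = sprintf("%d items (%s)", length(cal$params),
                                toupper(cal$model)))
  invisible(ti)
}
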