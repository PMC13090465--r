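#' Evaluate unidimensionality
#'
#' Three-member menu: (1) RMSEA <= 0.06, with RMSEA in (0.06, 0.08]
#' counting as "acceptable" (it still satisfies the member, flagged as
#' acceptable rather than good); (2) SRMR <= 0.08; (3) TLI >= 0.95 AND
#' CFI >= 0.95 as one joint member. Pass requires at least two members
#' satisfied. Missing indices drop their member from the menu with a
#' note; the pass rule still requires two.
#'
#' @param f a [fit_indices()] result (or list with `RMSEA`, `SRMR`,
#'   `CFI`, `TLI`).
#' @return list: `pass`, `n_met`, `criteria` (named logicals),
#'   `rmsea_acceptable` flag, `notes`.
#' @export
evaluate_unidimensionality <- function(f) {
  notes <- character()
  crit <- c(rmsea = NA, srmr = NA, tli_cfi = NA)
  acceptable <- FALSE
  if (!is.null(f$RMSEA) && is.finite(f$RMSEA)) {
    crit["rmsea"] <- f$RMSEA <= 0.08
    acceptable <- f$RMSEA > 0.06 && f$RMSEA <= 0.08
  } else notes <- c(notes, "RMSEA missing; member skipped")
  if (!is.null(f$SRMR) && is.finite(f$SRMR)) crit["srmr"] <- f$SRMR <= 0.08
  else notes <- c(notes, "SRMR missing; member skipped")
  if (!is.null(f$TLI) && !is.null(f$CFI) && is.finite(f$TLI) && is.finite(f$CFI))
    crit["tli_cfi"] <- f$TLI >= 0.95 && f$CFI >= 0.95
  else notes <- c(notes, "TLI/CFI missing; member skipped")
  n_met <- sum(crit, na.rm = TRUE)
  list(pass = n_met >= 2, n_met = n_met, criteria = crit,
       rmsea_acceptable = acceptable, notes = notes)
}

#' Evaluate local independence
#'
#' Pass iff all residual correlations satisfy `|r| < 0.2` OR the third
#' quartile of the unique off-diagonal correlations is `< 0.37`. Flagged
#' pairs are always carried along.
#'
#' @param r a [residual_correlations()] result.
#' @return list: `pass`, `all_below_02`, `q3`, `flagged`.
#' @export
evaluate_local_independence <- function(r) {
  ut <- upper.tri(r$matrix)
  all_below <- all(abs(r$matrix[ut]) < 0.2)
  list(pass = all_below || r$q3 < 0.37, all_below_02 = all_below,
       q3 = r$q3, flagged = r$flagged)
}

#' Evaluate monotonicity
#'
#' Pass iff every item scalability exceeds 0.3 AND no violation carries a
#' criticality score above 90; items with violations scoring in
#' `[40, 90]` are annotated "acceptable". The graphical escape ("adequate
#' looking graphs") is a manual override flag, never applied
#' automatically.
#'
#' @param k a [scalability_coefficients()] report.
#' @param v a [monotonicity_check()] report (optional; no violations
#'   assumed when absent).
#' @param graph_override logical manual override for the scalability
#'   branch (default FALSE).
#' @return list: `pass`, `low_scalability_items`, `n_low`, `max_crit`,
#'   `acceptable_violation_items`.
#' @export
evaluate_monotonicity <- function(k, v = NULL, graph_override = FALSE) {
  low <- names(k$H_i)[is.na(k$H_i) | k$H_i <= 0.3]
  crit <- if (!is.null(v)) v$crit else stats::setNames(numeric(0), character(0))
  max_crit <- if (length(crit)) max(crit) else 0
  acceptable <- names(crit)[crit >= 40 & crit <= 90]
  pass <- (length(low) == 0 || isTRUE(graph_override)) && max_crit <= 90
  list(pass = pass, low_scalability_items = low, n_low = length(low),
       max_crit = max_crit, acceptable_violation_items = acceptable)
}

#' Evaluate global model fit
#'
#' Pass iff the unidimensionality verdict passed AND every item infit
#' mean square lies in `[0.5, 1.5]`.
#'
#' @param uni an [evaluate_unidimensionality()] verdict.
#' @param infits an [infit_mean_squares()] report.
#' @return list: `pass`, `out_of_range_items`.
#' @export
evaluate_global_fit <- function(uni, infits) {
  out <- names(infits$item)[infits$item < 0.5 | infits$item > 1.5]
  list(pass = isTRUE(uni$pass) && length(out) == 0, out_of_range_items = out)
}

#' Classify factor loadings
#'
#' `below` if lambda <= 0.3, `positive` if 0.3 < lambda <= 0.5,
#' `very_positive` if lambda > 0.5.
#'
#' @param l an [irt_to_loadings()] data.frame (or numeric loadings).
#' @return named character vector of flags.
#' @export
loading_flags <- function(l) {
  lambda <- if (is.data.frame(l)) stats::setNames(l$loading, l$item_id) else l
  flags <- ifelse(lambda > 0.5, "very_positive",
                  ifelse(lambda > 0.3, "positive", "below"))
  stats::setNames(flags, names(lambda))
}

#' Compile a measurement-property verdict
#'
#' Combines the four factor-analysis criteria and the reliability rating
#' into one structured verdict. `overall` is `"supported"` iff all four
#' criteria pass and reliability is at least positive (set
#' `require_reliability = FALSE` to base the flag on the factor-analysis
#' criteria alone); `"incomplete"` whenever a component is missing, never
#' a silent pass. Every failed component contributes a machine-readable
#' reason code.
#'
#' @param unidimensionality,local_independence,monotonicity,global_fit
#'   component verdicts from the respective `evaluate_*` functions (any
#'   may be `NULL` if unavailable).
#' @param reliability a [reliability_report()] result or rating string.
#' @param loadings an [irt_to_loadings()] data.frame (optional).
#' @param require_reliability include reliability in `overall`
#'   (default TRUE).
#' @return list of class `cosmin_verdict` with the component verdicts,
#'   `loading_flags`, `overall` and `reasons`.
#' @export
compile_verdict <- function(unidimensionality, local_independence,
                            monotonicity, global_fit, reliability = NULL,
                            loadings = NULL, require_reliability = TRUE) {
  comps <- list(unidimensionality = unidimensionality,
                local_independence = local_independence,
                monotonicity = monotonicity, global_fit = global_fit)
  missing <- names(comps)[vapply(comps, is.null, TRUE)]
  rating <- if (is.list(reliability)) reliability$rating else reliability
  reasons <- character()
  if (length(missing)) {
    overall <- "incomplete"
    reasons <- paste0("missing:", missing)
  } else {
    fails <- names(comps)[!vapply(comps, function(c) isTRUE(c$pass), TRUE)]
    reasons <- if (length(fails)) paste0("fail:", fails) else character()
    rel_ok <- !require_reliability ||
      (!is.null(rating) && rating %in% c("positive", "good", "excellent"))
    if (!rel_ok) reasons <- c(reasons, "fail:reliability")
    overall <- if (!length(reasons)) "supported" else "not_supported"
    if (require_reliability && is.null(rating)) {
      overall <- "incomplete"; reasons <- c(reasons, "missing:reliability")
    }
  }
  structure(list(unidimensionality = unidimensionality,
                 local_independence = local_independence,
                 monotonicity = monotonicity, global_fit = global_fit,
                 reliability_rating = rating,
                 loading_flags = if (!is.null(loadings)) loading_flags(loadings),
                 overall = overall, reasons = reasons),
            class = "cosmin_verdict")
}

#' @export
print.cosmin_verdict <- function(x, ...) {
  cat("<cosmin_verdict>", x$overall, "\n")
  for (nm in c("unidimensionality", "local_independence", "monotonicity",
               "global_fit")) {
    c <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(c)) "missing" else if (isTRUE(c$pass)) "pass" else "FAIL"))
  }
  cat("  reliability:", x$reliability_rating %||% "missing", "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
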