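#' PROMIS-style severity band specification
#'
#' Bands partition the T line: minimal (T < 55), mild (55 <= T <= 59),
#' moderate (60 <= T <= 69), severe (T >= 70). Band membership is decided
#' on the raw T (continuous boundaries at 55, 60 and 70); display
#' truncation never changes membership. Colors follow the conventional
#' green/yellow/orange/red coding of severity tables.
#'
#' @param floor,ceiling display truncation limits for rendered T scores
#'   (defaults 20 and 80).
#' @return list of class `severity_band_spec`.
#' @export
severity_band_spec <- function(floor = 20, ceiling = 80) {
  structure(list(
    bands = data.frame(
      band = c("minimal", "mild", "moderate", "severe"),
      t_lo = c(-Inf, 55, 60, 70),
      t_hi = c(55, 60, 70, Inf),    # [lo, hi)
      color = c("#2e7d32", "#f9a825", "#ef6c00", "#c62828")),
    floor = floor, ceiling = ceiling),
    class = "severity_band_spec")
}

#' Assign a severity band to T scores
#'
#' @param T numeric T scores.
#' @param spec a [severity_band_spec()].
#' @return character vector of band labels; every finite T maps to
#'   exactly one band.
#' @export
promis_band <- function(T, spec = severity_band_spec()) {
  b <- spec$bands
  idx <- findInterval(T, b$t_lo[-1]) + 1L   # boundaries 55, 60, 70
  b$band[idx]
}

#' Standardize trait scores within norm groups
#'
#' Within each group, `Z = (theta - group mean) / group sd` and
#' `T = 50 + 10 Z`.
#'
#' @param scores an [eap_scores()] data.frame (column `theta_eap`), or a
#'   numeric vector.
#' @param group per-person group labels.
#' @param warn_below groups smaller than this trigger a warning
#'   (default 30).
#' @return data.frame with `group`, `theta`, `Z`, `T`.
#' @export
standardize_scores <- function(scores, group, warn_below = 30) {
  theta <- if (is.data.frame(scores)) scores$theta_eap else scores
  group <- as.character(group)
  stopifnot(length(theta) == length(group))
  Z <- numeric(length(theta))
  for (g in unique(group)) {
    idx <- group == g
    if (sum(idx) < 2) abort("group '", g, "' has fewer than 2 persons; sd undefined")
    if (sum(idx) < warn_below)
      warning("group '", g, "' has only ", sum(idx), " persons; norms unstable")
    s <- stats::sd(theta[idx])
    if (s == 0) abort("zero trait variance in group '", g, "'")
    Z[idx] <- (theta[idx] - mean(theta[idx])) / s
  }
  data.frame(group = group, theta = theta, Z = Z, T = 50 + 10 * Z)
}

#' Link crude summed scores to standardized scores for one group
#'
#' Model-based crude-score linking: `theta(s) = E[theta | S = s]` from the
#' summed-score posterior ([summed_score_posterior()]); Z and T standardize
#' `theta(s)` against the group members' trait distribution; the percentile
#' is the mid-probability empirical percentile of the group's observed
#' crude scores, `100 * (P(S < s) + P(S = s)/2)`.
#'
#' @param cal a [fit_grm()] calibration.
#' @param group_theta numeric trait estimates of the group's members.
#' @param group_sums integer observed crude scores of the same members.
#' @param ssp optional precomputed [summed_score_posterior()] table.
#' @return data.frame with `crude`, `theta`, `Z`, `T`, `percentile`,
#'   nondecreasing in `crude`.
#' @export
link_summed_scores <- function(cal, group_theta, group_sums, ssp = NULL) {
  ssp <- ssp %||% summed_score_posterior(cal)
  mu <- mean(group_theta); s <- stats::sd(group_theta)
  if (!is.finite(s) || s == 0) abort("degenerate group trait distribution")
  Z <- (ssp$theta_eap - mu) / s
  n <- length(group_sums)
  pct <- vapply(ssp$sum, function(sc)
    100 * (sum(group_sums < sc) + sum(group_sums == sc) / 2) / n, 0)
  data.frame(crude = ssp$sum, theta = ssp$theta_eap, Z = Z, T = 50 + 10 * Z,
             percentile = pct)
}

#' Rescale T scores for display within severity bands
#'
#' Raw T scores are kept for machine output; for rendering, values are
#' linearly mapped (slope one) and truncated at each band's nominal
#' display range: the minimal band is floored at `spec$floor`, the severe
#' band is capped at `spec$ceiling`. Band membership is decided before
#' truncation and never changed by it; values already inside their band's
#' display range are fixed points.
#'
#' @param T numeric raw T scores.
#' @param spec a [severity_band_spec()].
#' @return data.frame with `T`, `band`, `T_display`.
#' @export
band_rescale <- function(T, spec = severity_band_spec()) {
  band <- promis_band(T, spec)
  b <- spec$bands
  lo <- b$t_lo[match(band, b$band)]; hi <- b$t_hi[match(band, b$band)]
  lo[!is.finite(lo)] <- spec$floor
  hi[!is.finite(hi)] <- spec$ceiling
  data.frame(T = T, band = band, T_display = pmin(pmax(T, lo), hi))
}

#' Build a normative reference table
#'
#' For every norm group (age group x gender by default) and every
#' attainable crude score of the subscale: the model-linked Z, T,
#' percentile, severity band and display T. Groups below `min_group`
#' members are pooled across gender when possible, otherwise flagged
#' `unstable`.
#'
#' @param m a [response_matrix()] (the calibration cohort).
#' @param cal the subscale's [fit_grm()] calibration.
#' @param subscale character vector of item ids (defaults to the
#'   calibrated items).
#' @param scores optional [eap_scores()] for `m`.
#' @param by `"age_gender"` (default) or `"age"`.
#' @param min_group minimum stable group size (default 30).
#' @param band_spec a [severity_band_spec()].
#' @return data.frame of class `norm_table`: `group`, `age_group`,
#'   `gender`, `n_group`, `crude`, `theta`, `Z`, `T`, `percentile`,
#'   `band`, `T_display`, `unstable`; one row per (group, crude score),
#'   covering `0..max` crude score.
#' @export
build_norm_table <- function(m, cal, subscale = NULL, scores = NULL,
                             by = c("age_gender", "age"), min_group = 30,
                             band_spec = severity_band_spec()) {
  by <- match.arg(by)
  subscale <- subscale %||% cal$item_ids
  scores <- scores %||% eap_scores(m, cal)
  sums <- sum_scores(m, subscale)
  ssp <- summed_score_posterior(cal)
  age <- m$age_group
  gender <- if (by == "age_gender") m$gender else "all"
  key <- paste(age, gender, sep = " / ")
  ## pooled-gender fallback for small cells
  for (g in unique(key)) {
    if (!any(key == g)) next      # cell absorbed by an earlier pooling
    if (sum(key == g) < min_group && by == "age_gender") {
      ag <- age[key == g][1]
      if (sum(age == ag) >= min_group) {
        message("norm group '", g, "' below ", min_group,
                " persons; pooling across gender for age group ", ag)
        key[age == ag] <- paste(ag, "pooled", sep = " / ")
      }
    }
  }
  out <- list()
  for (g in unique(key)) {
    idx <- key == g
    link <- link_summed_scores(cal, scores$theta_eap[idx], sums[idx], ssp = ssp)
    br <- band_rescale(link$T, band_spec)
    out[[g]] <- data.frame(group = g,
                           age_group = age[idx][1],
                           gender = sub("^.* / ", "", g),
                           n_group = sum(idx),
                           link, band = br$band, T_display = br$T_display,
                           unstable = sum(idx) < min_group)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("norm_table", "data.frame")
  res
}

#' @export
print.norm_table <- function(x, ...) {
  cat(sprintf("<norm_table> %d groups x %d crude scores\n",
              length(unique(x$group)), length(unique(x$crude))))
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}
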