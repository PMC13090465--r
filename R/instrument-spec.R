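#' Instrument specification
#'
#' An instrument's items, response-category counts, rater(s), age range and
#' subscale partition. Six specifications are bundled with the package
#' (PSC-17, RCADS-25, SNAP-IV, MCHAT-R/F, CAST, CATS-2); see
#' [bundled_instruments()].
#'
#' @param name short instrument name.
#' @param items data.frame with columns `item_id` (character, unique) and
#'   `n_categories` (integer K >= 2; responses take values 0..K-1).
#' @param subscales named list of character vectors of item ids; every
#'   subscale must have at least two items, all present among `items`,
#'   none repeated within a subscale.
#' @param rater character vector, subset of `c("caregiver", "self")`.
#' @param age_range numeric length-2 `(min, max)` in years.
#' @param full_name optional descriptive name.
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, items, subscales, rater = "caregiver",
                            age_range = c(1, 18), full_name = name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    abort("`name` must be a nonempty string")
  if (!is.data.frame(items) || !all(c("item_id", "n_categories") %in% names(items)))
    abort("`items` must be a data.frame with columns item_id and n_categories")
  items$item_id <- as.character(items$item_id)
  items$n_categories <- as.integer(items$n_categories)
  if (anyDuplicated(items$item_id))
    abort("duplicated item ids: ",
          paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))
  if (any(is.na(items$n_categories)) || any(items$n_categories < 2))
    abort("every item needs n_categories >= 2")
  if (!is.list(subscales) ||
      (length(subscales) > 0 &&
       (is.null(names(subscales)) || any(!nzchar(names(subscales))))))
    abort("`subscales` must be a named list of item-id vectors")
  for (s in names(subscales)) {
    ids <- as.character(subscales[[s]])
    if (length(ids) < 2) abort("subscale '", s, "' has fewer than 2 items")
    if (anyDuplicated(ids)) abort("subscale '", s, "' repeats item ",
                                  ids[duplicated(ids)][1])
    unknown <- setdiff(ids, items$item_id)
    if (length(unknown))
      abort("subscale '", s, "' references unknown item(s): ",
            paste(unknown, collapse = ", "))
    subscales[[s]] <- ids
  }
  rater <- match.arg(rater, c("caregiver", "self"), several.ok = TRUE)
  if (length(age_range) != 2 || any(is.na(age_range)) || age_range[1] > age_range[2])
    abort("`age_range` must be (min, max) with min <= max")
  structure(list(name = name, full_name = full_name, rater = rater,
                 age_range = as.numeric(age_range), items = items,
                 subscales = subscales),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s (%s)\n", x$name, x$full_name))
  cat(sprintf("  rater: %s | ages %g-%g | %d items\n",
              paste(x$rater, collapse = "/"), x$age_range[1], x$age_range[2],
              nrow(x$items)))
  for (s in names(x$subscales))
    cat(sprintf("  subscale %-28s %d items\n", s, length(x$subscales[[s]])))
  invisible(x)
}

#' Load an instrument specification from YAML or JSON
#'
#' The canonical on-disk dialect is YAML (JSON is accepted) with fields
#' `name`, optional `full_name`, `rater`, `age_range`, `response:
#' n_categories` (instrument-wide default), `items` (vector of ids, or a
#' list of `{id, n_categories}` records for mixed formats) and `subscales`
#' (map name -> item-id list).
#'
#' @param path file path to a `.yaml`/`.yml` or `.json` spec.
#' @return A validated [instrument_spec()].
#' @seealso [bundled_instruments()]
#' @export
load_instrument_spec <- function(path) {
  if (!file.exists(path)) abort("instrument spec file not found: ", path)
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path),
    error = function(e) abort("cannot parse instrument spec '", path, "': ",
                              conditionMessage(e), class = "scalenorm_parse_error"))
  for (f in c("name", "items", "subscales"))
    if (is.null(raw[[f]])) abort("instrument spec '", path, "' is missing field '", f, "'",
                                 class = "scalenorm_parse_error")
  default_k <- raw$response$n_categories %||% NULL
  items <- raw$items
  if (is.character(items)) {
    if (is.null(default_k))
      abort("spec '", path, "': items given as plain ids but response$n_categories missing",
            class = "scalenorm_parse_error")
    items <- data.frame(item_id = items, n_categories = as.integer(default_k))
  } else if (is.list(items) && !is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(it) {
      data.frame(item_id = as.character(it$id %||% it$item_id),
                 n_categories = as.integer(it$n_categories %||% default_k))
    }))
  }
  subscales <- lapply(raw$subscales, function(v) as.character(unlist(v)))
  instrument_spec(name = raw$name,
                  items = items,
                  subscales = subscales,
                  rater = unlist(raw$rater) %||% "caregiver",
                  age_range = as.numeric(unlist(raw$age_range) %||% c(1, 18)),
                  full_name = raw$full_name %||% raw$name)
}

#' Bundled instrument specifications
#'
#' Lists (or loads) the instrument structure files shipped with the
#' package: `psc17`, `rcads25`, `snap_iv`, `mchat_rf`, `cast`, `cats2`.
#' CAST uses the 28-item two-factor structure (16 social-contact +
#' 12 inflexible/repetitive items) with the original item numbering up to
#' 37 preserved as ids; CATS-2 covers the 20 PTSD symptom items only (the
#' trauma-exposure checklist is not scored).
#'
#' @param name optional instrument key; if given, returns the loaded
#'   [instrument_spec()], otherwise the named vector of available files.
#' @return Character vector of paths, or one `instrument_spec`.
#' @examples
#' bundled_instruments()
#' psc <- bundled_instruments("psc17")
#' @export
bundled_instruments <- function(name = NULL) {
  dir <- system.file("extdata", "instruments", package = "scalenorm")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  keys <- sub("\\.yaml$", "", basename(files))
  names(files) <- keys
  if (is.null(name)) return(files)
  if (!name %in% keys) abort("unknown bundled instrument '", name, "'; available: ",
                             paste(keys, collapse = ", "))
  load_instrument_spec(files[[name]])
}
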