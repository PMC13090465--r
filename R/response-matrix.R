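#' Person-by-item response matrix
#'
#' Ordinal responses (0-based integer categories) for one instrument, with
#' per-person covariates `age_group` and `gender`. Construction validates
#' every cell against the item's category count.
#'
#' @param responses integer matrix or data.frame, persons in rows, items in
#'   columns; column names are item ids.
#' @param spec the [instrument_spec()] the data belong to.
#' @param age_group,gender per-person labels (recycled if length 1).
#' @param person_ids optional person identifiers (default `p1, p2, ...`).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, spec, age_group = "all", gender = "all",
                            person_ids = NULL) {
  m <- as.matrix(responses)
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) abort("response columns must be named with item ids")
  unknown <- setdiff(colnames(m), spec$items$item_id)
  if (length(unknown)) abort("columns not in instrument '", spec$name, "': ",
                             paste(unknown, collapse = ", "))
  n <- nrow(m)
  if (n < 1) abort("need at least one person")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort("missing cell at row ", bad[1], ", item ", colnames(m)[bad[2]],
          "; see read_responses(missing = 'listwise') for opt-in deletion",
          class = "scalenorm_missing_error")
  }
  k <- spec$items$n_categories[match(colnames(m), spec$items$item_id)]
  for (j in seq_len(ncol(m))) {
    out <- m[, j] < 0L | m[, j] > k[j] - 1L
    if (any(out))
      abort("response out of range [0, ", k[j] - 1, "] for item ",
            colnames(m)[j], " at row ", which(out)[1],
            " (value ", m[which(out)[1], j], ")",
            class = "scalenorm_range_error")
  }
  age_group <- rep_len(as.character(age_group), n)
  gender <- rep_len(as.character(gender), n)
  person_ids <- as.character(person_ids %||% paste0("p", seq_len(n)))
  if (length(person_ids) != n) abort("person_ids length must match rows")
  rownames(m) <- NULL
  structure(list(responses = m, person_ids = person_ids,
                 item_ids = colnames(m), age_group = age_group,
                 gender = gender, spec_name = spec$name),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %s: %d persons x %d items\n", x$spec_name,
              nrow(x$responses), ncol(x$responses)))
  tab <- table(x$age_group, x$gender)
  cat("  strata (age_group x gender):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' @export
as.data.frame.response_matrix <- function(x, ...) {
  data.frame(person_id = x$person_ids, age_group = x$age_group,
             gender = x$gender, x$responses, check.names = FALSE)
}

#' Read responses from delimited text
#'
#' Expects a header row with item-id columns plus covariate columns
#' `age_group` and `gender` (and optionally `person_id`). Cells must be
#' integer categories; sources coded from a different origin (e.g. 1..4)
#' are shifted at ingest with `origin`.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension, or
#'   set `sep`).
#' @param spec the [instrument_spec()] to validate against.
#' @param missing `"error"` (default: any blank cell rejects the file) or
#'   `"listwise"` (drop persons with any missing item, with a message).
#' @param origin integer value the source uses for the lowest category
#'   (default 0); responses are shifted to 0-based at ingest.
#' @param sep field delimiter override.
#' @return A [response_matrix()]; row order of the file is preserved.
#' @export
read_responses <- function(path, spec, missing = c("error", "listwise"),
                           origin = 0L, sep = NULL) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort("responses file not found: ", path)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  item_cols <- intersect(spec$items$item_id, names(df))
  if (length(item_cols) < 2)
    abort("file '", path, "' shares fewer than 2 item columns with instrument ",
          spec$name)
  m <- as.matrix(df[item_cols])
  if (!is.numeric(m)) abort("non-numeric responses in '", path, "'")
  if (origin != 0L) {
    m <- m - as.integer(origin)
    message("read_responses: shifted responses by -", origin,
            " to a 0-based coding")
  }
  keep <- rep(TRUE, nrow(m))
  if (anyNA(m)) {
    if (missing == "error") {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      abort("missing cell at row ", bad[1], ", item ", item_cols[bad[2]],
            " in '", path, "'", class = "scalenorm_missing_error")
    }
    keep <- stats::complete.cases(m)
    message("read_responses: listwise-deleted ",
            plural(sum(!keep), "person"), " with missing items")
    m <- m[keep, , drop = FALSE]
  }
  response_matrix(m, spec,
                  age_group = if ("age_group" %in% names(df)) df$age_group[keep] else "all",
                  gender = if ("gender" %in% names(df)) df$gender[keep] else "all",
                  person_ids = if ("person_id" %in% names(df)) df$person_id[keep] else NULL)
}

#' Write responses to delimited text
#'
#' Inverse of [read_responses()]: writes `person_id`, `age_group`,
#' `gender` and the item columns. Reading the file back reproduces every
#' cell exactly.
#'
#' @param m a [response_matrix()].
#' @param path output file (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_responses <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(m), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Crude summed scores over a subscale
#'
#' @param m a [response_matrix()].
#' @param subscale character vector of item ids (must all be present in
#'   `m`).
#' @return Integer vector, one sum per person, in
#'   `[0, sum(K_j - 1)]`.
#' @export
sum_scores <- function(m, subscale) {
  subscale <- as.character(subscale)
  if (length(subscale) < 1) abort("empty subscale")
  missing_items <- setdiff(subscale, m$item_ids)
  if (length(missing_items)) abort("subscale items not in data: ",
                                   paste(missing_items, collapse = ", "))
  as.integer(rowSums(m$responses[, subscale, drop = FALSE]))
}

## subset a response_matrix by persons (logical or integer index)
subset_persons <- function(m, idx) {
  structure(list(responses = m$responses[idx, , drop = FALSE],
                 person_ids = m$person_ids[idx],
                 item_ids = m$item_ids,
                 age_group = m$age_group[idx], gender = m$gender[idx],
                 spec_name = m$spec_name),
            class = "response_matrix")
}
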