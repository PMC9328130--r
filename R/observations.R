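#' Read and validate an observation table
#'
#' Reads a CSV of paired cover-crop / fallow comparisons, applies the row-level
#' inclusion rules, and returns the rows matching one response variable.
#' Rules applied, in order:
#'
#' * rows whose `response` is not `response` are set aside (counted as
#'   rejected with reason `"response_mismatch"`);
#' * rows with a missing or non-positive treatment or control mean are dropped
#'   (`"non-positive mean"`): the log response ratio is undefined there;
#' * blank replicate counts are imputed as 1 — the convention for studies
#'   reporting only an overall mean — and the imputation is recorded;
#' * replicate counts must be whole numbers `>= 1` (`"invalid replicate count"`).
#'
#' Missing moderator cells are kept as `NA`; such rows stay in the overall
#' analysis and are excluded per-moderator by [filter_moderator_levels()].
#'
#' @param path Path to a UTF-8 CSV with header columns exactly
#'   `article_id, obs_id, response, mean_cc, mean_ncc, n_cc, n_ncc, cc_family,
#'   cc_genus, soil_order, soil_texture, main_crop, tillage, rainfall_mm, temp_c`.
#' @param response Which response variable to keep: `"nitrate_leaching"` or
#'   `"water_drainage"`.
#' @param quiet Suppress the imputation warning.
#'
#' @return A tibble of class `cc_observations`, one row per accepted
#'   observation in input order, with attributes `provenance` (the source
#'   path), `response`, and `validation` (see [validation_report()]).
#' @seealso [validation_report()], [compute_effects()]
#' @export
read_observations <- function(path,
                              response = c("nitrate_leaching", "water_drainage"),
                              quiet = FALSE) {
  response <- match.arg(response)
  if (!file.exists(path)) {
    abort(paste0("cannot read observation table: '", path, "' does not exist"),
          class = "covermeta_io_error")
  }
  raw <- readr::read_csv(path, col_types = obs_col_types, progress = FALSE)
  missing_cols <- setdiff(obs_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("observation table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "covermeta_schema_error")
  }
  validate_observations(raw, response = response, provenance = path, quiet = quiet)
}

# Shared row-level validation for read and synthetic tables.
validate_observations <- function(raw, response, provenance = "in-memory",
                                  quiet = FALSE) {
  raw <- dplyr::select(raw, dplyr::all_of(obs_columns))
  bad_response <- !(raw$response %in% response)
  bad_mean <- !bad_response &
    (is.na(raw$mean_cc) | is.na(raw$mean_ncc) |
       raw$mean_cc <= 0 | raw$mean_ncc <= 0)

  imputed <- (is.na(raw$n_cc) | is.na(raw$n_ncc)) & !bad_response & !bad_mean
  n_cc <- dplyr::coalesce(raw$n_cc, 1)
  n_ncc <- dplyr::coalesce(raw$n_ncc, 1)
  bad_n <- !bad_response & !bad_mean &
    (n_cc < 1 | n_ncc < 1 | n_cc != round(n_cc) | n_ncc != round(n_ncc))

  reasons <- dplyr::bind_rows(
    tibble::tibble(obs_id = raw$obs_id[bad_response], reason = "response_mismatch"),
    tibble::tibble(obs_id = raw$obs_id[bad_mean], reason = "non-positive mean"),
    tibble::tibble(obs_id = raw$obs_id[bad_n], reason = "invalid replicate count")
  )

  keep <- !bad_response & !bad_mean & !bad_n
  obs <- raw[keep, , drop = FALSE]
  obs$n_cc <- as.integer(round(n_cc[keep]))
  obs$n_ncc <- as.integer(round(n_ncc[keep]))

  if (anyDuplicated(obs$obs_id)) {
    abort("obs_id values must be unique within an observation table",
          class = "covermeta_schema_error")
  }

  imputed_ids <- raw$obs_id[imputed & keep]
  if (length(imputed_ids) > 0 && !quiet) {
    shown <- paste(head(imputed_ids, 5), collapse = ", ")
    if (length(imputed_ids) > 5) shown <- paste0(shown, ", ...")
    warn(paste0("imputed n = 1 for ", length(imputed_ids),
                " row(s) with blank replicate counts (", shown, ")"))
  }

  new_cc_observations(
    obs,
    response = response,
    provenance = provenance,
    validation = list(
      accepted = sum(keep),
      rejected = sum(!keep),
      n_imputed = length(imputed_ids),
      imputed_obs_ids = imputed_ids,
      reasons = reasons
    )
  )
}

new_cc_observations <- function(x, response, provenance, validation) {
  out <- tibble::as_tibble(x)
  attr(out, "response") <- response
  attr(out, "provenance") <- provenance
  attr(out, "validation") <- validation
  class(out) <- c("cc_observations", class(out))
  out
}

#' Row-level validation report of an observation table
#'
#' @param obs A `cc_observations` tibble from [read_observations()] or
#'   [simulate_observations()].
#' @return A list with counts `accepted`, `rejected`, `n_imputed` (blank
#'   replicate counts imputed as 1) and a tibble `reasons` of
#'   `(obs_id, reason)` for every rejected row. `accepted + rejected` equals
#'   the input row count.
#' @export
validation_report <- function(obs) {
  rep <- attr(obs, "validation")
  if (is.null(rep)) {
    abort("no validation report attached; was this read with read_observations()?")
  }
  rep
}

#' Restrict a moderator to adequately supported levels
#'
#' A moderator level enters subgroup analysis only when it is supported by at
#' least `min_articles` distinct articles; rows whose moderator value is
#' missing, or whose level falls below that support, are dropped. At least
#' `min_levels` levels must survive, otherwise the moderator cannot be
#' partitioned and an error of class `covermeta_precondition_error` is raised.
#'
#' When `article_id` is entirely missing the article rule degrades, with a
#' warning, to counting observations instead.
#'
#' The operation is idempotent: filtering an already-filtered table changes
#' nothing.
#'
#' @param data A tibble carrying `article_id` and the moderator column
#'   (observations or effect records).
#' @param moderator Name of the moderator column (string).
#' @param min_articles Minimum distinct articles per retained level.
#' @param min_levels Minimum surviving levels.
#' @return The filtered tibble, input order and attributes preserved.
#' @export
filter_moderator_levels <- function(data, moderator, min_articles = 3,
                                    min_levels = 2) {
  if (!moderator %in% names(data)) {
    abort(paste0("unknown moderator column: ", moderator),
          class = "covermeta_schema_error")
  }
  values <- data[[moderator]]
  present <- !is.na(values) & values != ""

  if (!"article_id" %in% names(data) || all(is.na(data$article_id))) {
    warn("article_id unavailable; level support counted in observations, not articles")
    support <- table(values[present])
  } else {
    sup <- dplyr::distinct(
      tibble::tibble(level = values[present],
                     article = data$article_id[present])
    )
    support <- table(sup$level)
  }
  keep_levels <- names(support)[support >= min_articles]
  if (length(keep_levels) < min_levels) {
    abort(paste0("moderator '", moderator, "' has ", length(keep_levels),
                 " level(s) supported by >= ", min_articles,
                 " articles; at least ", min_levels, " required"),
          class = "covermeta_precondition_error")
  }
  out <- data[present & values %in% keep_levels, , drop = FALSE]
  for (a in c("response", "provenance", "validation", "truth")) {
    if (!is.null(attr(data, a))) attr(out, a) <- attr(data, a)
  }
  out
}

#' Write a result table as CSV
#'
#' Writes deterministic CSV output: columns and rows in the order given,
#' numeric columns rendered to 6 significant digits, so re-running on the same
#' input produces a byte-identical file.
#'
#' @param rows Non-empty data frame of homogeneous result records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort("result table must be a non-empty data frame")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(rows),
    dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.cc_observations <- function(x, ...) {
  rep <- attr(x, "validation")
  cat("<cc_observations> ", nrow(x), " observations (",
      attr(x, "response"), ")\n", sep = "")
  if (!is.null(rep)) {
    cat("  accepted ", rep$accepted, ", rejected ", rep$rejected,
        ", replicate counts imputed ", rep$n_imputed, "\n", sep = "")
  }
  NextMethod()
}
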