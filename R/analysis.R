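#' Run the full moderator analysis for one response variable
#'
#' Orchestrates the per-response pipeline: compute effect records, then for
#' each requested moderator apply the level-support filter
#' ([filter_moderator_levels()]) and the subgroup Q-partition
#' ([subgroup_partition()]). Moderators that fail their preconditions (too few
#' supported levels, all values missing) are skipped with a recorded reason,
#' never fatally. The overall pooled estimate and heterogeneity are computed
#' on the full, unfiltered (response-matched) effect set.
#'
#' @param obs A `cc_observations` tibble (or any observation table with the
#'   standard columns).
#' @param response Response to analyse; defaults to the table's `response`
#'   attribute (or its single `response` value).
#' @param moderators Character vector of moderator columns to partition by.
#' @param min_articles,min_levels Level-support rule passed to
#'   [filter_moderator_levels()].
#' @param tau2_mode,ci_level Passed to [subgroup_partition()].
#' @param hetero_alpha Significance convention for the heterogeneity p-value
#'   (recorded in the config; the low-power Q test is usually read at .10).
#' @return An object of class `cc_analysis`: list with `response`, `overall`
#'   (pooled + heterogeneity one-row tibble), `tables` (named list of
#'   `cc_subgroup`), `skipped` (tibble of moderator/reason), `config`, `log`.
#' @export
run_analysis <- function(obs,
                         response = NULL,
                         moderators = moderator_columns,
                         min_articles = 3,
                         min_levels = 2,
                         tau2_mode = c("separate", "pooled"),
                         ci_level = 0.95,
                         hetero_alpha = 0.10) {
  tau2_mode <- match.arg(tau2_mode)
  response <- response %||% attr(obs, "response") %||% unique(obs$response)
  if (length(response) != 1 || !response %in% response_levels) {
    abort("response must be one of 'nitrate_leaching', 'water_drainage'",
          class = "covermeta_domain_error")
  }
  if ("response" %in% names(obs)) {
    obs <- obs[obs$response == response, , drop = FALSE]
  }
  if (nrow(obs) == 0) {
    abort(paste0("no observations for response '", response, "'"),
          class = "covermeta_domain_error")
  }

  effects <- compute_effects(obs)
  overall <- dplyr::bind_cols(
    dplyr::select(cochran_q(effects), "Q", "df", "p_hetero", "I2"),
    pool_random(effects, ci_level = ci_level)
  )

  log_lines <- character()
  skipped <- tibble::tibble(moderator = character(), reason = character())
  tables <- list()
  for (m in moderators) {
    res <- tryCatch(
      {
        filtered <- filter_moderator_levels(effects, m,
                                            min_articles = min_articles,
                                            min_levels = min_levels)
        subgroup_partition(filtered, m, tau2_mode = tau2_mode,
                           ci_level = ci_level)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped <- dplyr::bind_rows(
        skipped, tibble::tibble(moderator = m, reason = conditionMessage(res))
      )
      log_lines <- c(log_lines, paste0("skip ", m, ": ", conditionMessage(res)))
    } else {
      tables[[m]] <- res
      log_lines <- c(log_lines,
                     paste0("moderator ", m, ": ", nrow(res$levels),
                            " levels, n = ", res$overall$k))
    }
  }

  structure(
    list(
      response = response,
      overall = overall,
      tables = tables,
      skipped = skipped,
      config = list(
        response = response, moderators = moderators,
        min_articles = min_articles, min_levels = min_levels,
        tau2_mode = tau2_mode, ci_level = ci_level,
        hetero_alpha = hetero_alpha
      ),
      log = log_lines
    ),
    class = "cc_analysis"
  )
}

#' Tillage-intensity contrast
#'
#' Convenience wrapper: the subgroup partition of effect sizes across
#' conventional (CT), reduced (RT), and no-tillage (NT) management, with
#' per-level percent change.
#'
#' @inheritParams run_analysis
#' @param ... Passed to [subgroup_partition()].
#' @return A `cc_subgroup` object for the `tillage` moderator.
#' @export
tillage_contrast <- function(obs, response = NULL, min_articles = 3, ...) {
  run <- run_analysis(obs, response = response, moderators = "tillage",
                      min_articles = min_articles, ...)
  if (is.null(run$tables$tillage)) {
    abort(paste0("tillage contrast unavailable: ", run$skipped$reason[1]),
          class = "covermeta_precondition_error")
  }
  run$tables$tillage
}

#' @describeIn run_analysis All moderator tables bound into one tibble with a
#'   leading `moderator` column.
#' @param x,object A `cc_analysis` object.
#' @param ... Unused.
#' @export
tidy.cc_analysis <- function(x, ...) {
  if (length(x$tables) == 0) {
    abort("no moderator tables in this analysis run")
  }
  purrr::imap(x$tables, ~ dplyr::mutate(tidy(.x), moderator = .y,
                                        .before = 1)) |>
    dplyr::bind_rows()
}

#' @describeIn run_analysis One-row overall summary for the response.
#' @export
glance.cc_analysis <- function(x, ...) {
  dplyr::mutate(x$overall, response = x$response, .before = 1)
}

#' @export
print.cc_analysis <- function(x, ...) {
  cat("<cc_analysis> response:", x$response, "\n")
  cat("  overall: k =", x$overall$k,
      " ln(R) =", signif(x$overall$es, 4),
      " (", signif(x$overall$pct_change, 3), "% change)",
      " I2 =", signif(x$overall$I2, 3), "%\n")
  cat("  moderators analysed:", paste(names(x$tables), collapse = ", "), "\n")
  if (nrow(x$skipped) > 0) {
    cat("  skipped:", paste(x$skipped$moderator, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the tables of an analysis run to a directory
#'
#' One CSV per moderator (`<moderator>.csv`, the [tidy()] layout) plus
#' `overall.csv`. Used by the command-line interface and handy for scripted
#' runs.
#'
#' @param run A `cc_analysis` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(run$tables)) {
    write_results_table(tidy(run$tables[[m]]), file.path(dir, paste0(m, ".csv")))
  }
  write_results_table(glance(run), file.path(dir, "overall.csv"))
  invisible(dir)
}
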