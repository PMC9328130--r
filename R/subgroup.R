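#' Subgroup heterogeneity partition for one moderator
#'
#' Splits the fixed-effect heterogeneity of a set of effect records by the
#' levels of a categorical moderator, in the additive layout of classic
#' moderator tables:
#'
#' * per level: Cochran Q, df, p, I-squared on that level's records, plus a
#'   random-effects pooled estimate;
#' * `total_within`: the sum of the level Q's and df's — residual
#'   heterogeneity not explained by the moderator;
#' * `total_between`: `Q_overall - Q_within` on `levels - 1` df — the
#'   heterogeneity the moderator accounts for;
#' * `overall`: Q and pooled estimate on all records together.
#'
#' All Q statistics use fixed-effect weights `1/v`, which makes the partition
#' exactly additive: `Q_within + Q_between = Q_overall`.
#'
#' By default each level gets its own DerSimonian-Laird tau-squared
#' (`tau2_mode = "separate"`); `"pooled"` estimates one common tau-squared
#' from the within-level moment equations and applies it to every level.
#'
#' @param effects Tibble of effect records (from [compute_effects()]),
#'   normally already restricted by [filter_moderator_levels()]; the moderator
#'   must be non-missing on every record.
#' @param moderator Moderator column name (string).
#' @param tau2_mode `"separate"` (default) or `"pooled"`.
#' @param ci_level Confidence level for pooled intervals.
#' @return An object of class `cc_subgroup`: a list with `moderator`,
#'   `levels` (per-level tibble), `total_within`, `total_between`, `overall`.
#'   Use [tidy()] for the flat table and [autoplot()] for a forest plot.
#' @export
subgroup_partition <- function(effects, moderator,
                               tau2_mode = c("separate", "pooled"),
                               ci_level = 0.95) {
  tau2_mode <- match.arg(tau2_mode)
  check_effects(effects, 1, "subgroup_partition()")
  if (!moderator %in% names(effects)) {
    abort(paste0("moderator '", moderator, "' absent from effect records"),
          class = "covermeta_domain_error")
  }
  values <- effects[[moderator]]
  if (any(is.na(values) | values == "")) {
    abort(paste0("moderator '", moderator, "' has missing values; ",
                 "apply filter_moderator_levels() first"),
          class = "covermeta_domain_error")
  }

  by_level <- split(seq_len(nrow(effects)), values)
  level_stats <- purrr::map(by_level, function(idx) {
    grp <- effects[idx, , drop = FALSE]
    list(het = cochran_q(grp),
         C = sum(1 / grp$v) - sum(1 / grp$v^2) / sum(1 / grp$v),
         grp = grp)
  })

  tau2_pooled <- NULL
  if (tau2_mode == "pooled") {
    # one moment equation across levels: residual Q against residual df
    Qw <- sum(purrr::map_dbl(level_stats, ~ .x$het$Q))
    dfw <- sum(purrr::map_dbl(level_stats, ~ .x$het$df))
    Cw <- sum(purrr::map_dbl(level_stats, ~ .x$C))
    tau2_pooled <- if (Cw > 0) max(0, (Qw - dfw) / Cw) else 0
  }

  levels_tbl <- purrr::imap(level_stats, function(st, lev) {
    pooled <- pool_random(
      st$grp,
      tau2 = if (is.null(tau2_pooled)) NULL else tau2_pooled,
      ci_level = ci_level
    )
    dplyr::bind_cols(
      tibble::tibble(level = lev, n = st$het$k,
                     Q = st$het$Q, df = st$het$df,
                     p_hetero = st$het$p_hetero, I2 = st$het$I2),
      dplyr::select(pooled, -"k")
    )
  })
  levels_tbl <- dplyr::bind_rows(levels_tbl)

  overall_het <- cochran_q(effects)
  overall_pooled <- pool_random(effects, ci_level = ci_level)
  q_within <- sum(levels_tbl$Q)
  df_within <- sum(levels_tbl$df)
  q_between <- overall_het$Q - q_within
  df_between <- nrow(levels_tbl) - 1L

  structure(
    list(
      moderator = moderator,
      tau2_mode = tau2_mode,
      levels = levels_tbl,
      total_within = tibble::tibble(
        Q = q_within, df = df_within,
        p = if (df_within == 0) 1 else pchisq(q_within, df_within, lower.tail = FALSE)
      ),
      total_between = tibble::tibble(
        Q = q_between, df = df_between,
        p = if (df_between == 0) 1 else
          pchisq(max(0, q_between), df_between, lower.tail = FALSE)
      ),
      overall = dplyr::bind_cols(
        dplyr::select(overall_het, "Q", "df", "p_hetero", "I2"),
        overall_pooled
      )
    ),
    class = "cc_subgroup"
  )
}

#' @describeIn subgroup_partition Flat moderator table: one row per level plus
#'   `Total within`, `Total between`, and `Overall` rows, mirroring the usual
#'   published layout (`level, n, Q, df, p_hetero, I2`, then the pooled
#'   columns).
#' @param x,object A `cc_subgroup` object.
#' @param ... Unused.
#' @export
tidy.cc_subgroup <- function(x, ...) {
  pooled_cols <- c("es", "se", "ci_low", "ci_high", "z", "p", "tau2", "pct_change")
  overall <- dplyr::bind_cols(
    tibble::tibble(level = "Overall", n = x$overall$k),
    dplyr::select(x$overall, "Q", "df", "p_hetero", "I2",
                  dplyr::all_of(pooled_cols))
  )
  dplyr::bind_rows(
    x$levels,
    tibble::tibble(level = "Total within", Q = x$total_within$Q,
                   df = x$total_within$df, p_hetero = x$total_within$p),
    tibble::tibble(level = "Total between", Q = x$total_between$Q,
                   df = x$total_between$df, p_hetero = x$total_between$p),
    overall
  )
}

#' @describeIn subgroup_partition One-row summary: overall heterogeneity,
#'   pooled effect, and the between-level test.
#' @export
glance.cc_subgroup <- function(x, ...) {
  tibble::tibble(
    moderator = x$moderator,
    k = x$overall$k,
    levels = nrow(x$levels),
    Q = x$overall$Q,
    df = x$overall$df,
    p_hetero = x$overall$p_hetero,
    I2 = x$overall$I2,
    Q_between = x$total_between$Q,
    df_between = x$total_between$df,
    p_between = x$total_between$p,
    es = x$overall$es,
    pct_change = x$overall$pct_change
  )
}

#' @describeIn subgroup_partition Forest plot of per-level percent change with
#'   back-transformed confidence intervals; the dashed line marks no effect,
#'   the dotted line the overall pooled change.
#' @export
autoplot.cc_subgroup <- function(object, ...) {
  dat <- dplyr::mutate(
    object$levels,
    pct_low = 100 * expm1(.data$ci_low),
    pct_high = 100 * expm1(.data$ci_high),
    label = paste0(.data$level, " (n=", .data$n, ")")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pct_change,
                                    y = stats::reorder(.data$label, .data$pct_change))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$overall$pct_change,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pct_low,
                                         xmax = .data$pct_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "% change (cover crop vs. fallow)",
      y = NULL,
      title = paste("Moderator:", object$moderator)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.cc_subgroup <- function(x, ...) {
  cat("<cc_subgroup> moderator:", x$moderator,
      "(tau2:", paste0(x$tau2_mode, ")"), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
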