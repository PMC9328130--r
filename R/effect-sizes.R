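#' Log response-ratio effect size
#'
#' The effect size is the natural log of the ratio of the cover-crop mean to
#' the fallow (no-cover-crop) control mean, \eqn{\ln R = \ln(\bar X_{CC} /
#' \bar X_{NCC})}. Negative values mean the cover crop reduced the response.
#' The log keeps increases and decreases symmetric, and the ratio is
#' unit-free, so treatment/control pairs in any common unit are comparable.
#'
#' @param mean_cc,mean_ncc Strictly positive treatment and control means
#'   (vectorised).
#' @return `ln(mean_cc / mean_ncc)`.
#' @examples
#' log_response_ratio(31, 100)   # about -1.171
#' percent_change(log_response_ratio(31, 100))  # -69%
#' @export
log_response_ratio <- function(mean_cc, mean_ncc) {
  if (any(!is.finite(mean_cc)) || any(!is.finite(mean_ncc)) ||
      any(mean_cc <= 0) || any(mean_ncc <= 0)) {
    abort("log_response_ratio() needs strictly positive, finite means",
          class = "covermeta_domain_error")
  }
  log(mean_cc / mean_ncc)
}

#' Nonparametric variance of the log response ratio
#'
#' Field syntheses often pool studies that report no dispersion at all, so the
#' variance of \eqn{\ln R} is approximated from replicate counts alone:
#' \eqn{v = (n_{CC} + n_{NCC}) / (n_{CC} \, n_{NCC})}. It is strictly
#' decreasing in each count and equals 2 at the minimum `n = 1/1` — the value
#' carried by single-report studies.
#'
#' @param n_cc,n_ncc Integer replicate counts `>= 1` (vectorised).
#' @return The variance `(n_cc + n_ncc) / (n_cc * n_ncc)`.
#' @examples
#' nonparametric_variance(1, 1)  # 2
#' nonparametric_variance(4, 4)  # 0.5
#' @export
nonparametric_variance <- function(n_cc, n_ncc) {
  ok <- is.finite(n_cc) & is.finite(n_ncc) &
    n_cc >= 1 & n_ncc >= 1 &
    n_cc == round(n_cc) & n_ncc == round(n_ncc)
  if (!all(ok)) {
    abort("replicate counts must be whole numbers >= 1",
          class = "covermeta_domain_error")
  }
  # compute in double: integer counts can overflow the product
  n_cc <- as.numeric(n_cc)
  n_ncc <- as.numeric(n_ncc)
  (n_cc + n_ncc) / (n_cc * n_ncc)
}

#' Back-transform a log response ratio to percent change
#'
#' `100 * (exp(es) - 1)`: the percent difference of the treatment relative to
#' the control. A pooled ratio of 0.31 reads as a 69% reduction.
#'
#' @param es Log response ratio(s).
#' @return Percent change, in `(-100, Inf)`, same sign as `es`.
#' @export
percent_change <- function(es) {
  if (any(!is.finite(es))) {
    abort("percent_change() needs finite effect sizes",
          class = "covermeta_domain_error")
  }
  100 * expm1(es)
}

#' Compute effect records for an observation table
#'
#' Turns each observation into an effect record: the log response ratio `es`,
#' its nonparametric variance `v`, and the fixed-effect weight
#' `w_fixed = 1/v`, with moderators and covariates carried through for
#' downstream subgrouping and meta-regression. Row order is preserved.
#'
#' @param obs A validated `cc_observations` tibble.
#' @return A tibble with columns `obs_id`, `article_id`, `response`, `es`,
#'   `v`, `w_fixed`, the moderator columns, and the covariate columns.
#' @export
compute_effects <- function(obs) {
  if (!is.data.frame(obs) || nrow(obs) == 0) {
    abort("compute_effects() needs a non-empty observation table",
          class = "covermeta_domain_error")
  }
  missing_cols <- setdiff(c("obs_id", "mean_cc", "mean_ncc", "n_cc", "n_ncc"),
                          names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("observation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "covermeta_schema_error")
  }
  bad <- which(!is.finite(obs$mean_cc) | !is.finite(obs$mean_ncc) |
                 obs$mean_cc <= 0 | obs$mean_ncc <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive mean for obs_id: ",
                 paste(head(obs$obs_id[bad], 5), collapse = ", ")),
          class = "covermeta_domain_error")
  }
  carried <- intersect(c("article_id", "response",
                         moderator_columns, covariate_columns), names(obs))
  v <- nonparametric_variance(obs$n_cc, obs$n_ncc)
  dplyr::bind_cols(
    tibble::tibble(
      obs_id = obs$obs_id,
      es = log_response_ratio(obs$mean_cc, obs$mean_ncc),
      v = v,
      w_fixed = 1 / v
    ),
    dplyr::select(tibble::as_tibble(obs), dplyr::all_of(carried))
  )
}
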