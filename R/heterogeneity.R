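# Fixed-effect building blocks shared across the pipeline.
check_effects <- function(effects, k_min = 1, caller = "this function") {
  if (!is.data.frame(effects) || !all(c("es", "v") %in% names(effects))) {
    abort(paste0(caller, " needs a tibble with columns es and v"),
          class = "covermeta_domain_error")
  }
  if (nrow(effects) < k_min) {
    abort(paste0(caller, " needs at least ", k_min, " effect record(s)"),
          class = "covermeta_domain_error")
  }
  if (any(!is.finite(effects$v)) || any(effects$v <= 0)) {
    abort("all effect-size variances must be positive and finite",
          class = "covermeta_domain_error")
  }
  invisible(effects)
}

fixed_mean <- function(es, v) {
  w <- 1 / v
  sum(w * es) / sum(w)
}

#' Cochran's Q heterogeneity statistic
#'
#' The weighted sum of squared deviations of the effect sizes from their
#' fixed-effect weighted mean, `Q = sum(w_i (es_i - es_bar)^2)` with
#' `w_i = 1/v_i`, referred to a chi-square distribution on `k - 1` degrees of
#' freedom. The heterogeneity p-value is conventionally read against .10
#' because the Q test has low power.
#'
#' @param effects Tibble of effect records with columns `es` and `v`.
#' @return One-row tibble with `k`, `Q`, `df`, `p_hetero`, and `I2` (percent).
#'   A single record gives `Q = 0`, `df = 0`, `p_hetero = 1`.
#' @export
cochran_q <- function(effects) {
  check_effects(effects, 1, "cochran_q()")
  es <- effects$es
  v <- effects$v
  k <- length(es)
  w <- 1 / v
  Q <- sum(w * (es - fixed_mean(es, v))^2)
  df <- k - 1L
  p <- if (df == 0L) 1 else pchisq(Q, df, lower.tail = FALSE)
  tibble::tibble(k = k, Q = Q, df = df, p_hetero = p, I2 = i_squared(Q, df))
}

#' I-squared: the share of variation due to true heterogeneity
#'
#' `I2 = max(0, (Q - df) / Q * 100)`: the percentage of total observed
#' variation attributable to between-study differences in true effects rather
#' than sampling error. It truncates to exactly 0 whenever `Q <= df`
#' (observed spread no larger than expected by chance) and is defined as 0 at
#' `Q = 0`.
#'
#' @param Q Non-negative Cochran Q value(s).
#' @param df Degrees of freedom (`k - 1`), non-negative.
#' @return I-squared in percent, in `[0, 100)`. Vectorised.
#' @examples
#' i_squared(943, 131)  # 86.1 (strong heterogeneity)
#' i_squared(2, 9)      # 0    (Q below its expectation)
#' @export
i_squared <- function(Q, df) {
  if (any(!is.finite(Q)) || any(Q < 0) || any(df < 0)) {
    abort("i_squared() needs Q >= 0 and df >= 0",
          class = "covermeta_domain_error")
  }
  ifelse(Q <= 0, 0, pmax(0, (Q - df) / Q * 100))
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimate of the variance of true effects,
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)` and
#' fixed-effect weights `w = 1/v`. Truncates to 0 when `Q <= df`.
#'
#' @param effects Tibble of effect records with columns `es` and `v`.
#' @return The estimate (scalar, `>= 0`). With fewer than two records the
#'   estimate is 0, with a warning.
#' @export
dl_tau2 <- function(effects) {
  check_effects(effects, 1, "dl_tau2()")
  if (nrow(effects) < 2) {
    warn("tau-squared is not estimable from fewer than two records; returning 0")
    return(0)
  }
  w <- 1 / effects$v
  Q <- cochran_q(effects)$Q
  df <- nrow(effects) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - df) / C)
}

#' Random-effects pooled estimate
#'
#' Pools effect records under the random-effects model: true effects vary
#' across studies with variance `tau2`, so each record is weighted
#' `1 / (v_i + tau2)`. The pooled log ratio, its standard error, a normal-
#' theory confidence interval, the z test against zero, and the
#' back-transformed percent change are returned.
#'
#' @param effects Tibble of effect records with columns `es` and `v`.
#' @param tau2 Between-study variance. Default `NULL` estimates it by
#'   [dl_tau2()]; pass a value to reuse an external estimate (e.g. a pooled
#'   subgroup tau-squared).
#' @param ci_level Confidence level (default 0.95).
#' @return One-row tibble: `k, es, se, ci_low, ci_high, z, p, tau2,
#'   pct_change`.
#' @export
pool_random <- function(effects, tau2 = NULL, ci_level = 0.95) {
  check_effects(effects, 1, "pool_random()")
  k <- nrow(effects)
  if (is.null(tau2)) {
    tau2 <- if (k < 2) 0 else dl_tau2(effects)
  }
  stopifnot(tau2 >= 0)
  w <- 1 / (effects$v + tau2)
  es <- sum(w * effects$es) / sum(w)
  se <- sqrt(1 / sum(w))
  crit <- qnorm(1 - (1 - ci_level) / 2)
  z <- es / se
  tibble::tibble(
    k = k, es = es, se = se,
    ci_low = es - crit * se, ci_high = es + crit * se,
    z = z, p = 2 * pnorm(-abs(z)),
    tau2 = tau2, pct_change = percent_change(es)
  )
}
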