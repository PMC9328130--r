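#' Standardized deviates for the rank-correlation bias test
#'
#' Each effect is centred on the fixed-effect pooled mean and standardized by
#' the variance of that deviation:
#' \eqn{t_i = (es_i - \bar{es}) / \sqrt{v_i - 1/\sum w}}, where
#' \eqn{\bar{es}} is the fixed-effect mean and \eqn{w = 1/v}. Subtracting
#' `1/sum(w)` removes the part of each study's variance already absorbed by
#' the pooled mean, so under homogeneity the deviates are (approximately)
#' standard normal and independent of study size.
#'
#' @param effects Tibble of effect records with columns `es` and `v`.
#' @return Numeric vector of deviates, one per record.
#' @export
standardized_deviates <- function(effects) {
  check_effects(effects, 2, "standardized_deviates()")
  w <- 1 / effects$v
  centre <- fixed_mean(effects$es, effects$v)
  vstar <- effects$v - 1 / sum(w)
  if (any(vstar <= 0)) {
    abort("degenerate deviate variance (v_i <= 1/sum(w)); too few records",
          class = "covermeta_domain_error")
  }
  (effects$es - centre) / sqrt(vstar)
}

# Kendall S, tie-corrected tau-b, and the tie counts, by pairwise signs.
kendall_stats <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  S <- sum(sx[up] * sy[up])
  k <- length(x)
  n0 <- k * (k - 1) / 2
  tie_term <- function(z) {
    t <- table(z)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x)
  n2 <- tie_term(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  list(S = S, tau = if (denom > 0) S / denom else NA_real_, n0 = n0,
       all_tied_y = n2 == n0)
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Tests whether effect sizes tend to grow as study precision falls — the
#' signature of small-study selection — by rank-correlating the standardized
#' deviates ([standardized_deviates()]) with the effect-size variances.
#' Kendall's tau-b (tie-corrected denominator) is used because the
#' nonparametric variances take few distinct values (every `n = 1/1` pair has
#' `v = 2`), so ties are pervasive. The test statistic is the concordance
#' score S with null variance `k (k-1) (2k+5) / 18` and a continuity
#' correction; an absolute tau below 0.20 is conventionally read as no
#' evidence of bias.
#'
#' @param effects Tibble of effect records with columns `es` and `v`
#'   (at least 3 rows).
#' @return Object of class `cc_begg` with fields `k`, `tau`, `z`,
#'   `p_two_tailed`, `threshold_flag` (`|tau| < 0.20`). [tidy()] returns the
#'   one-row tibble.
#' @export
begg_mazumdar <- function(effects) {
  check_effects(effects, 3, "begg_mazumdar()")
  t_i <- standardized_deviates(effects)
  ks <- kendall_stats(t_i, effects$v)
  if (ks$all_tied_y || is.na(ks$tau)) {
    warn("all variances tied; rank correlation undefined, reporting tau = 0")
    tau <- 0
    S <- 0
  } else {
    tau <- ks$tau
    S <- ks$S
  }
  k <- nrow(effects)
  var_s <- k * (k - 1) * (2 * k + 5) / 18
  z <- if (S == 0) 0 else (S - sign(S)) / sqrt(var_s)
  structure(
    list(k = k, tau = tau, z = z,
         p_two_tailed = 2 * pnorm(-abs(z)),
         threshold_flag = abs(tau) < 0.20),
    class = "cc_begg"
  )
}

#' @describeIn begg_mazumdar One-row tibble of the test result.
#' @param x A `cc_begg` object.
#' @param ... Unused.
#' @export
tidy.cc_begg <- function(x, ...) {
  tibble::tibble(k = x$k, tau = x$tau, z = x$z,
                 p_two_tailed = x$p_two_tailed,
                 threshold_flag = x$threshold_flag)
}

#' @export
glance.cc_begg <- function(x, ...) tidy(x)

#' @export
print.cc_begg <- function(x, ...) {
  cat("Begg-Mazumdar rank correlation (k =", x$k, ")\n")
  cat("  Kendall tau =", signif(x$tau, 3),
      " z =", signif(x$z, 3),
      " two-tailed p =", signif(x$p_two_tailed, 3), "\n")
  cat(if (x$threshold_flag) "  |tau| < 0.20: no evidence of publication bias\n"
      else "  |tau| >= 0.20: possible small-study effect\n")
  invisible(x)
}

#' Funnel-plot data
#'
#' Effect size against its standard error for each record, with the fixed-
#' and random-effects pooled means attached as reference lines.
#'
#' @param effects Tibble of effect records with columns `es` and `v`.
#' @return Tibble `(obs_id, es, se)` with attributes `es_fixed` and
#'   `es_random`.
#' @export
funnel_data <- function(effects) {
  check_effects(effects, 1, "funnel_data()")
  out <- tibble::tibble(
    obs_id = effects$obs_id %||% as.character(seq_len(nrow(effects))),
    es = effects$es,
    se = sqrt(effects$v)
  )
  attr(out, "es_fixed") <- fixed_mean(effects$es, effects$v)
  attr(out, "es_random") <- pool_random(effects)$es
  out
}

#' Funnel plot
#'
#' Scatter of effect sizes against standard error (inverted axis, the usual
#' funnel orientation), with the fixed- (solid) and random-effects (dashed)
#' pooled means.
#'
#' @param effects Effect records, or the output of [funnel_data()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(effects) {
  dat <- if (!is.null(attr(effects, "es_fixed"))) effects else funnel_data(effects)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$es, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = attr(dat, "es_fixed")) +
    ggplot2::geom_vline(xintercept = attr(dat, "es_random"), linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "ln(R)", y = "standard error") +
    ggplot2::theme_minimal()
}
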