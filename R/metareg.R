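# Restricted log-likelihood of tau2 for the weighted regression
# es_i = x_i' beta + u_i + e_i, u ~ N(0, tau2), e_i ~ N(0, v_i).
# Profiled over beta; constants dropped.
reml_loglik <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  r <- y - X %*% beta
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

#' Single-covariate random-effects meta-regression (REML)
#'
#' Regresses the log response ratio on one numeric study-level covariate under
#' the random-effects model: `es_i = b0 + b1 x_i + u_i + e_i` with
#' `u_i ~ N(0, tau2)` and known sampling variances `e_i ~ N(0, v_i)`. The
#' residual heterogeneity `tau2` is estimated by restricted maximum
#' likelihood, profiled over the coefficients and maximised by bounded
#' one-dimensional search on `[0, 10 Var(es)]` (convergence tolerance 1e-8);
#' coefficients are then weighted least squares at the REML `tau2`. The model
#' test `Q_model` is the Wald chi-square of the slope on 1 df. The covariate
#' is used uncentred, so the intercept is the predicted log ratio at
#' covariate zero.
#'
#' Rows with a missing covariate are dropped for this regression only (count
#' reported via a message).
#'
#' @param effects Tibble of effect records carrying the covariate column.
#' @param covariate Covariate column name, e.g. `"rainfall_mm"` or `"temp_c"`.
#' @param ci_level Confidence level.
#' @param knapp_hartung Use the Knapp-Hartung adjustment (scaled variances, t
#'   reference on `k - 2` df) instead of the default normal reference.
#' @return Object of class `cc_metareg`; [tidy()] gives the
#'   intercept/slope table (estimate, SE, CI, p), [glance()] the model-level
#'   row (`k, tau2, Q_model, df_model, p_model`).
#' @export
fit_meta_regression <- function(effects, covariate, ci_level = 0.95,
                                knapp_hartung = FALSE) {
  check_effects(effects, 1, "fit_meta_regression()")
  if (!covariate %in% names(effects)) {
    abort(paste0("covariate '", covariate, "' absent from effect records"),
          class = "covermeta_domain_error")
  }
  x_all <- effects[[covariate]]
  keep <- is.finite(x_all)
  if (sum(!keep) > 0) {
    inform(paste0("dropping ", sum(!keep), " row(s) with missing ", covariate))
  }
  dat <- effects[keep, , drop = FALSE]
  k <- nrow(dat)
  if (k < 3) {
    abort("meta-regression needs at least 3 records with the covariate",
          class = "covermeta_domain_error")
  }
  x <- dat[[covariate]]
  if (length(unique(x)) < 2) {
    abort(paste0("covariate '", covariate, "' is constant"),
          class = "covermeta_domain_error")
  }
  y <- dat$es
  v <- dat$v
  X <- cbind(intercept = 1, slope = x)

  ub <- max(10 * var(y), 1e-3)
  opt <- optimize(function(t2) reml_loglik(t2, y, X, v),
                  interval = c(0, ub), maximum = TRUE, tol = 1e-8)
  tau2 <- opt$maximum
  # optimize() cannot land exactly on the boundary; snap to zero when the
  # boundary value is at least as good
  if (tau2 < 1e-10 || reml_loglik(0, y, X, v) >= opt$objective) tau2 <- 0

  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, w * X)
  beta <- drop(solve(XtWX, crossprod(X, w * y)))
  vcov_beta <- solve(XtWX)
  r <- y - drop(X %*% beta)

  df_resid <- k - ncol(X)
  if (knapp_hartung) {
    s2 <- sum(w * r^2) / df_resid
    vcov_beta <- vcov_beta * max(s2, 1) # CMA-style truncation at 1
    crit <- stats::qt(1 - (1 - ci_level) / 2, df_resid)
    pfun <- function(stat) 2 * stats::pt(-abs(stat), df_resid)
  } else {
    crit <- qnorm(1 - (1 - ci_level) / 2)
    pfun <- function(stat) 2 * pnorm(-abs(stat))
  }
  se <- sqrt(diag(vcov_beta))
  stat <- beta / se
  q_model <- (beta["slope"] / se["slope"])^2

  structure(
    list(
      covariate = covariate,
      k = k,
      tau2_reml = tau2,
      coefficients = tibble::tibble(
        term = c("intercept", paste0("slope (", covariate, ")")),
        estimate = unname(beta),
        se = unname(se),
        ci_low = unname(beta - crit * se),
        ci_high = unname(beta + crit * se),
        statistic = unname(stat),
        p = pfun(unname(stat))
      ),
      Q_model = unname(q_model),
      df_model = 1L,
      p_model = pchisq(unname(q_model), 1, lower.tail = FALSE),
      knapp_hartung = knapp_hartung,
      data = tibble::tibble(es = y, v = v, x = x)
    ),
    class = "cc_metareg"
  )
}

#' @describeIn fit_meta_regression Coefficient table (intercept then slope).
#' @param x,object A `cc_metareg` object.
#' @param ... Unused.
#' @export
tidy.cc_metareg <- function(x, ...) x$coefficients

#' @describeIn fit_meta_regression Model-level one-row summary.
#' @export
glance.cc_metareg <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, k = x$k, tau2_reml = x$tau2_reml,
                 Q_model = x$Q_model, df_model = x$df_model,
                 p_model = x$p_model)
}

#' @describeIn fit_meta_regression Bubble plot: effects against the covariate,
#'   point area proportional to random-effects weight, fitted line overlaid.
#' @export
autoplot.cc_metareg <- function(object, ...) {
  b <- object$coefficients$estimate
  ggplot2::ggplot(
    dplyr::mutate(object$data, w = 1 / (.data$v + object$tau2_reml)),
    ggplot2::aes(x = .data$x, y = .data$es)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), alpha = 0.4,
                        show.legend = FALSE) +
    ggplot2::geom_abline(intercept = b[1], slope = b[2], colour = "steelblue") +
    ggplot2::labs(x = object$covariate, y = "ln(R)") +
    ggplot2::theme_minimal()
}

#' @export
print.cc_metareg <- function(x, ...) {
  cat("Random-effects meta-regression (REML), k =", x$k, "\n")
  cat("  covariate:", x$covariate,
      " tau2 =", signif(x$tau2_reml, 4), "\n")
  print(x$coefficients)
  cat("  Q_model =", signif(x$Q_model, 4), " df =", x$df_model,
      " p =", signif(x$p_model, 3), "\n")
  invisible(x)
}
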