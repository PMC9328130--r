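#' Configuration for the synthetic observation generator
#'
#' Describes a synthetic literature: how many articles, how many observations
#' each contributes, which moderator levels occur with which probabilities and
#' (optionally) which true mean log ratios, how heterogeneous the true effects
#' are, how replicate counts are distributed, and how the climate covariates
#' shift the true effect. The defaults mirror the marginal structure of a
#' global cover-crop nitrate-leaching synthesis: 41 articles of 20-34
#' observations each (about 1100 rows), five cover-crop families with
#' Poaceae dominant, twelve genera nested in those families, six soil orders,
#' eight textures, roughly 60% of rows carrying single-replicate means
#' (`n = 1/1`, hence variance 2), family mean response ratios of 0.25
#' (Brassicaceae) to 1.0 (Asteraceae), observation-level heterogeneity
#' `tau2 = 0.3`, and a rainfall slope of 0.001 per mm on the log-ratio scale.
#'
#' `subgroup_spec` is a named list (one entry per moderator) of tibbles with
#' columns `level`, `mu` (true mean log ratio contribution), and `prob`.
#' Contributions are additive across moderators; by default only `cc_family`
#' carries non-zero `mu`, the rest are pure labels. Covariate effects are
#' centred at the range midpoint, so subgroup means are unaffected by the
#' slopes.
#'
#' @param n_articles Number of synthetic articles.
#' @param obs_per_article Integer range `c(min, max)` of observations drawn
#'   per article.
#' @param response `"nitrate_leaching"` or `"water_drainage"`.
#' @param subgroup_spec Named list of per-moderator level tables (see above).
#' @param genus_map Named list mapping each `cc_family` level to its genera.
#' @param tau2 Between-observation variance of true effects.
#' @param article_sd Optional article-level random-effect SD (default 0:
#'   observations are independent).
#' @param replicate_dist Tibble `(n_cc, n_ncc, prob)` of replicate-count
#'   pairs.
#' @param baseline_ncc `c(meanlog, sdlog)` of the log-normal control means.
#' @param rainfall_range,temp_range Uniform ranges of the covariates.
#' @param slope_rainfall,slope_temp True covariate slopes (per mm, per degree
#'   C) on the log-ratio scale.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `cc_sim_config`.
#' @export
sim_config <- function(n_articles = 41,
                       obs_per_article = c(20, 34),
                       response = "nitrate_leaching",
                       subgroup_spec = default_subgroup_spec(),
                       genus_map = default_genus_map(),
                       tau2 = 0.3,
                       article_sd = 0,
                       replicate_dist = default_replicate_dist(),
                       baseline_ncc = c(meanlog = log(30), sdlog = 1),
                       rainfall_range = c(300, 1400),
                       temp_range = c(4, 18),
                       slope_rainfall = 0.001,
                       slope_temp = -0.009,
                       seed = NULL) {
  cfg <- list(
    n_articles = n_articles, obs_per_article = obs_per_article,
    response = response, subgroup_spec = subgroup_spec,
    genus_map = genus_map, tau2 = tau2, article_sd = article_sd,
    replicate_dist = replicate_dist, baseline_ncc = baseline_ncc,
    rainfall_range = rainfall_range, temp_range = temp_range,
    slope_rainfall = slope_rainfall, slope_temp = slope_temp, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cc_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$tau2 < 0 || cfg$article_sd < 0) {
    abort("tau2 and article_sd must be non-negative", class = "covermeta_config_error")
  }
  if (!cfg$response %in% response_levels) {
    abort("unknown response in sim config", class = "covermeta_config_error")
  }
  if (cfg$baseline_ncc[["sdlog"]] < 0) {
    abort("baseline sdlog must be non-negative", class = "covermeta_config_error")
  }
  for (m in names(cfg$subgroup_spec)) {
    spec <- cfg$subgroup_spec[[m]]
    if (!all(c("level", "mu", "prob") %in% names(spec))) {
      abort(paste0("subgroup_spec$", m, " needs columns level, mu, prob"),
            class = "covermeta_config_error")
    }
    if (any(spec$prob < 0) || abs(sum(spec$prob) - 1) > 1e-8) {
      abort(paste0("subgroup_spec$", m, " probabilities must be >= 0 and sum to 1"),
            class = "covermeta_config_error")
    }
  }
  if (abs(sum(cfg$replicate_dist$prob) - 1) > 1e-8 ||
      any(cfg$replicate_dist$n_cc < 1) || any(cfg$replicate_dist$n_ncc < 1)) {
    abort("replicate_dist probabilities must sum to 1 with counts >= 1",
          class = "covermeta_config_error")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_subgroup_spec <- function() {
  list(
    cc_family = tibble::tibble(
      level = c("Poaceae", "Brassicaceae", "Leguminosae", "Asteraceae", "Multigenera"),
      mu = log(c(0.48, 0.25, 0.60, 1.00, 0.48)),
      prob = c(348, 132, 46, 10, 55) / 591
    ),
    soil_order = tibble::tibble(
      level = c("Ultisols", "Mollisols", "Histosols", "Alfisols", "Inceptisols", "Entisols"),
      mu = 0,
      prob = c(9, 273, 44, 9, 95, 46) / 476
    ),
    soil_texture = tibble::tibble(
      level = c("Clay", "Silty clay loam", "Clay loam", "Silt loam",
                "Loam", "Sandy loam", "Loamy sand", "Sandy"),
      mu = 0,
      prob = c(6, 48, 146, 82, 102, 146, 46, 12) / 588
    ),
    main_crop = tibble::tibble(
      level = c("Tomato", "Potato", "Broccoli", "Sugar beet", "Sunflower",
                "Soybean", "Corn", "Wheat", "Barley", "Other beans", "Crop rotation"),
      mu = 0,
      prob = c(10, 7, 12, 7, 9, 80, 139, 23, 114, 6, 37) / 444
    ),
    tillage = tibble::tibble(
      level = c("CT", "NT", "RT"),
      mu = 0,
      prob = c(0.5, 0.3, 0.2)
    )
  )
}

#' @rdname sim_config
#' @export
default_genus_map <- function() {
  list(
    Poaceae = c("Secale", "Avena", "Hordeum", "Lolium", "Poa", "Triticum"),
    Brassicaceae = c("Brassica", "Raphanus", "Camelina", "Thlaspi"),
    Leguminosae = c("Trifolium", "Vicia"),
    Asteraceae = c("Helianthus"),
    Multigenera = c("Multigenera")
  )
}

#' @rdname sim_config
#' @export
default_replicate_dist <- function() {
  tibble::tibble(
    n_cc = c(1L, 2L, 3L, 4L, 3L),
    n_ncc = c(1L, 2L, 3L, 4L, 4L),
    prob = c(0.60, 0.10, 0.10, 0.15, 0.05)
  )
}

#' Generate a synthetic observation table
#'
#' Draws an observation table under the exact model the analysis assumes.
#' For each observation: moderator levels are drawn from `subgroup_spec`
#' (genus nested within family via `genus_map`), covariates uniformly from
#' their ranges, and the true effect is
#' `theta = sum(mu_level) + slope_rain (rain - mid) + slope_temp (temp - mid)
#' + N(0, tau2)` (plus an optional article effect). The control mean is
#' log-normal; the treatment mean is `mean_ncc * exp(theta) * exp(eps)` where
#' `eps ~ N(0, v)` and `v` is the nonparametric variance of the drawn
#' replicate counts — so each row's sampling noise matches the weight the
#' pipeline will assign it. All means are strictly positive by construction,
#' and the output is fully reproducible from the seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Overrides `config$seed` when given.
#' @return A validated `cc_observations` tibble with the standard columns and
#'   a `truth` attribute holding `config`.
#' @export
simulate_observations <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  sizes <- seq(config$obs_per_article[1], config$obs_per_article[2])
  n_per <- if (length(sizes) == 1) rep(sizes, config$n_articles) else
    sample(sizes, config$n_articles, replace = TRUE)
  n_obs <- sum(n_per)
  article_id <- rep(sprintf("art%03d", seq_len(config$n_articles)), n_per)

  draw_levels <- function(spec, n) {
    as.character(sample(spec$level, n, replace = TRUE, prob = spec$prob))
  }
  mods <- purrr::map(config$subgroup_spec, draw_levels, n = n_obs)

  # genus nested within family when both are in play
  genus <- if ("cc_family" %in% names(mods)) {
    purrr::map_chr(mods$cc_family, function(f) {
      g <- config$genus_map[[f]] %||% f
      sample(g, 1)
    })
  } else {
    rep(NA_character_, n_obs)
  }

  mu_total <- rep(0, n_obs)
  for (m in names(config$subgroup_spec)) {
    spec <- config$subgroup_spec[[m]]
    mu_total <- mu_total + spec$mu[match(mods[[m]], spec$level)]
  }

  rainfall <- runif(n_obs, config$rainfall_range[1], config$rainfall_range[2])
  temp <- runif(n_obs, config$temp_range[1], config$temp_range[2])
  theta <- mu_total +
    config$slope_rainfall * (rainfall - mean(config$rainfall_range)) +
    config$slope_temp * (temp - mean(config$temp_range)) +
    rnorm(n_obs, 0, sqrt(config$tau2))
  if (config$article_sd > 0) {
    art_eff <- rnorm(config$n_articles, 0, config$article_sd)
    theta <- theta + rep(art_eff, n_per)
  }

  rep_idx <- sample(nrow(config$replicate_dist), n_obs, replace = TRUE,
                    prob = config$replicate_dist$prob)
  n_cc <- config$replicate_dist$n_cc[rep_idx]
  n_ncc <- config$replicate_dist$n_ncc[rep_idx]
  v <- nonparametric_variance(n_cc, n_ncc)

  mean_ncc <- rlnorm(n_obs, config$baseline_ncc[["meanlog"]],
                     config$baseline_ncc[["sdlog"]])
  mean_cc <- mean_ncc * exp(theta) * exp(rnorm(n_obs, 0, sqrt(v)))

  raw <- tibble::tibble(
    article_id = article_id,
    obs_id = sprintf("obs%04d", seq_len(n_obs)),
    response = config$response,
    mean_cc = mean_cc,
    mean_ncc = mean_ncc,
    n_cc = as.numeric(n_cc),
    n_ncc = as.numeric(n_ncc),
    cc_family = mods$cc_family %||% NA_character_,
    cc_genus = genus,
    soil_order = mods$soil_order %||% NA_character_,
    soil_texture = mods$soil_texture %||% NA_character_,
    main_crop = mods$main_crop %||% NA_character_,
    tillage = mods$tillage %||% NA_character_,
    rainfall_mm = rainfall,
    temp_c = temp
  )
  out <- validate_observations(raw, response = config$response,
                               provenance = "simulate_observations()",
                               quiet = TRUE)
  attr(out, "truth") <- config
  out
}

#' Parameter-recovery report for a synthetic analysis
#'
#' Compares what the pipeline estimated on a synthetic table against the
#' generating truth: per-level percent change for every moderator the run
#' analysed (marginal truth — the level's own mean plus the average
#' contribution of the other, independently drawn moderators), the
#' within-level heterogeneity
#' `tau2` (df-weighted mean of the per-level DerSimonian-Laird estimates,
#' compared with the generator's `tau2`), and — when meta-regression fits are
#' supplied — the covariate slopes.
#'
#' @param truth The [sim_config()] used to generate the data.
#' @param run A `cc_analysis` from [run_analysis()] on the generated table.
#' @param metareg Optional named list of `cc_metareg` fits, names
#'   `rainfall_mm` / `temp_c`.
#' @return Tibble `(parameter, truth, estimate, abs_error, within_ci)`;
#'   `within_ci` is `NA` where no interval applies.
#' @export
recovery_report <- function(truth, run, metareg = NULL) {
  if (!inherits(run, "cc_analysis")) {
    abort("run must be a cc_analysis object", class = "covermeta_domain_error")
  }
  rows <- list()
  # marginal truth for a level of moderator m includes the mean contribution
  # of every other moderator (levels are drawn independently)
  mean_mu <- purrr::map_dbl(truth$subgroup_spec, ~ sum(.x$prob * .x$mu))
  for (m in intersect(names(truth$subgroup_spec), names(run$tables))) {
    offset <- sum(mean_mu) - mean_mu[[m]]
    spec <- truth$subgroup_spec[[m]]
    lev <- run$tables[[m]]$levels
    matched <- dplyr::inner_join(
      dplyr::select(lev, "level", "pct_change", "ci_low", "ci_high", "tau2", "df"),
      dplyr::select(spec, "level", "mu"),
      by = "level"
    )
    if (nrow(matched) == 0) {
      abort(paste0("no overlap between truth levels and estimated levels for '",
                   m, "'"),
            class = "covermeta_domain_error")
    }
    rows[[m]] <- tibble::tibble(
      parameter = paste0(m, ":", matched$level, ":pct_change"),
      truth = 100 * expm1(matched$mu + offset),
      estimate = matched$pct_change,
      within_ci = truth >= 100 * expm1(matched$ci_low) &
        truth <= 100 * expm1(matched$ci_high)
    )
  }
  # within-level tau2 across the first analysed moderator
  if (length(run$tables) > 0) {
    lev <- run$tables[[1]]$levels
    est <- sum(lev$tau2 * lev$df) / sum(lev$df)
    rows$tau2 <- tibble::tibble(
      parameter = "tau2", truth = truth$tau2, estimate = est, within_ci = NA
    )
  }
  if (!is.null(metareg)) {
    slope_truth <- c(rainfall_mm = truth$slope_rainfall,
                     temp_c = truth$slope_temp)
    for (cv in names(metareg)) {
      co <- metareg[[cv]]$coefficients
      srow <- co[grepl("^slope", co$term), ]
      rows[[paste0("slope_", cv)]] <- tibble::tibble(
        parameter = paste0("slope:", cv),
        truth = unname(slope_truth[cv]),
        estimate = srow$estimate,
        within_ci = truth >= srow$ci_low & truth <= srow$ci_high
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, abs_error = abs(.data$estimate - .data$truth),
                .before = "within_ci")
}
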