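test_that("generation is reproducible from the seed", {
  cfg <- sim_config(n_articles = 6, obs_per_article = c(5, 10))
  a <- simulate_observations(cfg, seed = 42)
  b <- simulate_observations(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_observations(cfg, seed = 43)
  expect_false(identical(a$mean_cc, c$mean_cc))
})

test_that("generated tables respect the schema and the variance structure", {
  obs <- simulate_observations(sim_config(seed = 42))
  expect_true(all(obs$mean_cc > 0 & obs$mean_ncc > 0))
  expect_false(anyDuplicated(obs$obs_id) > 0)
  expect_identical(unique(obs$response), "nitrate_leaching")
  expect_true(all(obs$tillage %in% c("CT", "RT", "NT")))
  # the generated replicate counts imply exactly the variances the pipeline uses
  eff <- compute_effects(obs)
  expect_equal(eff$v, (obs$n_cc + obs$n_ncc) / (obs$n_cc * obs$n_ncc))
  # about 41 articles x 20-34 observations
  expect_identical(length(unique(obs$article_id)), 41L)
  expect_gte(nrow(obs), 41 * 20)
  expect_lte(nrow(obs), 41 * 34)
})

test_that("the noise-free limit returns the configured effect exactly", {
  cfg <- sim_config(
    n_articles = 3, obs_per_article = c(10, 10),
    subgroup_spec = list(
      cc_family = tibble::tibble(level = c("OnlyA", "OnlyB"),
                                 mu = log(0.31), prob = c(0.5, 0.5))
    ),
    tau2 = 0,
    replicate_dist = tibble::tibble(n_cc = 1000000L, n_ncc = 1000000L, prob = 1),
    slope_rainfall = 0, slope_temp = 0
  )
  obs <- simulate_observations(cfg, seed = 42)
  eff <- compute_effects(obs)
  expect_equal(eff$es, rep(log(0.31), nrow(obs)), tolerance = 0.01)
})

test_that("within-level spread of es converges to tau2 + E[v]", {
  cfg <- sim_config(
    n_articles = 100, obs_per_article = c(1000, 1000),
    subgroup_spec = list(
      cc_family = tibble::tibble(level = "One", mu = log(0.5), prob = 1)
    ),
    tau2 = 0.3, slope_rainfall = 0, slope_temp = 0
  )
  obs <- simulate_observations(cfg, seed = 42)
  eff <- compute_effects(obs)
  expect_equal(var(eff$es), 0.3 + mean(eff$v), tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(tau2 = -1), class = "covermeta_config_error")
  expect_error(
    sim_config(subgroup_spec = list(
      cc_family = tibble::tibble(level = c("a", "b"), mu = 0, prob = c(0.5, 0.6))
    )),
    class = "covermeta_config_error"
  )
  expect_error(
    sim_config(replicate_dist = tibble::tibble(n_cc = 0L, n_ncc = 1L, prob = 1)),
    class = "covermeta_config_error"
  )
})

test_that("recovery report flags near-zero error in the degenerate limit", {
  cfg <- sim_config(
    n_articles = 10, obs_per_article = c(40, 40),
    subgroup_spec = list(
      cc_family = tibble::tibble(level = c("A", "B"),
                                 mu = log(c(0.4, 0.8)), prob = c(0.5, 0.5))
    ),
    tau2 = 0,
    replicate_dist = tibble::tibble(n_cc = 2000L, n_ncc = 2000L, prob = 1),
    slope_rainfall = 0, slope_temp = 0
  )
  obs <- simulate_observations(cfg, seed = 42)
  run <- run_analysis(obs, moderators = "cc_family")
  rep <- recovery_report(cfg, run)
  pct_rows <- rep[grepl("pct_change", rep$parameter), ]
  expect_true(all(pct_rows$abs_error < 2))
  expect_true(all(pct_rows$within_ci))
})

test_that("yaml round trip reproduces a configuration", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_articles: 5",
    "obs_per_article: [4, 6]",
    "tau2: 0.15",
    "slope_rainfall: 0.002",
    "subgroup_spec:",
    "  cc_family:",
    "    - {level: A, mu: -0.7, prob: 0.6}",
    "    - {level: B, mu: 0.0, prob: 0.4}",
    "replicate_dist:",
    "  - {n_cc: 1, n_ncc: 1, prob: 0.5}",
    "  - {n_cc: 3, n_ncc: 3, prob: 0.5}"
  ), path)
  cfg <- sim_config_from_yaml(path)
  expect_identical(cfg$n_articles, 5L)
  expect_equal(cfg$tau2, 0.15)
  expect_equal(cfg$subgroup_spec$cc_family$prob, c(0.6, 0.4))
  expect_equal(nrow(cfg$replicate_dist), 2L)
  obs <- simulate_observations(cfg, seed = 42)
  expect_true(all(obs$cc_family %in% c("A", "B")))
})
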