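test_that("a full run yields one table per analysable moderator", {
  obs <- simulate_observations(sim_config(seed = 42))
  run <- run_analysis(obs)
  expect_s3_class(run, "cc_analysis")
  expect_identical(nrow(run$tables$cc_family$levels), 5L)
  expect_setequal(
    c(names(run$tables), run$skipped$moderator),
    c("cc_family", "cc_genus", "soil_order", "soil_texture", "main_crop", "tillage")
  )
  # overall is the unfiltered effect set
  expect_identical(run$overall$k, nrow(obs))
  # deterministic given input
  run2 <- run_analysis(obs)
  expect_equal(tidy(run), tidy(run2))
})

test_that("moderators whose filters drop no rows share the overall Q and df", {
  obs <- simulate_observations(sim_config(seed = 42))
  run <- run_analysis(obs)
  full <- vapply(run$tables, function(t) t$overall$k == run$overall$k, logical(1))
  qs <- vapply(run$tables[full], function(t) t$overall$Q, numeric(1))
  dfs <- vapply(run$tables[full], function(t) t$overall$df, numeric(1))
  expect_gte(sum(full), 2)
  expect_true(all(abs(qs - qs[1]) < 1e-9))
  expect_true(all(dfs == dfs[1]))
  # and every table's level n column sums to its own overall n
  for (t in run$tables) expect_equal(sum(t$levels$n), t$overall$k)
})

test_that("an all-missing moderator is skipped with a reason, not fatally", {
  obs <- simulate_observations(sim_config(n_articles = 8,
                                          obs_per_article = c(8, 12),
                                          seed = 42))
  obs$soil_order <- NA_character_
  run <- run_analysis(obs, moderators = c("cc_family", "soil_order"))
  expect_true("cc_family" %in% names(run$tables))
  expect_true("soil_order" %in% run$skipped$moderator)
})

test_that("empty response selections are rejected", {
  obs <- simulate_observations(sim_config(n_articles = 4,
                                          obs_per_article = c(4, 6),
                                          seed = 42))
  expect_error(run_analysis(obs, response = "water_drainage"),
               class = "covermeta_domain_error")
})

test_that("tillage contrast recovers the configured tillage effects", {
  spec <- default_subgroup_spec()
  spec$cc_family$mu <- 0 # isolate the tillage signal
  spec$tillage <- tibble::tibble(
    level = c("CT", "NT", "RT"),
    mu = log(c(0.37, 0.50, 0.62)),
    prob = c(0.4, 0.35, 0.25)
  )
  cfg <- sim_config(n_articles = 60, obs_per_article = c(30, 36),
                    subgroup_spec = spec,
                    slope_rainfall = 0, slope_temp = 0)
  obs <- simulate_observations(cfg, seed = 42)
  tab <- tillage_contrast(obs)
  got <- setNames(tab$levels$pct_change, tab$levels$level)
  expect_equal(got[["CT"]], -63, tolerance = 0.12)
  expect_equal(got[["NT"]], -50, tolerance = 0.15)
  expect_equal(got[["RT"]], -38, tolerance = 0.25)
})

test_that("a single-level tillage table is a precondition error", {
  obs <- simulate_observations(sim_config(n_articles = 6,
                                          obs_per_article = c(5, 8),
                                          seed = 42))
  obs$tillage <- "CT"
  expect_error(tillage_contrast(obs), class = "covermeta_precondition_error")
})

test_that("analysis tables can be written and re-written identically", {
  obs <- simulate_observations(sim_config(n_articles = 10,
                                          obs_per_article = c(10, 14),
                                          seed = 42))
  run <- run_analysis(obs, moderators = c("cc_family", "tillage"))
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  write_analysis(run, d1)
  write_analysis(run, d2)
  expect_setequal(list.files(d1), c("cc_family.csv", "tillage.csv", "overall.csv"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
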