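test_that("reading filters by response, imputes blank replicate counts, rejects bad means", {
  rows <- toy_obs_rows()
  rows$mean_cc[5] <- 0 # log undefined -> must be rejected
  path <- write_obs_csv(rows)

  expect_warning(
    obs <- read_observations(path, "nitrate_leaching"),
    "imputed n = 1"
  )
  expect_s3_class(obs, "cc_observations")
  expect_identical(obs$obs_id, c("r1", "r2", "r3", "r4"))
  # row with blank counts got n = 1/1
  expect_identical(obs$n_cc[obs$obs_id == "r2"], 1L)
  expect_identical(obs$n_ncc[obs$obs_id == "r2"], 1L)

  rep <- validation_report(obs)
  expect_identical(rep$accepted + rep$rejected, nrow(rows))
  expect_identical(rep$n_imputed, 1L)
  expect_setequal(
    rep$reasons$reason[rep$reasons$obs_id == "r5"], "non-positive mean"
  )
  expect_true("response_mismatch" %in% rep$reasons$reason)
})

test_that("missing mandatory columns and missing files raise named errors", {
  rows <- dplyr::select(toy_obs_rows(), -mean_ncc)
  path <- write_obs_csv(rows)
  expect_error(suppressWarnings(read_observations(path, "nitrate_leaching")),
               "mean_ncc")
  expect_error(read_observations(tempfile(), "nitrate_leaching"),
               class = "covermeta_io_error")
})

test_that("round-trip write/read preserves all observation fields", {
  obs <- simulate_observations(sim_config(n_articles = 4,
                                          obs_per_article = c(5, 8),
                                          seed = 42))
  path <- tempfile(fileext = ".csv")
  write_results_table(obs, path)
  back <- read_observations(path, "nitrate_leaching", quiet = TRUE)
  expect_identical(back$obs_id, obs$obs_id)
  expect_identical(back$n_cc, obs$n_cc)
  # values pass through the 6-significant-digit CSV rendering
  expect_equal(back$mean_cc, obs$mean_cc, tolerance = 1e-5)
  expect_equal(back$rainfall_mm, obs$rainfall_mm, tolerance = 1e-5)
  expect_identical(back$cc_family, obs$cc_family)
})

test_that("result tables are written deterministically and reject empty input", {
  tbl <- tibble::tibble(level = c("a", "b"), Q = c(1.23456789, 2), df = c(1L, 2L))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_results_table(tbl, p1)
  write_results_table(tbl, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(write_results_table(tbl[0, ], tempfile()), "non-empty")
})

test_that("moderator level filter enforces the articles-per-level rule", {
  obs <- tibble::tibble(
    article_id = c("a1", "a2", "a3", "a4", "a4", "a4"),
    obs_id = paste0("r", 1:6),
    cc_family = c("Asteraceae", "Asteraceae", "Asteraceae",
                  "Poaceae", "Poaceae", "Poaceae")
  )
  # Asteraceae: 3 articles -> kept; Poaceae: 1 article -> dropped,
  # leaving one level -> precondition error
  expect_error(filter_moderator_levels(obs, "cc_family"),
               class = "covermeta_precondition_error")

  obs$article_id[5:6] <- c("a5", "a6") # now Poaceae spans 3 articles too
  kept <- filter_moderator_levels(obs, "cc_family")
  expect_identical(nrow(kept), 6L)

  # boundary below threshold: a level on 2 articles is dropped entirely
  obs2 <- dplyr::bind_rows(
    obs,
    tibble::tibble(article_id = c("a7", "a8"), obs_id = c("r7", "r8"),
                   cc_family = "Leguminosae")
  )
  kept2 <- filter_moderator_levels(obs2, "cc_family")
  expect_false("Leguminosae" %in% kept2$cc_family)

  # idempotence
  expect_identical(filter_moderator_levels(kept2, "cc_family"), kept2)

  # rows with missing moderator are excluded for that moderator only
  obs3 <- dplyr::bind_rows(
    obs, tibble::tibble(article_id = "a9", obs_id = "r9",
                        cc_family = NA_character_)
  )
  expect_false("r9" %in% filter_moderator_levels(obs3, "cc_family")$obs_id)

  expect_error(filter_moderator_levels(obs, "not_a_column"),
               class = "covermeta_schema_error")
})

test_that("level support degrades to observation counts without article ids", {
  obs <- tibble::tibble(
    article_id = NA_character_,
    obs_id = paste0("r", 1:8),
    tillage = rep(c("CT", "NT"), each = 4)
  )
  expect_warning(kept <- filter_moderator_levels(obs, "tillage"),
                 "article_id unavailable")
  expect_identical(nrow(kept), 8L)
})
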