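#' Observation-table schema
#'
#' The pipeline's unit of analysis is one paired comparison between a
#' cover-cropped (CC) plot and its no-cover-crop (NCC) fallow control:
#' treatment and control means of the response (nitrate leaching in
#' kg N ha\eqn{^{-1}} or water drainage in mm), replicate counts, categorical
#' moderators and numeric climate covariates. These constants name the columns
#' an observation CSV must carry.
#'
#' @name observation-schema
#' @keywords internal
NULL

obs_columns <- c(
  "article_id", "obs_id", "response", "mean_cc", "mean_ncc",
  "n_cc", "n_ncc", "cc_family", "cc_genus", "soil_order",
  "soil_texture", "main_crop", "tillage", "rainfall_mm", "temp_c"
)

moderator_columns <- c(
  "cc_family", "cc_genus", "soil_order", "soil_texture", "main_crop", "tillage"
)

covariate_columns <- c("rainfall_mm", "temp_c")

response_levels <- c("nitrate_leaching", "water_drainage")

tillage_levels <- c("CT", "RT", "NT")

obs_col_types <- readr::cols(
  article_id = readr::col_character(),
  obs_id = readr::col_character(),
  response = readr::col_character(),
  mean_cc = readr::col_double(),
  mean_ncc = readr::col_double(),
  n_cc = readr::col_double(),
  n_ncc = readr::col_double(),
  cc_family = readr::col_character(),
  cc_genus = readr::col_character(),
  soil_order = readr::col_character(),
  soil_texture = readr::col_character(),
  main_crop = readr::col_character(),
  tillage = readr::col_character(),
  rainfall_mm = readr::col_double(),
  temp_c = readr::col_double()
)
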