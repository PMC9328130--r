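# In-code fixtures shared across the suite.

# Minimal effect-record tibble from parallel vectors.
make_effects <- function(es, v, ...) {
  tibble::tibble(
    obs_id = sprintf("o%02d", seq_along(es)),
    es = es,
    v = v,
    w_fixed = 1 / v,
    ...
  )
}

# Random effect records with the nonparametric variance structure
# (replicate counts 1..4, so v has heavy ties at 2).
random_effects <- function(k, tau2 = 0, mu = 0) {
  n1 <- sample(1:4, k, replace = TRUE)
  n2 <- sample(1:4, k, replace = TRUE)
  v <- (n1 + n2) / (n1 * n2)
  make_effects(es = rnorm(k, mu, sqrt(tau2 + v)), v = v)
}

# Write a small observation CSV and return its path.
write_obs_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, na = "", progress = FALSE)
  path
}

# A hand-built observation table covering the schema.
toy_obs_rows <- function() {
  tibble::tibble(
    article_id = c("a1", "a1", "a2", "a3", "a4", "a4"),
    obs_id = paste0("r", 1:6),
    response = c(rep("nitrate_leaching", 5), "water_drainage"),
    mean_cc = c(10, 31, 5, 12, 8, 100),
    mean_ncc = c(10, 100, 10, 15, 16, 110),
    n_cc = c(4, NA, 3, 1, 2, 4),
    n_ncc = c(4, NA, 4, 1, 2, 4),
    cc_family = c("Poaceae", "Poaceae", "Brassicaceae", "Brassicaceae",
                  NA, "Poaceae"),
    cc_genus = c("Secale", "Avena", "Brassica", "Raphanus", NA, "Secale"),
    soil_order = "Mollisols",
    soil_texture = "Loam",
    main_crop = "Corn",
    tillage = c("CT", "CT", "NT", "NT", "RT", "CT"),
    rainfall_mm = c(600, 700, 800, NA, 900, 650),
    temp_c = c(8, 9, 10, 11, NA, 8)
  )
}

# Independent brute-force Kendall tau-b: explicit pair enumeration.
kendall_taub_oracle <- function(x, y) {
  k <- length(x)
  S <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  ties <- function(z) sum(sapply(table(z), function(t) t * (t - 1) / 2))
  n0 <- k * (k - 1) / 2
  S / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}
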