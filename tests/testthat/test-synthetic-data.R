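test_that("configuration defaults are valid and invalid settings are rejected", {
  cfg <- simulation_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$ga_mean_sd_ds, c(266.98, 17.65))
  expect_equal(cfg$ga_mean_sd_non_ds, c(274.47, 13.93))
  expect_error(simulation_config(n_ds = 0), "sample")
  expect_error(simulation_config(high_nrbc_fraction_ds = 1.2), "fraction")
  expect_error(simulation_config(mosaic_fraction_values = c(0.3, 1)),
               "strictly")
  expect_error(simulation_config(attenuation = 0), "attenuation")
  expect_error(simulation_config(ga_mean_sd_ds = c(267, -1)), "deviation")
})

test_that("cell reference generation is full rank, bounded and deterministic", {
  ref <- generate_cell_reference(50, seed = 1)
  expect_equal(dim(ref$mean_betas), c(7L, 50L))
  expect_equal(qr(ref$mean_betas)$rank, 7L)
  expect_true(all(ref$mean_betas >= 0 & ref$mean_betas <= 1))

  sq <- generate_cell_reference(7, seed = 1)
  expect_equal(qr(sq$mean_betas)$rank, 7L)

  expect_identical(generate_cell_reference(25, seed = 9)$mean_betas,
                   generate_cell_reference(25, seed = 9)$mean_betas)
  expect_error(generate_cell_reference(6), "identifiable")
})

test_that("synthetic clocks are exactly invertible via embed_age_signal", {
  # identity-transform clock: linear predictor equals output
  cl <- generate_synthetic_clock(10, "linear", seed = 2)
  b <- embed_age_signal(cl, c(a = -0.5, b = 0.3, c = 1.9))
  cv <- compute_clock(beta_matrix(b), cl)
  expect_equal(unname(cv$values), c(-0.5, 0.3, 1.9), tolerance = 1e-12)
  expect_equal(attr(b, "n_clipped"), 0L)

  # single-CpG clock: output = intercept + w * beta, closed form
  one <- clock_definition("one", intercept = 0.1, weights = c(cgX = 2),
                          transform = "linear")
  bm <- beta_matrix(matrix(0.25, 1, 1, dimnames = list("cgX", "s1")))
  expect_equal(unname(compute_clock(bm, one)$values), 0.1 + 2 * 0.25)

  # calibrated 391-CpG clock: round-trip a newborn-range target
  cal <- generate_synthetic_clock(391, "calibrated", seed = 3)
  b <- embed_age_signal(cal, c(s = 0.3))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(unname(compute_clock(beta_matrix(b), cal)$values), 0.3,
               tolerance = 1e-10)

  # gestational-scale clock covers the day range with in-bounds betas
  ga <- generate_synthetic_clock(25, "linear", seed = 4,
                                 output_units = "days")
  b <- embed_age_signal(ga, c(lo = 150, hi = 320))
  expect_equal(attr(b, "n_clipped"), 0L)
  expect_equal(unname(compute_clock(beta_matrix(b), ga)$values),
               c(150, 320), tolerance = 1e-9)
})

test_that("cohort generation is deterministic and structurally sound", {
  fx <- default_fixtures()
  cfg <- simulation_config(n_ds = 30, n_non_ds = 40, seed = 5,
                           mosaic_fraction_values = c(0.25, 0.4))
  a <- generate_cohort(cfg, list(fx$clock, fx$gaclock), fx$reference)
  b <- generate_cohort(cfg, list(fx$clock, fx$gaclock), fx$reference)
  expect_identical(a$betas$values, b$betas$values)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$bins, b$bins)
  expect_identical(a$truth, b$truth)

  expect_true(all(a$betas$values >= 0 & a$betas$values <= 1))
  expect_true(is.integer(a$truth$n_beta_clipped))
  expect_equal(unname(rowSums(a$truth$cell_props)), rep(1, 70),
               tolerance = 1e-12)
  expect_equal(sum(a$truth$t21_class == "mosaic"), 2L)
  expect_equal(sort(a$truth$mosaic_fraction[a$truth$mosaic_fraction > 0]),
               c(0.25, 0.4))
  # high-nRBC subset only among DS, at the configured rate
  expect_equal(sum(a$truth$high_nrbc), round(0.17 * 30))
  expect_true(all(a$sheet$ds[a$truth$high_nrbc]))
  expect_true(all(a$truth$cell_props[a$truth$high_nrbc, "nRBC"] > 0.25))
})

test_that("clock CpG collisions with the reference are a configuration error", {
  ref <- generate_cell_reference(10, seed = 1)
  w <- rep(0.5, 3)
  names(w) <- colnames(ref$mean_betas)[1:3]
  bad <- clock_definition("bad", 0, w, transform = "linear")
  cfg <- simulation_config(n_ds = 2, n_non_ds = 2, seed = 1)
  expect_error(generate_cohort(cfg, list(bad), ref), "collide")
  cfg2 <- simulation_config(n_ds = 2, n_non_ds = 2, seed = 1,
                            allow_cpg_overlap = TRUE)
  expect_s3_class(generate_cohort(cfg2, list(bad), ref), "synthetic_cohort")
})

test_that("zero-noise cohorts recover injected group structure exactly", {
  fx <- default_fixtures()
  cfg <- simulation_config(n_ds = 100, n_non_ds = 100, noise_sd_beta = 0,
                           gata1_fraction_ds = 0, seed = 6)
  coh <- generate_cohort(cfg, list(fx$clock), fx$reference)
  cv <- compute_clock(coh$betas, fx$clock)
  # closed loop: clock output equals truth
  expect_lt(max(abs(cv$values - coh$truth$epi_age[, "ageclock"])), 1e-8)
  # DS offset of 0.24 appears exactly as the deviation from the non-DS line
  line <- fit_reference_line(cv, coh$sheet$chron_age_days, !coh$sheet$ds)
  aa <- compute_dnamaa(cv, coh$sheet$chron_age_days, line)
  expect_equal(mean(aa$values[coh$sheet$ds]) - mean(aa$values[!coh$sheet$ds]),
               0.24, tolerance = 1e-10)
  expect_equal(line$slope, cfg$slope_years_per_day, tolerance = 1e-10)
})

test_that("chr21 dosage shift follows the attenuated copy-ratio form", {
  fx <- default_fixtures()
  cfg <- simulation_config(n_ds = 3, n_non_ds = 3, bin_log2_noise_sd = 0,
                           attenuation = 0.5,
                           mosaic_fraction_values = 0.3, seed = 8)
  coh <- generate_cohort(cfg, list(fx$clock), NULL)
  med <- chr21_median_log2(coh$bins)
  full <- coh$sheet$sample_id[coh$truth$t21_class == "full_T21"]
  mosa <- coh$sheet$sample_id[coh$truth$t21_class == "mosaic"]
  dis <- coh$sheet$sample_id[coh$truth$t21_class == "disomic"]
  expect_equal(unname(med[full]), rep(0.5 * log2(1.5), length(full)))
  expect_equal(unname(med[mosa]), 0.5 * log2(2.3 / 2))
  expect_equal(unname(med[dis]), rep(0, length(dis)))
})

test_that("large cohorts reproduce the configured covariate moments", {
  fx <- default_fixtures(n_clock = 10)
  cfg <- simulation_config(n_ds = 1000, n_non_ds = 1000, seed = 9)
  coh <- generate_cohort(cfg, list(fx$clock), NULL)
  s <- coh$sheet
  within3se <- function(x, mean_sd) {
    abs(mean(x) - mean_sd[1]) < 3 * mean_sd[2] / sqrt(length(x))
  }
  expect_true(within3se(s$ga_days[s$ds], cfg$ga_mean_sd_ds))
  expect_true(within3se(s$ga_days[!s$ds], cfg$ga_mean_sd_non_ds))
  expect_true(within3se(s$collection_age_days[s$ds],
                        cfg$collection_age_mean_sd_ds))
  expect_true(within3se(s$collection_age_days[!s$ds],
                        cfg$collection_age_mean_sd_non_ds))
  expect_true(within3se(s$birthweight_g[s$ds], cfg$birthweight_mean_sd_ds))
  expect_true(within3se(s$birthweight_g[!s$ds],
                        cfg$birthweight_mean_sd_non_ds))
  expect_true(all(s$collection_age_days >= 0))
  expect_true(all(s$ga_days >= 150 & s$ga_days <= 320))
})
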