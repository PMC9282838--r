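test_that("covariate screening keeps signal and drops most null covariates", {
  set.seed(81)
  n <- 500
  d <- data.frame(y = rnorm(n))
  d$self <- d$y                      # trivially associated
  d$noise <- rnorm(n)                # null covariate
  kept <- select_covariates(d, "y", c("self", "noise"))
  expect_true("self" %in% kept)

  # a null covariate survives the p < 0.2 screen at rate ~0.2
  retained <- vapply(1:40, function(r) {
    set.seed(810 + r)
    d <- data.frame(y = rnorm(n), x = rnorm(n))
    "x" %in% select_covariates(d, "y", "x")
  }, logical(1))
  expect_gte(mean(!retained), 0.65)

  # constant candidate is skipped with a warning; empty set is legal
  d$const <- 1
  expect_warning(out <- select_covariates(d, "y", "const"), "constant")
  expect_length(out, 0)

  # multi-level factors are screened via the overall F test
  d$grp <- sample(letters[1:3], n, replace = TRUE)
  expect_type(select_covariates(d, "y", "grp"), "character")
})

test_that("AIC-based PC selection picks signal PCs and respects the cap", {
  set.seed(82)
  n <- 300
  pcs <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("pc", 1:5)))
  d <- data.frame(pcs)
  d$y_null <- rnorm(n)
  d$y_pc1 <- d$pc1
  sel_signal <- select_num_pcs(d, "y_pc1", paste0("pc", 1:5), max_pcs = 5)
  expect_gte(sel_signal$k, 1L)
  expect_length(sel_signal$lrt_p, 5L)
  expect_lt(sel_signal$lrt_p[["k1"]], 1e-10)

  # null outcome: the AIC penalty keeps k small most of the time
  ks <- vapply(1:20, function(r) {
    set.seed(820 + r)
    d$y <- rnorm(n)
    select_num_pcs(d, "y", paste0("pc", 1:5), max_pcs = 5)$k
  }, integer(1))
  expect_gte(mean(ks == 0), 0.5)

  expect_warning(capped <- select_num_pcs(d, "y_null", paste0("pc", 1:5),
                                          max_pcs = 10), "capped")
  expect_length(capped$aic, 6L)
})

test_that("fit_model applies subsets, reports t-based CIs and day conversions", {
  set.seed(83)
  n <- 400
  d <- data.frame(ds = rep(c(TRUE, FALSE), each = n / 2),
                  sex = sample(c("F", "M"), n, TRUE),
                  high_nrbc = FALSE, gata1_status = NA_character_)
  d$high_nrbc[1:40] <- TRUE
  d$gata1_status[d$ds] <- sample(c("wildtype", "mutant"), n / 2, TRUE,
                                 prob = c(0.8, 0.2))
  d$y <- 0.24 * d$ds + rnorm(n, 0, 0.1)
  m <- fit_model(d, "y", "ds", covariates = "sex",
                 line = list(slope = 0.001))
  expect_true(m$ci_low <= m$estimate && m$estimate <= m$ci_high)
  expect_equal(m$aa_days, m$estimate / 0.001)
  expect_equal(m$aa_days_ci, c(m$ci_low, m$ci_high) / 0.001)
  expect_equal(m$n_used, n)
  expect_equal(m$estimate, 0.24, tolerance = 0.1)

  m2 <- fit_model(d, "y", "ds", subset_rule = "exclude_high_nrbc")
  expect_equal(m2$n_used, n - 40)
  m3 <- fit_model(d, "y", "ds", subset_rule = "gata1_wildtype_plus_nonds")
  expect_equal(m3$n_used,
               sum(!d$ds) + sum(d$gata1_status == "wildtype", na.rm = TRUE))

  # degenerate subsets and designs are informative errors
  d_allwt <- d; d_allwt$gata1_status[d_allwt$ds] <- NA
  expect_error(fit_model(d_allwt, "y", "ds",
                         subset_rule = "gata1_wildtype_plus_nonds"),
               "single level")
  d$dup <- as.numeric(d$ds)
  expect_error(fit_model(d, "y", "ds", covariates = "dup"), "collinear")
  expect_error(fit_model(d, "y", "ds", covariates = "Gran"), "granulocyte")
})

test_that("clock and acceleration outcomes give matching DS estimates at zero noise", {
  fx <- default_fixtures()
  cfg <- simulation_config(n_ds = 80, n_non_ds = 80, noise_sd_beta = 0,
                           gata1_fraction_ds = 0, seed = 84)
  coh <- generate_cohort(cfg, list(fx$clock), fx$reference)
  cv <- compute_clock(coh$betas, fx$clock)
  line <- fit_reference_line(cv, coh$sheet$chron_age_days, !coh$sheet$ds)
  aa <- compute_dnamaa(cv, coh$sheet$chron_age_days, line)
  d <- coh$sheet
  d$clock <- cv$values[d$sample_id]
  d$aa <- aa$values[d$sample_id]
  d$high_nrbc <- coh$truth$high_nrbc
  m_clock <- fit_model(d, "clock", "ds", covariates = "chron_age_days")
  m_aa <- fit_model(d, "aa", "ds")
  expect_lt(abs(m_clock$estimate - m_aa$estimate), 1e-6)
  expect_equal(m_aa$estimate, 0.24, tolerance = 1e-8)

  # excluding high-nRBC samples cannot flip a clock-borne DS effect
  m_ex <- fit_model(d, "aa", "ds", subset_rule = "exclude_high_nrbc")
  expect_gt(m_ex$estimate, 0)
  expect_equal(m_ex$estimate, 0.24, tolerance = 1e-8)
})

test_that("GATA1 status and VAF models recover the injected effects", {
  fx <- default_fixtures()
  cfg <- simulation_config(n_ds = 250, n_non_ds = 100, noise_sd_beta = 0.01,
                           gata1_fraction_ds = 0.3,
                           gata1_sequenced_fraction_ds = 1, seed = 85)
  coh <- generate_cohort(cfg, list(fx$linclock), NULL)
  cv <- compute_clock(coh$betas, fx$linclock)
  d <- coh$sheet
  d$clock <- cv$values[d$sample_id]
  res <- fit_gata1_models(d, "clock", line = list(slope = 0.001))
  expect_s3_class(res$status, "model_result")
  expect_gt(res$status$estimate, 0)
  expect_lt(res$status$p_value, 0.05)
  # true VAF slope 1.78 lies in the VAF-model confidence interval
  expect_true(res$vaf$ci_low <= 1.78 && 1.78 <= res$vaf$ci_high)
  expect_equal(res$vaf$days_per_10pct_vaf, res$vaf$estimate * 0.1 / 0.001)

  d_wt <- d
  d_wt$gata1_status[d_wt$gata1_status == "mutant"] <- "wildtype"
  expect_error(fit_gata1_models(d_wt, "clock"), "wildtype")

  # few mutants: VAF model skipped with a warning
  d_few <- d
  mut_ids <- which(d_few$gata1_status == "mutant")
  d_few$gata1_status[mut_ids[-(1:2)]] <- "wildtype"
  d_few$gata1_vaf[mut_ids[-(1:2)]] <- 0
  expect_warning(res_few <- fit_gata1_models(d_few, "clock"), "skipped")
  expect_null(res_few$vaf)
})

test_that("bivariate tests select the right procedure per variable type", {
  set.seed(86)
  n <- 200
  d <- data.frame(g = rep(c(TRUE, FALSE), each = n / 2),
                  x = rnorm(n), cat = sample(c("a", "b"), n, TRUE))
  d$x_shift <- d$x + 2 * d$g
  d$age <- runif(n, 200, 350)
  d$clock <- 0.002 * d$age + rnorm(n, 0, 0.1)
  out <- bivariate_tests(d, "g", continuous = c("x", "x_shift"),
                         categorical = "cat",
                         spearman = list(clock_age = c("clock", "age")))
  expect_equal(out$test, c("t", "t", "chisq", "spearman"))
  expect_gt(out$p_value[out$variable == "x"], 0.05)
  expect_lt(out$p_value[out$variable == "x_shift"], 1e-10)
  expect_gt(out$statistic[out$variable == "clock_age"], 0)

  # near-identical groups: statistic near zero, p near one
  d2 <- data.frame(g = rep(c(TRUE, FALSE), each = 3), v = rep(c(1, 2, 3), 2))
  out2 <- bivariate_tests(d2, "g", continuous = "v")
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)

  # a group with n < 2 is skipped and flagged
  d3 <- data.frame(g = c(TRUE, FALSE, FALSE, FALSE),
                   v = c(1, 2, 3, 4))
  out3 <- bivariate_tests(d3, "g", continuous = "v")
  expect_true(out3$skipped)
})

test_that("three-group comparisons use Kruskal-Wallis with BH-adjusted pairwise Wilcoxon", {
  set.seed(87)
  vals <- c(rnorm(50, 0), rnorm(8, 0.8), rnorm(50, 1.5))
  grp <- rep(c("non_DS", "mosaic", "full"), c(50, 8, 50))
  out <- group_comparison_tests(vals, grp)
  expect_lt(out$global_p, 1e-6)
  expect_equal(sort(unname(out$n_per_group)), c(8L, 50L, 50L))
  pw <- out$pairwise
  expect_true(all(pw[!is.na(pw)] >= 0 & pw[!is.na(pw)] <= 1))
  expect_error(group_comparison_tests(vals, rep("x", 108)), ">= 2 groups")

  # BH step-up on the pairwise procedure's p-values: hand-derived values
  # and monotonicity in the input order statistics
  p <- c(0.01, 0.02, 0.04)
  adj <- p.adjust(p, "BH")
  expect_equal(adj, c(0.03, 0.03, 0.04))
  expect_true(all(diff(adj[order(p)]) >= 0))
})
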