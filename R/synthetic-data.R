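#' Configuration of a synthetic newborn cohort
#'
#' Defines the statistical structure of a simulated two-group (Down
#' syndrome / non-DS) newborn bloodspot cohort: covariate distributions
#' matching the study population's printed moments, an epigenetic-age
#' signal carried by clock CpGs, reference-mixture betas at deconvolution
#' CpGs, chromosome 21 dosage signal in binned log2 copy ratios, and DS
#' subsets with high nucleated-red-blood-cell (nRBC) proportions or somatic
#' GATA1 mutations.
#'
#' The true (noise-free) value of an age clock for sample *i* is
#' `baseline_intercept_years + slope_years_per_day * chron_age_days_i +
#' ds_clock_offset_years * 1[DS_i] + gata1_vaf_clock_slope * VAF_i`.
#' Gestational clocks carry the gestational-age signal only (true value =
#' observed gestational age in days, no DS offset).
#'
#' @param n_ds,n_non_ds Group sizes (>= 1).
#' @param ds_clock_offset_years Injected DS effect on age clocks, clock
#'   units (years). Default 0.24.
#' @param slope_years_per_day Chronological-age signal on age clocks.
#'   Default 0.001.
#' @param baseline_intercept_years Population intercept of the age-clock
#'   truth line. Default -0.676, placing non-DS clock values near -0.40 at
#'   the mean non-DS chronological age.
#' @param ga_mean_sd_ds,ga_mean_sd_non_ds Gestational age mean/SD, days.
#' @param collection_age_mean_sd_ds,collection_age_mean_sd_non_ds Age at
#'   blood collection mean/SD, days.
#' @param birthweight_mean_sd_ds,birthweight_mean_sd_non_ds Birthweight
#'   mean/SD, grams.
#' @param high_nrbc_fraction_ds Fraction of DS newborns with markedly high
#'   true nRBC proportions (> 25%). Default 0.17.
#' @param gata1_fraction_ds Fraction of sequenced DS newborns carrying a
#'   somatic GATA1 mutation. Default 0.16.
#' @param gata1_sequenced_fraction_ds Fraction of DS newborns with GATA1
#'   sequencing available. Default 0.53.
#' @param gata1_vaf_clock_slope Clock units per unit variant allele
#'   fraction. Default 1.78.
#' @param mosaic_fraction_values Mosaic cell fractions in (0,1) assigned to
#'   the first DS samples; remaining DS samples are full trisomy 21.
#' @param noise_sd_beta SD of Gaussian beta-value noise (clipped to
#'   \[0,1\]). Default 0.01.
#' @param attenuation Multiplier in (0,1\] modelling array compression of
#'   the theoretical chromosome 21 dosage shift `log2((2+f)/2)`. Default 0.5.
#' @param bin_log2_noise_sd SD of bin-level log2-ratio noise. Default 0.05.
#' @param n_chr21_bins Number of chromosome 21 bins. Default 317.
#' @param n_other_bins Bins simulated on a disomic reference chromosome.
#' @param n_pcs Number of ancestry principal-component columns.
#' @param n_batches Number of array batches.
#' @param all_case_fraction_ds,all_case_fraction_non_ds Fraction of later
#'   acute lymphoblastic leukemia cases per group.
#' @param allow_cpg_overlap Permit clock CpGs to coincide with reference
#'   CpGs (otherwise an overlap is a configuration error).
#' @param seed Integer seed; every random draw in [generate_cohort()]
#'   derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_ds = 346, n_non_ds = 567,
                              ds_clock_offset_years = 0.24,
                              slope_years_per_day = 0.001,
                              baseline_intercept_years = -0.676,
                              ga_mean_sd_ds = c(266.98, 17.65),
                              ga_mean_sd_non_ds = c(274.47, 13.93),
                              collection_age_mean_sd_ds = c(55.25, 49.74),
                              collection_age_mean_sd_non_ds = c(32.72, 17.46),
                              birthweight_mean_sd_ds = c(3029.90, 686.27),
                              birthweight_mean_sd_non_ds = c(3386.10, 541.77),
                              high_nrbc_fraction_ds = 0.17,
                              gata1_fraction_ds = 0.16,
                              gata1_sequenced_fraction_ds = 0.53,
                              gata1_vaf_clock_slope = 1.78,
                              mosaic_fraction_values = numeric(),
                              noise_sd_beta = 0.01,
                              attenuation = 0.5,
                              bin_log2_noise_sd = 0.05,
                              n_chr21_bins = 317,
                              n_other_bins = 100,
                              n_pcs = 10,
                              n_batches = 4,
                              all_case_fraction_ds = 0.425,
                              all_case_fraction_non_ds = 0.229,
                              allow_cpg_overlap = FALSE,
                              seed = 1L) {
  cfg <- as.list(environment())
  frac <- c(high_nrbc_fraction_ds, gata1_fraction_ds,
            gata1_sequenced_fraction_ds, all_case_fraction_ds,
            all_case_fraction_non_ds)
  if (any(frac < 0 | frac > 1)) stop_neoclocks("fractions must lie in [0, 1]")
  sds <- c(ga_mean_sd_ds[2], ga_mean_sd_non_ds[2], collection_age_mean_sd_ds[2],
           collection_age_mean_sd_non_ds[2], birthweight_mean_sd_ds[2],
           birthweight_mean_sd_non_ds[2], noise_sd_beta, bin_log2_noise_sd)
  if (any(sds < 0)) stop_neoclocks("standard deviations must be >= 0")
  if (n_ds < 1 || n_non_ds < 1) stop_neoclocks("each group needs >= 1 sample")
  if (length(mosaic_fraction_values) > 0 &&
      (any(mosaic_fraction_values <= 0) || any(mosaic_fraction_values >= 1)))
    stop_neoclocks("mosaic fractions must lie strictly in (0, 1)")
  if (length(mosaic_fraction_values) > n_ds)
    stop_neoclocks("more mosaic fractions than DS samples")
  if (attenuation <= 0 || attenuation > 1)
    stop_neoclocks("attenuation must lie in (0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic cell-type methylation reference
#'
#' Draws mean beta profiles for the seven cord-blood cell types over
#' `n_deconv_cpgs` CpGs, redrawing in the (vanishingly unlikely) event of a
#' rank-deficient draw so that mixture proportions are identifiable.
#'
#' @param n_deconv_cpgs Number of deconvolution CpGs (>= 7).
#' @param seed Integer seed.
#' @param cpg_prefix Prefix for generated CpG ids.
#' @return A [cell_reference()].
#' @export
generate_cell_reference <- function(n_deconv_cpgs, seed = 1L,
                                    cpg_prefix = "cgREF") {
  if (n_deconv_cpgs < length(CELL_TYPES))
    stop_neoclocks("need at least ", length(CELL_TYPES),
                   " CpGs for identifiable 7-type deconvolution")
  set.seed(seed)
  repeat {
    m <- matrix(runif(length(CELL_TYPES) * n_deconv_cpgs, 0.05, 0.95),
                nrow = length(CELL_TYPES),
                dimnames = list(CELL_TYPES,
                                sprintf("%s%05d", cpg_prefix,
                                        seq_len(n_deconv_cpgs))))
    if (qr(m)$rank == length(CELL_TYPES)) return(cell_reference(m))
  }
}

#' Generate a synthetic clock with known coefficients
#'
#' Produces a clock whose weights and intercept are sized so that every
#' target age in the newborn range is attainable by some beta vector in
#' \[0,1\]^n via [embed_age_signal()]: weights alternate in sign with
#' magnitudes near a unit scale, the intercept centres the linear-predictor
#' range at baseline betas of 0.5, and weights are rescaled upward whenever
#' the required per-CpG excursion from 0.5 would otherwise exceed 0.5.
#'
#' @param n_cpgs Number of clock CpGs (>= 1).
#' @param transform `"linear"` or `"calibrated"` output transform.
#' @param seed Integer seed.
#' @param output_units `"years"` (targets in \[-1, 2\]) or `"days"`
#'   (gestational clock; targets in \[150, 320\]).
#' @param cpg_prefix Prefix for generated CpG ids.
#' @param name Clock label.
#' @return A [clock_definition()].
#' @export
generate_synthetic_clock <- function(n_cpgs,
                                     transform = c("linear", "calibrated"),
                                     seed = 1L,
                                     output_units = c("years", "days"),
                                     cpg_prefix = "cgCLK",
                                     name = "synthetic") {
  transform <- match.arg(transform)
  output_units <- match.arg(output_units)
  if (n_cpgs < 1L) stop_neoclocks("n_cpgs must be >= 1")
  set.seed(seed)
  w <- runif(n_cpgs, 0.5, 1.5) * rep_len(c(1, -1), n_cpgs) *
    if (output_units == "days") 100 else 1
  names(w) <- sprintf("%s%05d", cpg_prefix, seq_len(n_cpgs))

  target_range <- if (output_units == "days") c(150, 320) else c(-0.99, 2)
  lp_range <- if (transform == "calibrated")
    forward_age_transform(target_range) else target_range
  centre <- mean(lp_range)
  half <- diff(lp_range) / 2
  # ensure |delta| * max|w| / sum(w^2) <= 0.45 so embedded betas stay in [0,1]
  ratio <- half * max(abs(w)) / sum(w^2)
  if (ratio > 0.45) w <- w * (ratio / 0.45)
  intercept <- centre - 0.5 * sum(w)
  clock_definition(name, intercept, w, transform = transform,
                   output_units = output_units)
}

#' Embed a target age signal into clock-CpG betas
#'
#' Given target clock outputs, computes the required linear predictor
#' (inverting the calibrated transform where applicable) and distributes the
#' deviation from the 0.5-baseline predictor across the clock CpGs
#' proportionally to `w_j / sum(w^2)`, so that applying the clock to the
#' returned betas reproduces the targets exactly. Betas are clipped to
#' \[0,1\]; the clip count is attached as attribute `n_clipped` (clocks from
#' [generate_synthetic_clock()] never clip over their design range).
#'
#' @param clock A [clock_definition()].
#' @param target Numeric vector of target clock outputs, in the clock's
#'   output units.
#' @param base_beta Baseline beta level, default 0.5.
#' @return Matrix of betas, clock CpGs x targets.
#' @export
embed_age_signal <- function(clock, target, base_beta = 0.5) {
  lp_target <- switch(clock$transform,
                      calibrated = forward_age_transform(target,
                                                         clock$adult_age),
                      linear = target)
  w <- clock$weights
  delta <- lp_target - clock$intercept - base_beta * sum(w)
  betas <- base_beta + outer(w / sum(w^2), delta)
  betas <- clip01(betas)
  dimnames(betas) <- list(names(w), names(target))
  betas
}

# truncated-normal draw by redrawing out-of-bounds values
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Dirichlet draw via gamma variates
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Baseline mean cell proportions for cord blood, and the DS shift pattern:
# lower B/CD4T/Gran/Mono, higher CD8T/NK/nRBC.
.base_cell_means <- c(B = 0.08, CD4T = 0.13, CD8T = 0.06, NK = 0.03,
                      Mono = 0.08, Gran = 0.55, nRBC = 0.07)
.ds_cell_shift <- c(B = -0.02, CD4T = -0.03, CD8T = 0.02, NK = 0.015,
                    Mono = -0.02, Gran = -0.05, nRBC = 0.055)

#' Generate a synthetic newborn cohort with known ground truth
#'
#' Draws a two-group cohort according to a [simulation_config()]: sample
#' sheet covariates from the configured distributions; true seven-type cell
#' proportions (Dirichlet around cord-blood means, shifted in DS, with a
#' high-nRBC DS subset and elevated nRBC in GATA1-mutant samples);
#' deconvolution-CpG betas as reference mixtures; clock-CpG betas embedding
#' each clock's true value via [embed_age_signal()]; and binned log2 copy
#' ratios with the attenuated chromosome 21 dosage shift
#' `attenuation * log2((2 + f) / 2)` (f = 1 for full trisomy 21, the mosaic
#' cell fraction for mosaics, 0 otherwise). Gaussian noise of SD
#' `noise_sd_beta` is added to all betas and clipped to \[0,1\].
#'
#' @param config A [simulation_config()].
#' @param clocks List of [clock_definition()] objects (synthetic or
#'   published-style). Clocks with `output_units = "years"` carry the
#'   chronological-age + DS + GATA1-VAF signal; clocks with `"days"` carry
#'   the gestational-age signal only.
#' @param reference Optional [cell_reference()]; when `NULL` no
#'   deconvolution CpGs are generated.
#' @return A list of class `synthetic_cohort` with elements `betas`
#'   ([beta_matrix()]), `sheet` (sample-sheet `data.frame`), `bins`
#'   (bin-level log2 `data.frame`) and `truth` (list: `epi_age` matrix of
#'   true clock values, `cell_props`, `t21_class`, `mosaic_fraction`,
#'   `gata1_vaf`, `ds_offset_applied`, `n_beta_clipped`).
#' @export
generate_cohort <- function(config, clocks, reference = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(clocks, "clock_definition")) clocks <- list(clocks)
  clock_cpgs <- unlist(lapply(clocks, function(cl) names(cl$weights)))
  if (anyDuplicated(unlist(lapply(clocks, `[[`, "name"))))
    stop_neoclocks("clock names must be unique")
  if (!is.null(reference)) {
    overlap <- intersect(clock_cpgs, colnames(reference$mean_betas))
    if (length(overlap) > 0L && !config$allow_cpg_overlap)
      stop_neoclocks("clock CpGs collide with reference CpGs (",
                     length(overlap), "); set allow_cpg_overlap = TRUE ",
                     "if intentional")
  }
  set.seed(config$seed)
  n_ds <- config$n_ds; n_non <- config$n_non_ds
  n <- n_ds + n_non
  ds <- rep(c(TRUE, FALSE), c(n_ds, n_non))
  sid <- sprintf("S%04d", seq_len(n))

  draw2 <- function(ms_ds, ms_non, lo = -Inf, hi = Inf) {
    c(rnorm_trunc(n_ds, ms_ds[1], ms_ds[2], lo, hi),
      rnorm_trunc(n_non, ms_non[1], ms_non[2], lo, hi))
  }
  ga <- draw2(config$ga_mean_sd_ds, config$ga_mean_sd_non_ds, 150, 320)
  # collection age is nonnegative and right-skewed; a gamma matched to the
  # configured mean/SD keeps both moments exact (a zero-truncated normal
  # would inflate the mean)
  rgamma_ms <- function(n, ms) rgamma(n, shape = (ms[1] / ms[2])^2,
                                      scale = ms[2]^2 / ms[1])
  coll <- c(rgamma_ms(n_ds, config$collection_age_mean_sd_ds),
            rgamma_ms(n_non, config$collection_age_mean_sd_non_ds))
  bw <- draw2(config$birthweight_mean_sd_ds, config$birthweight_mean_sd_non_ds,
              300, 6500)
  age <- ga + coll

  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- sample(paste0("B", seq_len(config$n_batches)), n, replace = TRUE)
  pcs <- matrix(rnorm(n * config$n_pcs), nrow = n,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))
  all_status <- ifelse(
    runif(n) < ifelse(ds, config$all_case_fraction_ds,
                      config$all_case_fraction_non_ds), "case", "control")

  # GATA1 sequencing and mutation status (DS only)
  sequenced <- ds & runif(n) < config$gata1_sequenced_fraction_ds
  mutant <- sequenced & runif(n) < config$gata1_fraction_ds
  vaf <- rep(0, n)
  vaf[mutant] <- runif(sum(mutant), 0.05, 0.45)
  gata1_status <- rep(NA_character_, n)
  gata1_status[sequenced] <- ifelse(mutant[sequenced], "mutant", "wildtype")

  # mosaic assignment: first k DS samples get the configured fractions
  mosaic_fraction <- rep(0, n)
  k <- length(config$mosaic_fraction_values)
  if (k > 0L) mosaic_fraction[which(ds)[seq_len(k)]] <- config$mosaic_fraction_values
  t21_class <- ifelse(!ds, "disomic",
                      ifelse(mosaic_fraction > 0, "mosaic", "full_T21"))

  # true cell proportions
  alpha <- 60
  props <- matrix(NA_real_, n, length(CELL_TYPES),
                  dimnames = list(sid, CELL_TYPES))
  mu_non <- .base_cell_means
  mu_ds <- .base_cell_means + .ds_cell_shift
  props[!ds, ] <- rdirichlet(n_non, mu_non * alpha)
  props[ds, ] <- rdirichlet(n_ds, mu_ds * alpha)
  high_nrbc_true <- rep(FALSE, n)
  ds_idx <- which(ds)
  n_high <- round(config$high_nrbc_fraction_ds * n_ds)
  # GATA1-mutant samples are over-represented in the high-nRBC subset
  # (the confounding structure seen in the study population)
  pool <- c(which(mutant), setdiff(ds_idx, which(mutant)))
  high_idx <- pool[seq_len(min(n_high, length(pool)))]
  if (length(high_idx) > 0L) {
    high_nrbc_true[high_idx] <- TRUE
    target_nrbc <- runif(length(high_idx), 0.27, 0.50)
    props[high_idx, ] <- props[high_idx, , drop = FALSE] *
      (1 - target_nrbc) /
      (1 - props[high_idx, "nRBC"])
    props[high_idx, "nRBC"] <- target_nrbc
  }

  # true clock values
  epi_age <- matrix(NA_real_, n, length(clocks),
                    dimnames = list(sid, vapply(clocks, `[[`, "", "name")))
  for (j in seq_along(clocks)) {
    cl <- clocks[[j]]
    epi_age[, j] <- if (cl$output_units == "years") {
      config$baseline_intercept_years + config$slope_years_per_day * age +
        config$ds_clock_offset_years * ds + config$gata1_vaf_clock_slope * vaf
    } else {
      ga
    }
  }

  # assemble beta matrix: clock CpG blocks then deconvolution block
  blocks <- lapply(seq_along(clocks), function(j)
    embed_age_signal(clocks[[j]], epi_age[, j]))
  if (!is.null(reference))
    blocks <- c(blocks, list(t(props %*% reference$mean_betas)))
  values <- do.call(rbind, blocks)
  colnames(values) <- sid
  if (anyDuplicated(rownames(values))) {
    if (!config$allow_cpg_overlap)
      stop_neoclocks("duplicate CpG ids across clocks/reference; ",
                     "use distinct prefixes or allow_cpg_overlap")
    # overlapping ids keep their first (clock-block) value
    values <- values[!duplicated(rownames(values)), , drop = FALSE]
  }
  n_clipped <- sum(vapply(blocks, function(b) attr(b, "n_clipped") %||% 0L, 0))
  if (config$noise_sd_beta > 0) {
    values <- values + rnorm(length(values), 0, config$noise_sd_beta)
    values <- clip01(values)
    n_clipped <- n_clipped + attr(values, "n_clipped")
    attr(values, "n_clipped") <- NULL
  }
  chromosome <- sample(paste0("chr", 1:22), nrow(values), replace = TRUE)
  names(chromosome) <- rownames(values)
  betas <- beta_matrix(values, chromosome)

  # binned log2 copy ratios: disomic baseline zero, chr21 shifted by dosage
  shift <- config$attenuation * log2((2 + pmin(mosaic_fraction + (t21_class == "full_T21"), 1)) / 2)
  bins <- data.frame(
    sample_id = rep(sid, each = config$n_chr21_bins + config$n_other_bins),
    chromosome = rep(c(rep("chr21", config$n_chr21_bins),
                       rep("chr1", config$n_other_bins)), n),
    bin_index = rep(c(seq_len(config$n_chr21_bins),
                      seq_len(config$n_other_bins)), n),
    log2_ratio = rep(shift, each = config$n_chr21_bins + config$n_other_bins) *
      rep(rep(c(1, 0), c(config$n_chr21_bins, config$n_other_bins)), n) +
      rnorm(n * (config$n_chr21_bins + config$n_other_bins), 0,
            config$bin_log2_noise_sd),
    stringsAsFactors = FALSE)

  sheet <- data.frame(sample_id = sid, ds = ds, sex = sex, ga_days = ga,
                      collection_age_days = coll, chron_age_days = age,
                      birthweight_g = bw, batch = batch,
                      all_status = all_status, gata1_status = gata1_status,
                      gata1_vaf = ifelse(sequenced, vaf, NA_real_),
                      stringsAsFactors = FALSE)
  sheet <- cbind(sheet, as.data.frame(pcs))

  truth <- list(epi_age = epi_age, cell_props = props, t21_class = t21_class,
                mosaic_fraction = mosaic_fraction, gata1_vaf = vaf,
                high_nrbc = high_nrbc_true,
                ds_offset_applied = config$ds_clock_offset_years,
                n_beta_clipped = as.integer(n_clipped))
  structure(list(betas = betas, sheet = sheet, bins = bins, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples (%d DS), %d CpGs, %d bin rows\n",
              nrow(x$sheet), sum(x$sheet$ds), nrow(x$betas$values),
              nrow(x$bins)))
  invisible(x)
}
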