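run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_neoclocks("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e))
  })
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

# lightweight deterministic hash of the scalar configuration settings
config_hash <- function(config) {
  scalars <- Filter(function(x) is.character(x) || is.numeric(x) ||
                      is.logical(x), config)
  txt <- paste(names(scalars),
               vapply(scalars, function(x) paste(format(x), collapse = ","),
                      ""), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Run the end-to-end newborn epigenetic-aging pipeline
#'
#' Executes, in order: QC filtering; clock imputation and computation (with
#' chromosome-21/deconvolution-CpG-excluded sensitivity variants of the
#' year-scale clocks when a reference and chromosome annotation are
#' available); cell-type deconvolution and high-nRBC flagging; trisomy 21
#' classification from binned log2 copy ratios; reference-line fitting and
#' age-acceleration residuals for year-scale clocks; gestational
#' age acceleration for day-scale clocks; covariate screening, PC-count
#' selection, and the DS association model suite (base and
#' cell-proportion-adjusted models with sensitivity subsets); GATA1 status
#' and VAF models when sequencing data are present; and bivariate tests.
#' All stages are deterministic given the inputs, so re-running a
#' configuration reproduces its outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list (class `pipeline_result`) with elements `qc`, `clocks`
#'   (list of `clock_values`), `proportions`, `t21`, `reference_lines`,
#'   `dnamaa`, `gestational_aa`, `covariates_used`, `models` (a
#'   `data.frame` report), `gata1`, `bivariate`, `t21_comparison`, `data`
#'   (the merged per-sample analysis table) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(package_version = as.character(utils::packageVersion("neoclocks")),
              config_hash = config_hash(config), seed = config$seed,
              stages = list())
  betas <- run_stage("input", resolve_input(config$betas, read_betas))
  sheet <- run_stage("input", resolve_input(config$sheet, read_sample_sheet))
  bins <- if (!is.null(config$bins))
    run_stage("input", resolve_input(config$bins, read_bins))
  reference <- if (!is.null(config$reference))
    run_stage("input", resolve_input(config$reference, read_cell_reference))
  clocks <- run_stage("input", lapply(config$clocks, function(cl)
    if (is.character(cl)) load_clock(cl) else cl))
  names(clocks) <- vapply(clocks, `[[`, "", "name")

  qc <- run_stage("qc", qc_filter(betas, config$detection_p,
                                  config$detection_threshold,
                                  config$missingness_threshold))
  betas <- qc$betas
  sheet <- sheet[sheet$sample_id %in% sample_ids(betas), , drop = FALSE]
  log$stages$qc <- c(n_cpgs = nrow(betas$values),
                     n_samples = ncol(betas$values))

  # clocks, plus CpG-excluded sensitivity variants of year-scale clocks
  year_clocks <- names(clocks)[vapply(clocks, `[[`, "", "output_units") ==
                                 "years"]
  if (!is.null(reference) && !is.null(betas$chromosome)) {
    for (nm in year_clocks) {
      excl <- union(clock_reference_overlap(clocks[[nm]], reference),
                    intersect(names(clocks[[nm]]$weights),
                              cpgs_on_chromosome(betas, "chr21")))
      if (length(excl) > 0L)
        clocks[[paste0(nm, "_noChr21deconv")]] <-
          suppressWarnings(restrict_clock(clocks[[nm]], exclude_cpgs = excl,
                                          suffix = "_noChr21deconv"))
    }
  }
  clock_values <- run_stage("clocks", lapply(clocks, function(cl)
    compute_clock(impute_missing_clock_cpgs(betas, cl), cl)))
  log$stages$clocks <- vapply(clock_values, function(cv)
    cv$n_imputed_cpgs, 0L)

  props <- NULL
  if (!is.null(reference)) {
    props <- run_stage("deconvolution",
                       deconvolve(betas, reference,
                                  threshold = config$nrbc_threshold))
    log$stages$deconvolution <- c(n_high_nrbc = sum(props$high_nrbc))
  }

  t21 <- NULL
  if (!is.null(bins)) {
    t21 <- run_stage("cnv", {
      med <- chr21_median_log2(bins)
      ds <- sheet$ds[match(names(med), sheet$sample_id)]
      keep <- !is.na(ds)
      classify_t21(med[keep], ds[keep],
                   full_threshold = config$full_t21_threshold,
                   sd_mult = config$sd_mult)
    })
    log$stages$cnv <- table(t21$call)
  }

  # merged analysis table
  data <- sheet
  for (nm in names(clock_values))
    data[[paste0("clock_", nm)]] <-
      clock_values[[nm]]$values[data$sample_id]
  if (!is.null(props)) {
    data <- merge(data, as.data.frame(props), by = "sample_id",
                  sort = FALSE)
  } else {
    data$high_nrbc <- FALSE
  }

  # reference lines and age acceleration
  lines <- list(); aa <- list()
  primary <- config$primary_clock %||% year_clocks[1L]
  for (nm in intersect(names(clock_values),
                       c(year_clocks,
                         paste0(year_clocks, "_noChr21deconv")))) {
    lines[[nm]] <- run_stage("dnamaa",
      fit_reference_line(clock_values[[nm]],
                         data$chron_age_days[match(names(clock_values[[nm]]$values),
                                                   data$sample_id)],
                         !data$ds[match(names(clock_values[[nm]]$values),
                                        data$sample_id)]))
    aa[[nm]] <- compute_dnamaa(clock_values[[nm]],
                               data$chron_age_days[match(names(clock_values[[nm]]$values),
                                                         data$sample_id)],
                               lines[[nm]])
    data[[paste0("dnamaa_", nm)]] <- aa[[nm]]$values[data$sample_id]
  }
  gest_aa <- list()
  day_clocks <- names(clocks)[vapply(clocks, `[[`, "", "output_units") ==
                                "days"]
  for (nm in day_clocks) {
    gest_aa[[nm]] <- run_stage("gestational_aa",
      gestational_dnamaa(clock_values[[nm]],
                         data$ga_days[match(names(clock_values[[nm]]$values),
                                            data$sample_id)],
                         data$ds[match(names(clock_values[[nm]]$values),
                                       data$sample_id)]))
    data[[paste0("gaa_", nm)]] <- gest_aa[[nm]]$values[data$sample_id]
  }

  # model suite on the primary year-scale clock
  models <- NULL; gata1 <- NULL; covariates_used <- NULL
  if (length(primary) == 1L && !is.na(primary)) {
    out_clock <- paste0("clock_", primary)
    out_aa <- paste0("dnamaa_", primary)
    slope <- config$paper_slope %||% lines[[primary]]$slope
    day_line <- list(slope = slope)
    pc_cols <- grep("^pc[0-9]+$", names(data), value = TRUE)
    screened <- run_stage("models",
      select_covariates(data, out_clock,
                        intersect(c("sex", "birthweight_g", "batch"),
                                  names(data)),
                        p_threshold = config$covariate_p,
                        reference_mask = !data$ds))
    k_clock <- if (length(pc_cols))
      select_num_pcs(data, out_clock, pc_cols,
                     covariates = c("ds", "chron_age_days", screened),
                     max_pcs = min(config$max_pcs, length(pc_cols)))$k else 0L
    k_aa <- if (length(pc_cols))
      select_num_pcs(data, out_aa, pc_cols,
                     covariates = c("ds", screened),
                     max_pcs = min(config$max_pcs, length(pc_cols)))$k else 0L
    cell_covs <- if (!is.null(props)) setdiff(CELL_TYPES, "Gran") else
      character()
    base_clock <- c("chron_age_days", screened, pc_cols[seq_len(k_clock)])
    base_aa <- c(screened, pc_cols[seq_len(k_aa)])
    covariates_used <- list(screened = screened, n_pcs_clock = k_clock,
                            n_pcs_dnamaa = k_aa, cell = cell_covs)
    specs <- list(
      list("base", out_clock, base_clock, "all"),
      list("full", out_clock, c(base_clock, cell_covs), "all"),
      list("full_excl_high_nrbc", out_clock, c(base_clock, cell_covs),
           "exclude_high_nrbc"),
      list("full_gata1_wildtype", out_clock, c(base_clock, cell_covs),
           "gata1_wildtype_plus_nonds"),
      list("base", out_aa, base_aa, "all"),
      list("full", out_aa, c(base_aa, cell_covs), "all"),
      list("full_excl_high_nrbc", out_aa, c(base_aa, cell_covs),
           "exclude_high_nrbc"),
      list("full_gata1_wildtype", out_aa, c(base_aa, cell_covs),
           "gata1_wildtype_plus_nonds"))
    models <- run_stage("models", do.call(rbind, lapply(specs, function(s) {
      skip_gata1 <- s[[4]] == "gata1_wildtype_plus_nonds" &&
        all(is.na(data$gata1_status))
      if (skip_gata1) return(NULL)
      m <- fit_model(data, s[[2]], "ds", covariates = s[[3]],
                     subset_rule = s[[4]], line = day_line)
      data.frame(model = s[[1]], outcome = s[[2]], subset = s[[4]],
                 estimate = m$estimate, ci_low = m$ci_low,
                 ci_high = m$ci_high, p_value = m$p_value,
                 n_used = m$n_used, aa_days = m$aa_days,
                 stringsAsFactors = FALSE)
    })))
    if (any(!is.na(data$gata1_status)) &&
        any(data$gata1_status == "mutant", na.rm = TRUE))
      gata1 <- run_stage("gata1", suppressWarnings(
        fit_gata1_models(data, out_clock, covariates = cell_covs,
                         line = day_line)))
  }

  bivar <- run_stage("bivariate", {
    cont <- intersect(c("ga_days", "collection_age_days", "chron_age_days",
                        "birthweight_g"), names(data))
    cont <- c(cont, grep("^clock_|^dnamaa_", names(data), value = TRUE))
    sp <- if (length(primary) == 1L && !is.na(primary))
      stats::setNames(list(c(paste0("clock_", primary), "chron_age_days")),
                      paste0("clock_", primary, "_vs_age")) else list()
    bivariate_tests(data, "ds", continuous = cont,
                    categorical = intersect(c("sex", "all_status"),
                                            names(data)),
                    spearman = sp)
  })
  t21_cmp <- NULL
  if (!is.null(t21) && length(primary) == 1L && !is.na(primary)) {
    grp <- ifelse(!data$ds, "non_DS",
                  t21$call[match(data$sample_id, t21$sample_id)])
    if (length(unique(grp[!is.na(grp)])) >= 2L)
      t21_cmp <- run_stage("t21_comparison",
        group_comparison_tests(data[[paste0("clock_", primary)]], grp))
  }

  result <- structure(list(qc = qc$report, clocks = clock_values,
                           proportions = props, t21 = t21,
                           reference_lines = lines, dnamaa = aa,
                           gestational_aa = gest_aa,
                           covariates_used = covariates_used,
                           models = models, gata1 = gata1,
                           bivariate = bivar, t21_comparison = t21_cmp,
                           data = data, log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", ncol(x$data), "columns x", nrow(x$data),
      "samples;", length(x$clocks), "clocks\n")
  if (!is.null(x$models)) {
    cat("DS association models:\n")
    print(x$models, digits = 4)
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clocks_df <- do.call(rbind, lapply(result$clocks, as.data.frame))
  write.csv(clocks_df, file.path(dir, "clocks.csv"), row.names = FALSE)
  if (!is.null(result$proportions))
    write.csv(as.data.frame(result$proportions),
              file.path(dir, "proportions.csv"), row.names = FALSE)
  if (!is.null(result$t21))
    write.csv(result$t21, file.path(dir, "t21_calls.csv"), row.names = FALSE)
  if (length(result$dnamaa) > 0L)
    write.csv(do.call(rbind, lapply(result$dnamaa, as.data.frame)),
              file.path(dir, "dnamaa.csv"), row.names = FALSE)
  if (!is.null(result$models))
    write.csv(result$models, file.path(dir, "models.csv"), row.names = FALSE)
  jsonlite::write_json(result$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
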