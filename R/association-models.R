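# Shared OLS fitting with collinearity detection and t-based Wald CIs.
fit_ols <- function(formula, data, exposure, conf_level = 0.95) {
  mf <- model.frame(formula, data = data, na.action = na.omit)
  fit <- lm(formula, data = mf)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_neoclocks("collinear design; aliased columns: ",
                   paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  hit <- grep(paste0("^", exposure), rownames(sm), value = TRUE)
  if (length(hit) != 1L)
    stop_neoclocks("could not identify a single coefficient for exposure '",
                   exposure, "' (found: ", paste(hit, collapse = ", "), ")")
  est <- sm[hit, "Estimate"]
  se <- sm[hit, "Std. Error"]
  tcrit <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  list(estimate = unname(est), ci_low = unname(est - tcrit * se),
       ci_high = unname(est + tcrit * se),
       p_value = unname(sm[hit, "Pr(>|t|)"]), n_used = nrow(mf),
       coefficient = hit, fit = fit)
}

#' Screen candidate covariates by univariable regression
#'
#' Retains the candidates whose univariable linear regression against the
#' outcome, within the reference (non-DS) group, yields p < `p_threshold`.
#' Constant candidates are skipped with a warning. An empty survivor set is
#' returned as such; downstream models then fall back to exposure-only.
#'
#' @param data Data frame (already restricted to the screening group, or
#'   restricted via `reference_mask`).
#' @param outcome Outcome column name.
#' @param candidates Candidate covariate column names.
#' @param p_threshold Retention threshold, default 0.2.
#' @param reference_mask Optional logical vector restricting `data`.
#' @return Character vector of retained covariate names.
#' @export
select_covariates <- function(data, outcome, candidates, p_threshold = 0.2,
                              reference_mask = NULL) {
  if (length(candidates) < 1L) stop_neoclocks("need at least one candidate")
  if (!is.null(reference_mask)) data <- data[reference_mask, , drop = FALSE]
  keep <- vapply(candidates, function(v) {
    d <- data[!is.na(data[[outcome]]) & !is.na(data[[v]]), c(outcome, v)]
    if (length(unique(d[[v]])) < 2L) {
      warning("constant candidate '", v, "' skipped")
      return(FALSE)
    }
    fit <- lm(reformulate(v, response = outcome), data = d)
    # overall F test covers multi-level factors; equals the t test when 1 df
    fs <- summary(fit)$fstatistic
    p <- pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
    is.finite(p) && p < p_threshold
  }, logical(1))
  candidates[keep]
}

#' Choose the number of ancestry principal components by AIC
#'
#' Fits the nested sequence of models with the first k PCs (k = 0..max)
#' added to any base covariates, on the common complete-case rows, and
#' returns the smallest k minimizing AIC (ties broken toward smaller k).
#' Likelihood-ratio p-values of each successive PC are reported alongside.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param pc_cols Ordered PC column names.
#' @param covariates Base covariates included in every model.
#' @param max_pcs Maximum number of PCs considered, capped (with a warning)
#'   at the number of available PC columns.
#' @return List with `k` (selected count), `aic` (named vector over k),
#'   `lrt_p` (p-value of adding PC k to the k-1 model).
#' @export
select_num_pcs <- function(data, outcome, pc_cols, covariates = character(),
                           max_pcs = 10) {
  if (max_pcs > length(pc_cols)) {
    warning("max_pcs exceeds available PC columns; capped at ",
            length(pc_cols))
    max_pcs <- length(pc_cols)
  }
  use <- c(outcome, covariates, pc_cols[seq_len(max_pcs)])
  d <- data[complete.cases(data[, use, drop = FALSE]), use, drop = FALSE]
  fits <- lapply(0:max_pcs, function(k) {
    rhs <- c(covariates, pc_cols[seq_len(k)])
    lm(reformulate(if (length(rhs)) rhs else "1", response = outcome),
       data = d)
  })
  aic <- vapply(fits, AIC, numeric(1))
  names(aic) <- paste0("k", 0:max_pcs)
  lrt_p <- vapply(seq_len(max_pcs), function(k) {
    a <- anova(fits[[k]], fits[[k + 1L]])
    a[["Pr(>F)"]][2L]
  }, numeric(1))
  names(lrt_p) <- paste0("k", seq_len(max_pcs))
  list(k = unname(which.min(aic)) - 1L, aic = aic, lrt_p = lrt_p)
}

#' Fit a covariate-adjusted association model
#'
#' Ordinary least squares of an epigenetic outcome (clock value, age
#' acceleration, or cell proportion) on an exposure, with Wald 95%
#' confidence intervals from the t distribution. Subset rules implement the
#' sensitivity analyses: excluding high-nRBC samples, restricting to
#' GATA1-wildtype DS plus all non-DS newborns, or to DS newborns only.
#' When a reference line is supplied and the outcome is on the clock scale,
#' the estimate and CI are also expressed as days of age acceleration via
#' [estimate_to_days()].
#'
#' @param data Data frame containing outcome, exposure, covariates and any
#'   columns the subset rule needs (`high_nrbc`, `gata1_status`, `ds`).
#' @param outcome Outcome column name.
#' @param exposure Exposure column name (e.g. `"ds"`, `"gata1_vaf"`).
#' @param covariates Covariate column names. Granulocyte proportions must
#'   not be included (the seven proportions sum to one; granulocytes are the
#'   dropped reference category).
#' @param subset_rule One of `"all"`, `"exclude_high_nrbc"`,
#'   `"gata1_wildtype_plus_nonds"`, `"ds_only"`.
#' @param line Optional [fit_reference_line()] result for day conversion.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `model_result`: `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `n_used`, `aa_days` (with `aa_days_ci`), plus
#'   bookkeeping fields (`outcome`, `exposure`, `subset_rule`, `formula`).
#' @export
fit_model <- function(data, outcome, exposure, covariates = character(),
                      subset_rule = c("all", "exclude_high_nrbc",
                                      "gata1_wildtype_plus_nonds", "ds_only"),
                      line = NULL, conf_level = 0.95) {
  subset_rule <- match.arg(subset_rule)
  if ("Gran" %in% covariates)
    stop_neoclocks("granulocyte proportion must not be a covariate ",
                   "(compositional collinearity); it is the dropped category")
  d <- switch(subset_rule,
    all = data,
    exclude_high_nrbc = data[!data$high_nrbc, , drop = FALSE],
    gata1_wildtype_plus_nonds =
      data[!data$ds | (!is.na(data$gata1_status) &
                         data$gata1_status == "wildtype"), , drop = FALSE],
    ds_only = data[data$ds, , drop = FALSE])
  if (is.logical(d[[exposure]]) || is.factor(d[[exposure]]) ||
      is.character(d[[exposure]])) {
    lev <- unique(d[[exposure]][!is.na(d[[exposure]])])
    if (length(lev) < 2L)
      stop_neoclocks("subset rule '", subset_rule,
                     "' leaves a single level of '", exposure, "'")
  }
  fm <- reformulate(c(exposure, covariates), response = outcome)
  fit <- fit_ols(fm, d, exposure = exposure, conf_level = conf_level)
  aa_days <- aa_days_ci <- NULL
  if (!is.null(line)) {
    aa_days <- estimate_to_days(fit$estimate, line$slope)
    aa_days_ci <- estimate_to_days(c(fit$ci_low, fit$ci_high), line$slope)
  }
  structure(list(estimate = fit$estimate, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, p_value = fit$p_value,
                 n_used = fit$n_used, aa_days = aa_days,
                 aa_days_ci = aa_days_ci, outcome = outcome,
                 exposure = exposure, subset_rule = subset_rule,
                 formula = deparse(fm)),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model %s ~ %s [%s]: estimate %.4f (%.4f-%.4f), p = %s, n = %d%s\n",
              x$outcome, x$exposure, x$subset_rule, x$estimate, x$ci_low,
              x$ci_high, format_p(x$p_value), x$n_used,
              if (!is.null(x$aa_days))
                sprintf(", AA = %.1f days", x$aa_days) else ""))
  invisible(x)
}

#' Format a p-value with the conventional reporting floor
#' @param p Numeric p-value(s).
#' @param floor Values below this print as `"< floor"`; raw values are kept
#'   in the model objects.
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-4) {
  ifelse(p < floor, paste0("<", format(floor)), signif(p, 3))
}

#' GATA1 mutation models among sequenced DS newborns
#'
#' Two models on the DS subset with GATA1 sequencing: (1) mutation status
#' (mutant vs wildtype) against the epigenetic outcome; (2) among
#' mutation-positive newborns only, variant allele fraction (VAF) against
#' the outcome. Both adjust for the supplied covariates. The VAF estimate is
#' also expressed as days of acceleration per 10% VAF increase
#' (`estimate * 0.1 / slope`).
#'
#' @param data Data frame restricted (or restrictable via its `ds` and
#'   `gata1_status` columns) to sequenced DS newborns.
#' @inheritParams fit_model
#' @return List with elements `status` (a `model_result`), `vaf` (a
#'   `model_result` with extra field `days_per_10pct_vaf`, or `NULL` when
#'   fewer than 3 mutation-positive samples are available).
#' @export
fit_gata1_models <- function(data, outcome, covariates = character(),
                             line = NULL) {
  d <- data[data$ds & !is.na(data$gata1_status), , drop = FALSE]
  if (nrow(d) == 0L)
    stop_neoclocks("no sequenced DS samples")
  if (all(d$gata1_status == "wildtype"))
    stop_neoclocks("all sequenced DS samples are GATA1 wildtype; ",
                   "status model is degenerate")
  d$gata1_mutant <- d$gata1_status == "mutant"
  status <- fit_model(d, outcome, "gata1_mutant", covariates,
                      subset_rule = "all", line = line)
  mut <- d[d$gata1_mutant, , drop = FALSE]
  vaf <- NULL
  if (sum(!is.na(mut$gata1_vaf)) < 3L) {
    warning("fewer than 3 GATA1 mutation-positive samples; VAF model skipped")
  } else {
    vaf_covs <- covariates
    if (nrow(mut) < length(covariates) + 3L) {
      warning("too few mutation-positive samples to adjust for ",
              length(covariates), " covariates; VAF model fitted unadjusted")
      vaf_covs <- character()
    }
    vaf <- fit_model(mut, outcome, "gata1_vaf", vaf_covs,
                     subset_rule = "all", line = line)
    if (!is.null(line))
      vaf$days_per_10pct_vaf <- estimate_to_days(vaf$estimate * 0.1,
                                                 line$slope)
  }
  list(status = status, vaf = vaf)
}

#' Bivariate group comparisons
#'
#' Two-group comparisons of cohort characteristics: Student's t test for
#' continuous variables, the chi-squared test for categorical variables,
#' and Spearman correlations for clock-versus-age associations. Variables
#' whose groups have fewer than 2 observations are skipped and flagged.
#'
#' @param data Data frame.
#' @param group_col Name of a two-level grouping column (e.g. `"ds"`).
#' @param continuous,categorical Column names to test.
#' @param spearman Optional named list of 2-element character vectors; each
#'   entry adds a Spearman correlation test between the two columns.
#' @return A `data.frame` with `variable`, `test`, `statistic`, `p_value`,
#'   `skipped`.
#' @export
bivariate_tests <- function(data, group_col, continuous = character(),
                            categorical = character(), spearman = list()) {
  g <- data[[group_col]]
  if (length(unique(g[!is.na(g)])) < 2L)
    stop_neoclocks("grouping column must have >= 2 levels")
  rows <- list()
  for (v in continuous) {
    ok <- !is.na(data[[v]]) & !is.na(g)
    if (min(table(g[ok])) < 2L) {
      rows[[v]] <- data.frame(variable = v, test = "t", statistic = NA_real_,
                              p_value = NA_real_, skipped = TRUE)
      next
    }
    tt <- t.test(data[[v]][ok] ~ g[ok])
    rows[[v]] <- data.frame(variable = v, test = "t",
                            statistic = unname(tt$statistic),
                            p_value = tt$p.value, skipped = FALSE)
  }
  for (v in categorical) {
    ok <- !is.na(data[[v]]) & !is.na(g)
    tab <- table(data[[v]][ok], g[ok])
    if (any(dim(tab) < 2L)) {
      rows[[v]] <- data.frame(variable = v, test = "chisq",
                              statistic = NA_real_, p_value = NA_real_,
                              skipped = TRUE)
      next
    }
    ct <- suppressWarnings(chisq.test(tab))
    rows[[v]] <- data.frame(variable = v, test = "chisq",
                            statistic = unname(ct$statistic),
                            p_value = ct$p.value, skipped = FALSE)
  }
  for (nm in names(spearman)) {
    pair <- spearman[[nm]]
    ct <- suppressWarnings(cor.test(data[[pair[1L]]], data[[pair[2L]]],
                                    method = "spearman"))
    rows[[nm]] <- data.frame(variable = nm, test = "spearman",
                             statistic = unname(ct$estimate),
                             p_value = ct$p.value, skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-group comparison with BH-adjusted pairwise tests
#'
#' Kruskal–Wallis global test across groups (e.g. full T21, likely
#' mosaic/partial T21, non-DS), followed by pairwise Wilcoxon rank-sum
#' tests with Benjamini–Hochberg adjustment.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping factor (>= 2 levels).
#' @return List with `global_p` (Kruskal–Wallis), `pairwise` (matrix of
#'   BH-adjusted Wilcoxon p-values), `n_per_group`.
#' @export
group_comparison_tests <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop_neoclocks("need >= 2 groups")
  kw <- kruskal.test(values, groups)
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = "BH"))
  n_per <- as.integer(table(groups))
  names(n_per) <- levels(groups)
  list(global_p = kw$p.value, pairwise = pw$p.value, n_per_group = n_per)
}
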