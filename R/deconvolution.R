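#' Estimate blood cell-type proportions by constrained projection
#'
#' For each sample, solves the nonnegative least-squares problem
#' `min_w || beta - t(ref) %*% w ||^2  s.t.  w >= 0` over the reference
#' CpGs (Lawson–Hanson NNLS via [pracma::lsqnonneg()]), then normalizes the
#' solution to sum to 1 so the estimates are compositional proportions.
#'
#' @param betas A [beta_matrix()] containing every reference CpG.
#' @param reference A [cell_reference()].
#' @param threshold High-nRBC flag threshold passed to [flag_high_nrbc()].
#' @return A `data.frame` (class `cell_proportions`) with one row per
#'   sample: `sample_id`, one column per cell type, `residual_norm` (of the
#'   unnormalized NNLS fit), and logical `high_nrbc`.
#' @export
deconvolve <- function(betas, reference, threshold = 0.25) {
  ref <- reference$mean_betas
  if (qr(ref)$rank < nrow(ref))
    stop_neoclocks("rank-deficient reference: proportions unidentifiable")
  missing_cpgs <- setdiff(colnames(ref), cpg_ids(betas))
  if (length(missing_cpgs) > 0L)
    stop_neoclocks("reference CpGs missing from beta matrix: ",
                   paste(utils::head(missing_cpgs, 5L), collapse = ", "),
                   if (length(missing_cpgs) > 5L) ", ...")
  x <- betas$values[colnames(ref), , drop = FALSE]
  if (anyNA(x))
    stop_neoclocks("NA beta values among reference CpGs; run QC/imputation first")
  C <- t(ref)  # CpGs x cell types
  fits <- lapply(seq_len(ncol(x)), function(i) pracma::lsqnonneg(C, x[, i]))
  w <- t(vapply(fits, `[[`, numeric(nrow(ref)), "x"))
  resid <- vapply(fits, `[[`, numeric(1), "resid.norm")
  tot <- rowSums(w)
  if (any(tot <= 0))
    stop_neoclocks("all-zero NNLS solution for sample(s): ",
                   paste(colnames(x)[tot <= 0], collapse = ", "))
  w <- w / tot
  colnames(w) <- rownames(ref)
  out <- data.frame(sample_id = colnames(x), w, residual_norm = sqrt(resid),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$high_nrbc <- flag_high_nrbc(out, threshold = threshold)
  class(out) <- c("cell_proportions", "data.frame")
  out
}

#' Flag samples with markedly high nucleated-red-blood-cell proportions
#'
#' High nRBC proportions distort newborn blood methylation genome-wide, so
#' such samples are flagged and excluded in sensitivity analyses. The flag
#' is strict: a proportion exactly at the threshold is not flagged.
#'
#' @param props A `cell_proportions` data frame (or any data frame with an
#'   `nRBC` column), or a numeric vector of nRBC proportions.
#' @param threshold Flag threshold, default 0.25 (i.e. > 25%).
#' @return Logical vector.
#' @export
flag_high_nrbc <- function(props, threshold = 0.25) {
  nrbc <- if (is.numeric(props)) props else props$nRBC
  if (is.null(nrbc)) stop_neoclocks("no nRBC proportions supplied")
  if (any(nrbc < 0 | nrbc > 1, na.rm = TRUE))
    stop_neoclocks("nRBC proportions must lie in [0, 1]")
  nrbc > threshold
}

#' Compare cell-type proportions between groups by adjusted regression
#'
#' Fits, per cell type, a linear model with the cell proportion as outcome
#' and DS status as exposure, adjusting for sex, gestational age, age at
#' blood collection, birthweight, batch, and ancestry principal components.
#'
#' @param props A `cell_proportions` data frame from [deconvolve()].
#' @param sheet Sample sheet with columns `sample_id`, `ds`, `sex`,
#'   `ga_days`, `collection_age_days`, `birthweight_g`, `batch` and PC
#'   columns.
#' @param pc_cols Names of principal-component columns to adjust for.
#' @return A `data.frame` with one row per cell type: `estimate` (DS
#'   effect), `ci_low`, `ci_high`, `p_value`, `n_used`.
#' @export
compare_cell_props <- function(props, sheet,
                               pc_cols = grep("^pc", names(sheet),
                                              value = TRUE)) {
  dat <- merge(sheet, as.data.frame(props), by = "sample_id")
  covs <- c("sex", "ga_days", "collection_age_days", "birthweight_g",
            "batch", pc_cols)
  covs <- covs[covs %in% names(dat)]
  res <- lapply(CELL_TYPES, function(ct) {
    fm <- reformulate(c("ds", covs), response = ct)
    fit <- fit_ols(fm, dat, exposure = "dsTRUE")
    data.frame(cell_type = ct, estimate = fit$estimate, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p_value = fit$p_value,
               n_used = fit$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
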