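#' Per-bin log2 copy ratios against a reference cohort
#'
#' For each genomic bin, the copy ratio is the sample's intensity divided by
#' the median intensity of the reference samples in that bin, on the log2
#' scale. In practice the reference is a set of randomly selected disomic
#' (non-DS) newborns.
#'
#' @param sample_bins Numeric vector of per-bin intensities for one sample.
#' @param reference_samples Numeric matrix (bins x reference samples) or a
#'   list of per-bin intensity vectors.
#' @return Numeric vector of per-bin log2 ratios.
#' @export
compute_bin_log2 <- function(sample_bins, reference_samples) {
  if (is.list(reference_samples))
    reference_samples <- do.call(cbind, reference_samples)
  if (is.vector(reference_samples))
    reference_samples <- matrix(reference_samples, ncol = 1L)
  if (ncol(reference_samples) < 1L)
    stop_neoclocks("need at least one reference sample")
  if (nrow(reference_samples) != length(sample_bins))
    stop_neoclocks("reference bin count does not match the sample")
  if (any(sample_bins <= 0) || any(reference_samples <= 0))
    stop_neoclocks("intensities must be strictly positive")
  ref_med <- apply(reference_samples, 1L, median)
  log2(sample_bins / ref_med)
}

#' Median chromosome 21 log2 copy ratio
#'
#' @param bins Bin-level `data.frame` with columns `sample_id`,
#'   `chromosome`, `bin_index`, `log2_ratio`.
#' @param sample_id Optional sample id(s); default all samples in `bins`.
#' @param chr Chromosome label, default `"chr21"`.
#' @return Named numeric vector of per-sample medians over the chromosome's
#'   bins.
#' @export
chr21_median_log2 <- function(bins, sample_id = NULL, chr = "chr21") {
  stopifnot(all(c("sample_id", "chromosome", "log2_ratio") %in% names(bins)))
  sub <- bins[bins$chromosome == chr, , drop = FALSE]
  if (!is.null(sample_id)) {
    absent <- setdiff(sample_id, sub$sample_id)
    if (length(absent) > 0L)
      stop_neoclocks("no ", chr, " bins for sample(s): ",
                     paste(absent, collapse = ", "))
    sub <- sub[sub$sample_id %in% sample_id, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop_neoclocks("no ", chr, " bins in the table")
  if (anyNA(sub$log2_ratio) || any(!is.finite(sub$log2_ratio)))
    stop_neoclocks("non-finite log2 ratios on ", chr)
  out <- tapply(sub$log2_ratio, sub$sample_id, median)
  med <- as.numeric(out)
  names(med) <- names(out)
  if (!is.null(sample_id)) med <- med[sample_id]
  med
}

#' Classify full versus likely mosaic/partial trisomy 21
#'
#' Applies the two-rule classification to per-sample median chromosome 21
#' log2 copy ratios. For a DS-labelled sample: it is called
#' `likely_mosaic_partial` when its median lies more than `sd_mult` standard
#' deviations below the DS-cohort mean (the cohort statistics include all DS
#' samples, candidates included) while still exceeding the maximum non-DS
#' median; otherwise it is `full_T21` when the median is at least
#' `full_threshold`; otherwise `not_elevated`, with a QC warning. The mosaic
#' rule takes precedence: the flagged range in practice sits below the full
#' trisomy threshold. Non-DS samples are always `not_elevated`.
#'
#' @param medians Named numeric vector of per-sample median chr21 log2
#'   ratios (e.g. from [chr21_median_log2()]).
#' @param ds_labels Logical vector (same order or same names) marking DS
#'   samples.
#' @param full_threshold Full-trisomy threshold on the median log2 ratio,
#'   default 0.2.
#' @param sd_mult Standard-deviation multiplier of the mosaic rule,
#'   default 2. The SD uses the n-1 denominator.
#' @param cohort_stats Optional fixed statistics (named vector with
#'   `mean_ds`, `sd_ds`, `max_non_ds`), e.g. from a previous cohort's
#'   classification; by default they are derived from the data at hand.
#' @return A `data.frame` with `sample_id`, `chr21_median_log2`, `call`,
#'   and the cohort statistics (`mean_ds`, `sd_ds`, `max_non_ds`) attached
#'   both as columns and as attribute `cohort_stats`.
#' @export
classify_t21 <- function(medians, ds_labels, full_threshold = 0.2,
                         sd_mult = 2, cohort_stats = NULL) {
  if (length(medians) != length(ds_labels))
    stop_neoclocks("'medians' and 'ds_labels' lengths differ")
  if (is.null(cohort_stats)) {
    if (!any(ds_labels) || all(ds_labels))
      stop_neoclocks("classification needs both DS and non-DS samples ",
                     "(the mosaic window is defined by both cohorts)")
    mean_ds <- mean(medians[ds_labels])
    sd_ds <- sd(medians[ds_labels])
    max_non_ds <- max(medians[!ds_labels])
  } else {
    mean_ds <- cohort_stats[["mean_ds"]]
    sd_ds <- cohort_stats[["sd_ds"]]
    max_non_ds <- cohort_stats[["max_non_ds"]]
  }
  call <- rep("not_elevated", length(medians))
  mosaic <- ds_labels & medians < mean_ds - sd_mult * sd_ds &
    medians > max_non_ds
  full <- ds_labels & !mosaic & medians >= full_threshold
  call[mosaic] <- "likely_mosaic_partial"
  call[full] <- "full_T21"
  low <- ds_labels & call == "not_elevated"
  if (any(low))
    warning(sum(low), " DS sample(s) with median chr21 log2 ratio below ",
            full_threshold, " and outside the mosaic window: ",
            paste(utils::head(names(medians)[low] %||%
                                which(low), 5L), collapse = ", "))
  out <- data.frame(sample_id = names(medians) %||%
                      as.character(seq_along(medians)),
                    chr21_median_log2 = unname(medians), call = call,
                    mean_ds = mean_ds, sd_ds = sd_ds,
                    max_non_ds = max_non_ds,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cohort_stats") <- c(mean_ds = mean_ds, sd_ds = sd_ds,
                                 max_non_ds = max_non_ds)
  out
}

#' Draw the disomic reference set for copy-ratio computation
#'
#' @param sheet Sample sheet with `sample_id` and logical `ds`.
#' @param n_reference Number of non-DS reference samples, default 20.
#' @param seed Integer seed for the draw (logged in the result's attribute).
#' @return Character vector of reference sample ids, with attribute `seed`.
#' @export
select_cnv_reference <- function(sheet, n_reference = 20, seed = 1L) {
  pool <- sheet$sample_id[!sheet$ds]
  if (length(pool) < 1L) stop_neoclocks("no non-DS samples to draw from")
  n_reference <- min(n_reference, length(pool))
  set.seed(seed)
  out <- sample(pool, n_reference)
  attr(out, "seed") <- seed
  out
}
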