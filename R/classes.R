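#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds CpG-by-sample DNA methylation fractions (beta
#' values) together with an optional CpG-to-chromosome annotation. Rows are
#' CpGs, columns are samples. Non-missing values must lie in \[0, 1\];
#' missing values (`NA`) are allowed and are handled by QC filtering and
#' clock imputation.
#'
#' @param values Numeric matrix with unique rownames (CpG ids) and unique
#'   colnames (sample ids).
#' @param chromosome Optional character vector of chromosome labels (e.g.
#'   `"chr21"`), either named by CpG id or in row order of `values`.
#' @return An object of class `beta_matrix` with elements `values` and
#'   `chromosome`.
#' @export
beta_matrix <- function(values, chromosome = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_neoclocks("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_neoclocks("rownames(values) must be unique CpG ids")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_neoclocks("colnames(values) must be unique sample ids")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop_neoclocks("beta values must lie in [0, 1]; got range [",
                   signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (!is.null(chromosome)) {
    if (is.null(names(chromosome))) {
      if (length(chromosome) != nrow(values))
        stop_neoclocks("unnamed 'chromosome' must have one entry per CpG")
      names(chromosome) <- rownames(values)
    }
    chromosome <- chromosome[rownames(values)]
    names(chromosome) <- rownames(values)
  }
  structure(list(values = values, chromosome = chromosome),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%s chromosome annotation, %d NA)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$chromosome)) "no" else "with",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' CpG and sample identifiers of a beta matrix
#' @param x A `beta_matrix`.
#' @return Character vector of ids.
#' @export
cpg_ids <- function(x) rownames(x$values)

#' @rdname cpg_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' CpGs lying on given chromosomes
#'
#' @param x A `beta_matrix` with chromosome annotation.
#' @param chr Chromosome labels, e.g. `"chr21"`.
#' @return CpG ids of `x` annotated to `chr`.
#' @export
cpgs_on_chromosome <- function(x, chr) {
  if (is.null(x$chromosome))
    stop_neoclocks("beta matrix carries no chromosome annotation")
  names(x$chromosome)[x$chromosome %in% chr]
}

#' Define an epigenetic clock
#'
#' A clock is a linear predictor over CpG beta values — an intercept plus a
#' weighted sum — optionally passed through the standard age-calibration
#' transform. Adult-trained age clocks (pan-tissue, skin & blood) use the
#' calibrated transform with an anchor age of 20 years; gestational age
#' clocks return the linear predictor directly, in days.
#'
#' @param name Clock label.
#' @param intercept Numeric intercept of the linear predictor.
#' @param weights Named numeric vector of per-CpG weights; names are CpG ids.
#' @param transform `"calibrated"` (log-linear age calibration inverted on
#'   output) or `"linear"` (predictor returned unchanged).
#' @param output_units `"years"` or `"days"`.
#' @param adult_age Anchor age (years) of the calibrated transform.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, weights,
                             transform = c("calibrated", "linear"),
                             output_units = c("years", "days"),
                             adult_age = 20) {
  transform <- match.arg(transform)
  output_units <- match.arg(output_units)
  if (length(weights) < 1L) stop_neoclocks("clock must have at least one CpG weight")
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop_neoclocks("'weights' must be uniquely named by CpG id")
  if (!all(is.finite(c(intercept, weights))))
    stop_neoclocks("clock coefficients must be finite")
  structure(list(name = name, intercept = unname(intercept), weights = weights,
                 transform = transform, output_units = output_units,
                 expected_n_cpgs = length(weights), adult_age = adult_age),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("clock '%s': %d CpGs, %s transform, output in %s\n",
              x$name, x$expected_n_cpgs, x$transform, x$output_units))
  invisible(x)
}

# Canonical cord-blood cell types, granulocytes and nucleated red blood
# cells included. Order is fixed across the package.
#' Blood cell types used for deconvolution
#' @export
CELL_TYPES <- c("B", "CD4T", "CD8T", "NK", "Mono", "Gran", "nRBC")

#' Construct a cell-type methylation reference
#'
#' Mean beta profiles of sorted blood cell populations over a set of
#' deconvolution CpGs. Rows are the seven cord-blood cell types, columns are
#' CpGs. Full row rank is required so that mixture proportions are
#' identifiable.
#'
#' @param mean_betas Numeric matrix, 7 cell types x CpGs, values in \[0, 1\],
#'   with rownames equal to [CELL_TYPES] and unique CpG colnames.
#' @return An object of class `cell_reference`.
#' @export
cell_reference <- function(mean_betas) {
  if (!is.matrix(mean_betas) || nrow(mean_betas) != length(CELL_TYPES))
    stop_neoclocks("reference must be a matrix with ", length(CELL_TYPES), " cell-type rows")
  if (is.null(rownames(mean_betas))) rownames(mean_betas) <- CELL_TYPES
  if (!setequal(rownames(mean_betas), CELL_TYPES))
    stop_neoclocks("reference rows must be the cell types: ",
                   paste(CELL_TYPES, collapse = ", "))
  mean_betas <- mean_betas[CELL_TYPES, , drop = FALSE]
  if (is.null(colnames(mean_betas)) || anyDuplicated(colnames(mean_betas)))
    stop_neoclocks("reference CpG ids (colnames) must be unique")
  if (anyNA(mean_betas) || min(mean_betas) < 0 || max(mean_betas) > 1)
    stop_neoclocks("reference mean betas must lie in [0, 1]")
  if (qr(mean_betas)$rank < nrow(mean_betas))
    stop_neoclocks("reference is rank-deficient: cell profiles are not ",
                   "linearly independent, proportions are unidentifiable")
  structure(list(mean_betas = mean_betas), class = "cell_reference")
}

#' @export
print.cell_reference <- function(x, ...) {
  cat(sprintf("cell_reference: %d cell types x %d CpGs\n",
              nrow(x$mean_betas), ncol(x$mean_betas)))
  invisible(x)
}
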