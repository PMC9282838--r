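#' Read and write beta matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column is
#' `cpg_id`, second `chromosome`, followed by one numeric column per sample.
#'
#' @param betas A [beta_matrix()].
#' @param path File path.
#' @return `read_betas` returns a [beta_matrix()]; `write_betas` returns
#'   `path` invisibly.
#' @export
write_betas <- function(betas, path) {
  chr <- if (is.null(betas$chromosome)) NA_character_ else
    unname(betas$chromosome)
  tab <- data.frame(cpg_id = cpg_ids(betas), chromosome = chr,
                    betas$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || names(tab)[1L] != "cpg_id" ||
      names(tab)[2L] != "chromosome")
    stop_neoclocks("malformed beta TSV (expect columns cpg_id, chromosome, ",
                   "then samples): ", path)
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(values) <- tab$cpg_id
  chr <- tab$chromosome
  if (all(is.na(chr))) chr <- NULL else names(chr) <- tab$cpg_id
  beta_matrix(values, chr)
}

#' Read and write sample sheets as CSV
#'
#' Required columns: `sample_id`, `ds` (logical), `sex`, `ga_days`,
#' `collection_age_days`, `chron_age_days`, `birthweight_g`, `batch`.
#' Optional: `all_status`, `gata1_status`, `gata1_vaf`, PC columns
#' (`pc1`, `pc2`, ...).
#'
#' @param sheet Sample-sheet `data.frame`.
#' @param path File path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ds", "sex", "ga_days", "collection_age_days",
            "chron_age_days", "birthweight_g", "batch")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols) > 0L)
    stop_neoclocks("sample sheet missing column(s): ",
                   paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_neoclocks("duplicate sample ids in sample sheet")
  sheet$ds <- as.logical(sheet$ds)
  sheet
}

#' Read and write bin-level log2 copy-ratio tables as CSV
#'
#' Columns: `sample_id`, `chromosome`, `bin_index`, `log2_ratio`.
#'
#' @param bins Bin-level `data.frame`.
#' @param path File path.
#' @export
write_bins <- function(bins, path) {
  write.csv(bins, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  bins <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "bin_index", "log2_ratio")
  if (!all(need %in% names(bins)))
    stop_neoclocks("malformed bin table (expect ",
                   paste(need, collapse = ", "), "): ", path)
  bins
}

#' Read and write a cell reference as long-format CSV
#'
#' Columns: `cell_type`, `cpg_id`, `mean_beta`.
#'
#' @param reference A [cell_reference()].
#' @param path File path.
#' @export
write_cell_reference <- function(reference, path) {
  m <- reference$mean_betas
  tab <- data.frame(cell_type = rep(rownames(m), times = ncol(m)),
                    cpg_id = rep(colnames(m), each = nrow(m)),
                    mean_beta = as.vector(m), stringsAsFactors = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_reference
#' @export
read_cell_reference <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "cpg_id", "mean_beta") %in% names(tab)))
    stop_neoclocks("malformed reference CSV (expect cell_type, cpg_id, ",
                   "mean_beta): ", path)
  cpgs <- unique(tab$cpg_id)
  m <- matrix(NA_real_, length(CELL_TYPES), length(cpgs),
              dimnames = list(CELL_TYPES, cpgs))
  m[cbind(match(tab$cell_type, CELL_TYPES), match(tab$cpg_id, cpgs))] <-
    tab$mean_beta
  if (anyNA(m)) stop_neoclocks("incomplete reference table: ", path)
  cell_reference(m)
}

#' Write a synthetic cohort (betas, sheet, bins, truth) to a directory
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_betas(cohort$betas, file.path(dir, "betas.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.csv"))
  write_bins(cohort$bins, file.path(dir, "bins.csv"))
  truth <- cohort$truth
  truth$epi_age <- as.data.frame(truth$epi_age)
  truth$cell_props <- as.data.frame(truth$cell_props)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Quality-control filtering of a beta matrix
#'
#' Filtering proceeds in a fixed order: (1) CpGs with mean detection
#' p-value above `detection_threshold` are removed (when a detection-p
#' matrix is supplied); (2) CpGs with missingness above
#' `missingness_threshold` are removed; (3) samples with missingness above
#' `missingness_threshold` (computed after CpG removal) are removed.
#'
#' @param betas A [beta_matrix()].
#' @param detection_p Optional numeric matrix of detection p-values aligned
#'   to `betas` (same dimnames).
#' @param detection_threshold Mean detection-p cutoff, default 0.01.
#' @param missingness_threshold Missing-fraction cutoff, default 0.15.
#' @return List with `betas` (filtered) and `report`, a `qc_report` with
#'   removal counts, the removed ids, and the thresholds used.
#' @export
qc_filter <- function(betas, detection_p = NULL, detection_threshold = 0.01,
                      missingness_threshold = 0.15) {
  values <- betas$values
  removed_det <- character()
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop_neoclocks("detection-p matrix not aligned to the beta matrix")
    if (!is.null(rownames(detection_p)) &&
        !identical(rownames(detection_p), rownames(values)))
      detection_p <- detection_p[rownames(values), colnames(values),
                                 drop = FALSE]
    removed_det <- rownames(values)[rowMeans(detection_p) >
                                      detection_threshold]
    values <- values[setdiff(rownames(values), removed_det), , drop = FALSE]
  }
  cpg_miss <- rowMeans(is.na(values))
  removed_cpg <- rownames(values)[cpg_miss > missingness_threshold]
  values <- values[setdiff(rownames(values), removed_cpg), , drop = FALSE]
  smp_miss <- colMeans(is.na(values))
  removed_smp <- colnames(values)[smp_miss > missingness_threshold]
  values <- values[, setdiff(colnames(values), removed_smp), drop = FALSE]
  if (ncol(values) == 0L)
    stop_neoclocks("QC removed every sample (missingness threshold ",
                   missingness_threshold, ")")
  if (nrow(values) == 0L)
    stop_neoclocks("QC removed every CpG")
  report <- structure(list(
    n_cpgs_removed_detection = length(removed_det),
    n_cpgs_removed_missingness = length(removed_cpg),
    n_samples_removed = length(removed_smp),
    removed_detection = removed_det, removed_cpgs = removed_cpg,
    removed_samples = removed_smp,
    thresholds = c(detection = detection_threshold,
                   missingness = missingness_threshold)),
    class = "qc_report")
  chr <- betas$chromosome
  if (!is.null(chr)) chr <- chr[rownames(values)]
  list(betas = beta_matrix(values, chr), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d CpGs removed by detection p > %.3g, ",
                     "%d CpGs and %d samples removed by missingness > %.3g\n"),
              x$n_cpgs_removed_detection, x$thresholds["detection"],
              x$n_cpgs_removed_missingness, x$n_samples_removed,
              x$thresholds["missingness"]))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles input locations (or in-memory objects), analysis thresholds and
#' the seed for the end-to-end driver [run_pipeline()]. The configuration
#' round-trips losslessly through YAML when all inputs are paths.
#'
#' @param betas,sheet,bins Paths or in-memory objects (a [beta_matrix()],
#'   sample-sheet `data.frame`, bin-level `data.frame`).
#' @param clocks Named list of [clock_definition()] objects, or of paths to
#'   coefficient CSVs (paths are loaded with default transform settings).
#' @param reference Optional [cell_reference()] or path to its CSV.
#' @param detection_p Optional detection-p matrix (in-memory only).
#' @param primary_clock Name of the clock driving the headline DS models;
#'   default the first clock with `output_units = "years"`.
#' @param detection_threshold,missingness_threshold,nrbc_threshold,full_t21_threshold,sd_mult,covariate_p
#'   Analysis thresholds (defaults 0.01, 0.15, 0.25, 0.2, 2, 0.2).
#' @param max_pcs Maximum ancestry PCs considered.
#' @param paper_slope Reporting-compatibility override: when non-`NULL`
#'   (e.g. `0.001`), day conversions use this rounded slope instead of the
#'   fitted reference slope.
#' @param seed Integer seed.
#' @param out_dir Optional directory for stage outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(betas, sheet, bins = NULL, clocks, reference = NULL,
                            detection_p = NULL, primary_clock = NULL,
                            detection_threshold = 0.01,
                            missingness_threshold = 0.15,
                            nrbc_threshold = 0.25, full_t21_threshold = 0.2,
                            sd_mult = 2, covariate_p = 0.2, max_pcs = 10,
                            paper_slope = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(detection_threshold > 0, detection_threshold < 1,
            missingness_threshold > 0, missingness_threshold < 1,
            nrbc_threshold > 0, nrbc_threshold < 1, sd_mult > 0,
            covariate_p > 0, covariate_p <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' Only path-valued inputs and scalar settings are serialized; in-memory
#' objects are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- lapply(config, function(x) {
    if (is.list(x) && !is.null(names(x)) && all(vapply(x, is.character, TRUE)))
      return(x)
    x
  })
  obj <- vapply(flat, function(x)
    !(is.null(x) || is.character(x) || is.numeric(x) || is.logical(x) ||
        (is.list(x) && all(vapply(x, is.character, TRUE)))), TRUE)
  if (any(obj))
    stop_neoclocks("cannot serialize in-memory objects: ",
                   paste(names(flat)[obj], collapse = ", "))
  yaml::write_yaml(flat[!vapply(flat, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
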