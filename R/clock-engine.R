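#' Read a clock coefficient file
#'
#' Coefficient files are two-column CSVs with header `cpg_id,weight` and
#' exactly one intercept row whose id is the reserved label `"(Intercept)"`.
#'
#' @param path Path to the CSV file.
#' @param name Clock label; defaults to the file name without extension.
#' @inheritParams clock_definition
#' @return A [clock_definition()].
#' @export
load_clock <- function(path, name = NULL,
                       transform = c("calibrated", "linear"),
                       output_units = c("years", "days"), adult_age = 20) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cpg_id", "weight") %in% names(tab)))
    stop_neoclocks("clock file must have columns 'cpg_id' and 'weight': ", path)
  if (!is.numeric(tab$weight))
    stop_neoclocks("non-numeric weight column in ", path)
  is_int <- tab$cpg_id == "(Intercept)"
  if (sum(is_int) != 1L)
    stop_neoclocks("clock file must contain exactly one '(Intercept)' row: ", path)
  cpgs <- tab$cpg_id[!is_int]
  if (anyDuplicated(cpgs))
    stop_neoclocks("duplicate CpG ids in clock file: ",
                   paste(unique(cpgs[duplicated(cpgs)]), collapse = ", "))
  weights <- tab$weight[!is_int]
  names(weights) <- cpgs
  clock_definition(name %||% sub("\\.[^.]+$", "", basename(path)),
                   intercept = tab$weight[is_int], weights = weights,
                   transform = transform, output_units = output_units,
                   adult_age = adult_age)
}

#' Write a clock coefficient file
#' @param clock A [clock_definition()].
#' @param path Output CSV path.
#' @export
write_clock <- function(clock, path) {
  tab <- data.frame(cpg_id = c("(Intercept)", names(clock$weights)),
                    weight = c(clock$intercept, unname(clock$weights)))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute missing clock CpGs by the per-sample mean of available clock CpGs
#'
#' Clock CpGs absent from the array (or with missing entries in individual
#' samples) are replaced, per sample, by the mean beta over that sample's
#' available clock CpGs. Non-clock CpGs are untouched. This is the standard
#' fallback when a clock trained on one array platform is applied to
#' another that lacks some of its probes.
#'
#' @param betas A [beta_matrix()].
#' @param clock A [clock_definition()].
#' @return A `beta_matrix` in which every clock CpG has a value for every
#'   sample, with attribute `n_imputed_cpgs` (number of clock CpGs that were
#'   absent from the input matrix).
#' @export
impute_missing_clock_cpgs <- function(betas, clock) {
  need <- names(clock$weights)
  have <- intersect(need, cpg_ids(betas))
  absent <- setdiff(need, have)
  if (length(have) == 0L)
    stop_neoclocks("no clock CpGs present in the beta matrix for clock '",
                   clock$name, "'")
  sub <- betas$values[have, , drop = FALSE]
  n_avail <- colSums(!is.na(sub))
  if (any(n_avail == 0L))
    stop_neoclocks("sample(s) with zero available clock CpGs, cannot impute: ",
                   paste(colnames(sub)[n_avail == 0L], collapse = ", "))
  sample_means <- colMeans(sub, na.rm = TRUE)

  values <- betas$values
  # fill per-sample NA entries among present clock CpGs
  na_idx <- which(is.na(sub), arr.ind = TRUE)
  if (nrow(na_idx) > 0L)
    values[cbind(match(have, rownames(values))[na_idx[, 1L]], na_idx[, 2L])] <-
      sample_means[na_idx[, 2L]]
  # append rows for clock CpGs absent from the matrix
  if (length(absent) > 0L) {
    add <- matrix(rep(sample_means, each = length(absent)),
                  nrow = length(absent),
                  dimnames = list(absent, colnames(values)))
    values <- rbind(values, add)
  }
  chromosome <- betas$chromosome
  if (!is.null(chromosome) && length(absent) > 0L) {
    extra <- rep(NA_character_, length(absent))
    names(extra) <- absent
    chromosome <- c(chromosome, extra)
  }
  out <- beta_matrix(values, chromosome)
  attr(out, "n_imputed_cpgs") <- length(absent)
  out
}

#' Calibrated age transform and its inverse
#'
#' Age clocks trained with the standard log-linear age calibration produce a
#' linear predictor `x` that is mapped back to years by an anti-transform
#' that is exponential below the anchor age and linear above it:
#' `x < 0 -> (1 + adult_age) * exp(x) - 1`, `x >= 0 -> (1 + adult_age) * x +
#' adult_age`. The map is continuous and strictly increasing, with fixed
#' point `adult_age` at `x = 0`.
#'
#' @param x Linear-predictor value(s).
#' @param adult_age Anchor age in years (default 20).
#' @return Age in years (`inverse_age_transform`) or the linear predictor
#'   (`forward_age_transform`).
#' @export
inverse_age_transform <- function(x, adult_age = 20) {
  ifelse(x < 0, (1 + adult_age) * exp(x) - 1, (1 + adult_age) * x + adult_age)
}

#' @rdname inverse_age_transform
#' @param age Age(s) in years, greater than -1.
#' @export
forward_age_transform <- function(age, adult_age = 20) {
  ifelse(age < adult_age,
         log((age + 1) / (1 + adult_age)),
         (age - adult_age) / (1 + adult_age))
}

#' Compute a clock over a beta matrix
#'
#' Per sample, forms the linear predictor `intercept + sum_j w_j * beta_j`
#' over the clock's CpGs and applies the clock's output transform
#' (calibrated anti-transform for adult-calibrated age clocks; identity for
#' gestational clocks, whose predictor is already in days).
#'
#' The beta matrix must already contain a value for every clock CpG in every
#' sample — run [impute_missing_clock_cpgs()] first.
#'
#' @param betas A [beta_matrix()] imputed for this clock.
#' @param clock A [clock_definition()].
#' @return An object of class `clock_values`: list with `values` (named
#'   numeric, one per sample, in `clock$output_units`), `clock_name`,
#'   `units`, `n_imputed_cpgs` (carried from imputation when available) and
#'   `excluded_cpgs`.
#' @export
compute_clock <- function(betas, clock) {
  need <- names(clock$weights)
  missing_cpgs <- setdiff(need, cpg_ids(betas))
  if (length(missing_cpgs) > 0L)
    stop_neoclocks("unimputed clock CpGs for clock '", clock$name, "': ",
                   paste(utils::head(missing_cpgs, 5L), collapse = ", "),
                   if (length(missing_cpgs) > 5L) ", ...")
  sub <- betas$values[need, , drop = FALSE]
  if (anyNA(sub))
    stop_neoclocks("NA beta values among clock CpGs; impute first (clock '",
                   clock$name, "')")
  lp <- drop(crossprod(sub, clock$weights)) + clock$intercept
  values <- switch(clock$transform,
                   calibrated = inverse_age_transform(lp, clock$adult_age),
                   linear = lp)
  names(values) <- colnames(sub)
  structure(list(values = values, clock_name = clock$name,
                 units = clock$output_units,
                 n_imputed_cpgs = attr(betas, "n_imputed_cpgs") %||% 0L,
                 excluded_cpgs = attr(clock, "excluded_cpgs") %||% character()),
            class = "clock_values")
}

#' @export
print.clock_values <- function(x, ...) {
  cat(sprintf("clock_values '%s' (%s): n = %d, mean = %.4g\n",
              x$clock_name, x$units, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.clock_values <- function(x, ...) {
  data.frame(sample_id = names(x$values), clock_name = x$clock_name,
             value = unname(x$values), stringsAsFactors = FALSE)
}

#' Drop CpGs from a clock (sensitivity variants)
#'
#' Builds the CpG-excluded clock variants used in sensitivity analyses —
#' e.g. dropping CpGs on the trisomic chromosome 21, or CpGs shared with the
#' cell-deconvolution reference. Excluded CpGs are removed from the weight
#' map entirely (not imputed), so the restricted clock never reads them.
#'
#' @param clock A [clock_definition()].
#' @param exclude_cpgs CpG ids to drop.
#' @param exclude_chr Chromosome label(s) whose CpGs are dropped; requires
#'   `betas` with chromosome annotation.
#' @param betas Optional [beta_matrix()] supplying the chromosome lookup.
#' @param suffix Name suffix marking the variant.
#' @return A `clock_definition` with the surviving weights, its name
#'   suffixed, and attribute `excluded_cpgs` recording what was dropped.
#' @export
restrict_clock <- function(clock, exclude_cpgs = character(),
                           exclude_chr = NULL, betas = NULL,
                           suffix = "_restricted") {
  exclude <- as.character(exclude_cpgs)
  if (!is.null(exclude_chr)) {
    if (is.null(betas))
      stop_neoclocks("excluding by chromosome requires 'betas' with annotation")
    exclude <- union(exclude, cpgs_on_chromosome(betas, exclude_chr))
  }
  if (length(exclude) == 0L)
    stop_neoclocks("empty exclusion set")
  hit <- intersect(exclude, names(clock$weights))
  if (length(hit) == 0L) {
    warning("no excluded CpGs are in clock '", clock$name, "'; clock unchanged")
    return(clock)
  }
  keep <- setdiff(names(clock$weights), hit)
  if (length(keep) == 0L)
    stop_neoclocks("exclusion removes every CpG of clock '", clock$name, "'")
  out <- clock_definition(paste0(clock$name, suffix), clock$intercept,
                          clock$weights[keep], transform = clock$transform,
                          output_units = clock$output_units,
                          adult_age = clock$adult_age)
  attr(out, "excluded_cpgs") <- hit
  out
}

#' CpGs shared between a clock and a deconvolution reference
#'
#' @param clock A [clock_definition()].
#' @param reference A [cell_reference()].
#' @return CpG ids present in both the clock and the reference.
#' @export
clock_reference_overlap <- function(clock, reference) {
  intersect(names(clock$weights), colnames(reference$mean_betas))
}
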