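# Shared builders for small in-code fixtures.

tiny_betas <- function() {
  v <- matrix(c(0.2, 0.4, 0.6,
                0.3, 0.5, 0.7,
                0.1, 0.9, 0.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2", "s3")))
  beta_matrix(v, c(cg1 = "chr1", cg2 = "chr21", cg3 = "chr2"))
}

# default clocks / reference used by several test files
default_fixtures <- function(n_clock = 30, n_ref = 30, n_ga = 20) {
  list(
    clock = generate_synthetic_clock(n_clock, "calibrated", seed = 11,
                                     output_units = "years",
                                     name = "ageclock"),
    linclock = generate_synthetic_clock(n_clock, "linear", seed = 12,
                                        output_units = "years",
                                        cpg_prefix = "cgLIN",
                                        name = "linclock"),
    gaclock = generate_synthetic_clock(n_ga, "linear", seed = 13,
                                       output_units = "days",
                                       cpg_prefix = "cgGA", name = "gaclock"),
    reference = generate_cell_reference(n_ref, seed = 14))
}

# integer compositions of n into k nonnegative parts (rows)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(0:n, function(i)
    cbind(i, compositions(n - i, k - 1L))))
}

# Exhaustive simplex grid search oracle for deconvolution.
# Enumerates all proportion vectors on the given grid: every support of
# size <= max_support at the fine step, plus (optionally) the full
# 7-dimensional simplex at coarse_step. Returns the grid point minimizing
# the least-squares objective against the reference mixture.
grid_simplex_oracle <- function(beta, ref_mat, step = 0.01,
                                max_support = 3L, coarse_step = 0.05) {
  d <- nrow(ref_mat)
  N <- round(1 / step)
  cand <- list()
  for (s in 1:max_support) {
    comps <- compositions(N, s) / N
    for (sup in utils::combn(d, s, simplify = FALSE)) {
      W <- matrix(0, nrow(comps), d)
      W[, sup] <- comps
      cand[[length(cand) + 1L]] <- W
    }
  }
  if (!is.null(coarse_step)) {
    Nc <- round(1 / coarse_step)
    cand[[length(cand) + 1L]] <- compositions(Nc, d) / Nc
  }
  W <- do.call(rbind, cand)
  err <- rowSums((W %*% ref_mat - matrix(beta, nrow(W), length(beta),
                                         byrow = TRUE))^2)
  W[which.min(err), ]
}

published_estimates <- function() {
  read.csv(system.file("extdata", "published_estimates.csv",
                       package = "neoclocks"), stringsAsFactors = FALSE)
}
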