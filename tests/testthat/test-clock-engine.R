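test_that("clock coefficient files round-trip and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cpg_id,weight", "(Intercept),0.5", "cg1,0.2", "cg2,-0.1"),
             path)
  cl <- load_clock(path, name = "toy", transform = "linear")
  expect_equal(cl$intercept, 0.5)
  expect_equal(cl$weights, c(cg1 = 0.2, cg2 = -0.1))
  expect_equal(cl$expected_n_cpgs, 2L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_clock(cl, out)
  back <- load_clock(out, name = "toy", transform = "linear")
  expect_equal(back$weights, cl$weights)
  expect_equal(back$intercept, cl$intercept)

  writeLines(c("cpg_id,weight", "(Intercept),0.5", "cg1,0.2", "cg1,0.3"),
             path)
  expect_error(load_clock(path), "duplicate")
  writeLines(c("cpg_id,weight", "cg1,0.2"), path)
  expect_error(load_clock(path), "Intercept")
  writeLines(c("cpg_id,weight", "(Intercept),0.5", "cg1,abc"), path)
  expect_error(load_clock(path), "numeric")
})

test_that("missing clock CpGs are imputed with the per-sample mean of available ones", {
  cl <- clock_definition("c", 0, c(cg1 = 1, cg2 = 1, cg9 = 1),
                         transform = "linear")
  b <- tiny_betas()  # has cg1, cg2, cg3; cg9 absent
  imp <- impute_missing_clock_cpgs(b, cl)
  # per sample mean of cg1, cg2
  expect_equal(imp$values["cg9", ], colMeans(b$values[c("cg1", "cg2"), ]))
  expect_equal(attr(imp, "n_imputed_cpgs"), 1L)
  # non-clock CpGs untouched, present clock CpGs untouched
  expect_equal(imp$values[c("cg1", "cg2", "cg3"), ],
               b$values[c("cg1", "cg2", "cg3"), ])

  # per-sample NA entry among present CpGs is filled with that sample's mean
  v <- b$values
  v["cg2", "s1"] <- NA
  b2 <- beta_matrix(v, b$chromosome)
  imp2 <- impute_missing_clock_cpgs(b2, cl)
  expect_equal(unname(imp2$values["cg2", "s1"]), unname(v["cg1", "s1"]))

  # nothing missing -> identity
  cl2 <- clock_definition("c2", 0, c(cg1 = 1, cg2 = 1), transform = "linear")
  expect_identical(impute_missing_clock_cpgs(b, cl2)$values, b$values)

  # no clock CpG present at all -> informative error
  cl3 <- clock_definition("c3", 0, c(cgZ = 1), transform = "linear")
  expect_error(impute_missing_clock_cpgs(b, cl3), "no clock CpGs")
})

test_that("the calibrated anti-transform is exact, continuous and monotone", {
  expect_equal(inverse_age_transform(0), 20)
  # analytic inversion: (1 + 20) * exp(x) - 1 = -0.40  =>  x = log(0.6/21)
  expect_equal(inverse_age_transform(log(0.6 / 21)), -0.40, tolerance = 1e-12)
  expect_equal(inverse_age_transform(-3.5553), -0.40, tolerance = 1e-3)
  # continuity at the calibration knot
  eps <- 1e-10
  expect_equal(inverse_age_transform(-eps), inverse_age_transform(eps),
               tolerance = 1e-8)
  # strict monotonicity over random predictors
  set.seed(1)
  x <- sort(runif(200, -6, 4))
  expect_true(all(diff(inverse_age_transform(x)) > 0))
  # forward transform is the exact inverse on both branches
  age <- c(-0.9, 0, 3, 19.9, 20, 35)
  expect_equal(inverse_age_transform(forward_age_transform(age)), age,
               tolerance = 1e-12)
})

test_that("compute_clock applies the weighted combination and transform", {
  # all-zero betas with calibrated transform -> anti-transform of intercept
  cal <- clock_definition("cal", intercept = -2,
                          weights = c(cg1 = 1, cg2 = -1),
                          transform = "calibrated")
  bm <- beta_matrix(matrix(0, 2, 2, dimnames = list(c("cg1", "cg2"),
                                                    c("s1", "s2"))))
  expect_equal(unname(compute_clock(bm, cal)$values),
               rep(inverse_age_transform(-2), 2))

  # unimputed CpG -> precondition error
  b <- tiny_betas()
  clz <- clock_definition("z", 0, c(cg1 = 1, cgZ = 1), transform = "linear")
  expect_error(compute_clock(b, clz), "unimputed")

  # linearity for identity transform: convex combinations commute
  cl <- generate_synthetic_clock(8, "linear", seed = 21)
  set.seed(22)
  v <- matrix(runif(16), 8, 2,
              dimnames = list(names(cl$weights), c("a", "b")))
  lam <- 0.3
  mix <- beta_matrix(matrix(lam * v[, 1] + (1 - lam) * v[, 2],
                            dimnames = list(rownames(v), "mix")))
  out <- compute_clock(beta_matrix(v), cl)$values
  expect_equal(unname(compute_clock(mix, cl)$values),
               unname(lam * out["a"] + (1 - lam) * out["b"]),
               tolerance = 1e-12)
})

test_that("imputation is neutral when the missing beta equals the clock-CpG mean", {
  cl <- clock_definition("c", 0.2, c(cg1 = 0.7, cg2 = -0.3, cg3 = 0.4),
                         transform = "linear")
  v <- matrix(c(0.2, 0.4, 0.3), 3, 1, dimnames = list(paste0("cg", 1:3), "s"))
  full <- compute_clock(beta_matrix(v), cl)
  v2 <- v[1:2, , drop = FALSE]  # cg3 missing; its true beta equals mean(cg1,cg2)
  imp <- impute_missing_clock_cpgs(beta_matrix(v2), cl)
  expect_equal(compute_clock(imp, cl)$values, full$values, tolerance = 1e-12)
})

test_that("clock restriction drops CpGs without ever reading them", {
  cal <- generate_synthetic_clock(391, "calibrated", seed = 31)
  ten <- names(cal$weights)[1:10]
  r <- restrict_clock(cal, exclude_cpgs = ten, suffix = "_noDeconv")
  expect_equal(r$expected_n_cpgs, 381L)
  expect_false(any(ten %in% names(r$weights)))
  expect_match(r$name, "_noDeconv$")
  expect_equal(attr(r, "excluded_cpgs"), ten)

  # excluding a CpG not in the clock leaves it unchanged, with a warning
  expect_warning(same <- restrict_clock(cal, exclude_cpgs = "cgNOPE"),
                 "unchanged")
  expect_identical(same$weights, cal$weights)

  # emptying the clock errors
  expect_error(restrict_clock(cal, exclude_cpgs = names(cal$weights)),
               "every CpG")

  # access tracking: corrupt the excluded CpGs; restricted output unchanged
  b <- embed_age_signal(cal, c(s1 = 0.1, s2 = 0.6))
  bm_clean <- impute_missing_clock_cpgs(beta_matrix(b), r)
  v_bad <- b
  v_bad[ten, ] <- 0.999
  bm_bad <- impute_missing_clock_cpgs(beta_matrix(v_bad), r)
  expect_identical(compute_clock(bm_clean, r)$values,
                   compute_clock(bm_bad, r)$values)

  # chromosome-based exclusion uses the annotation
  chr <- rep("chr5", 391)
  chr[1:7] <- "chr21"
  names(chr) <- names(cal$weights)
  bm_chr <- beta_matrix(b, chr)
  r21 <- restrict_clock(cal, exclude_chr = "chr21", betas = bm_chr,
                        suffix = "_noChr21")
  expect_equal(r21$expected_n_cpgs, 384L)
  expect_error(restrict_clock(cal, exclude_chr = "chr21"), "annotation")
  expect_error(restrict_clock(cal), "empty exclusion")
})

test_that("clock/reference CpG overlap is computed from the loaded objects", {
  ref <- generate_cell_reference(20, seed = 41)
  w <- rep(1, 15)
  names(w) <- c(colnames(ref$mean_betas)[1:10], paste0("cgU", 1:5))
  cl <- clock_definition("c", 0, w, transform = "linear")
  expect_equal(clock_reference_overlap(cl, ref),
               colnames(ref$mean_betas)[1:10])
})
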