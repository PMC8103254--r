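test_that("degenerate and perfectly correlated inputs behave as documented", {
  set.seed(4)
  dens <- matrix(rexp(30) + 0.5, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  # constant empty densities: corr 0 with a warning
  emp_const <- matrix(1, 10, 3, dimnames = dimnames(dens))
  expect_warning(m0 <- fit_empty_room_model(dens, emp_const), "zero variance")
  expect_equal(m0$corr, rep(0, 3))
  expect_equal(m0$n_pairs, rep(10L, 3))
  # empty equal to subject densities: corr 1, correction zeroes everything
  m1 <- fit_empty_room_model(dens, dens)
  expect_equal(m1$corr, rep(1, 3), tolerance = 1e-12)
  corrected <- correct_density(dens, dens, m1)
  expect_equal(unname(corrected), matrix(0, 10, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_empty_room_model(dens, dens[1:5, ]), "identical shape")
  expect_error(fit_empty_room_model(dens[1:2, ], dens[1:2, ]), "at least 3")
})

test_that("correction matches the hand-computed case and flags negatives", {
  model <- structure(data.frame(region_id = "a", corr = 0.4, n_pairs = 10L),
                     class = c("empty_room_model", "data.frame"))
  out <- correct_density(c(a = 2.0), c(a = 1.5), model)
  expect_equal(unname(out["a"]), 2.0 - 0.4 * 1.5)   # = 1.4
  out_neg <- correct_density(c(a = 0.1), c(a = 1.5), model)
  expect_lt(unname(out_neg["a"]), 0)
  expect_equal(attr(out_neg, "n_negative"), 1L)
  # missing paired empty-room densities are an error
  expect_error(correct_density(c(a = 2), c(b = 1), model), "mismatched")
})

test_that("zero correlation leaves densities untouched", {
  set.seed(5)
  dens <- matrix(rexp(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  emp <- matrix(rexp(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  model <- structure(data.frame(region_id = c("a", "b"), corr = 0, n_pairs = 10L),
                     class = c("empty_room_model", "data.frame"))
  expect_equal(correct_density(dens, emp, model), dens, ignore_attr = TRUE)
})

test_that("equal-variance correction is the regression residual: corrected
          densities decorrelate from the empty room", {
  # Construct paired densities with exactly equal variances per region so
  # corr * rho_empty equals the regression coefficient in expectation.
  set.seed(6)
  n <- 600
  n_reg <- 20
  r <- matrix(NA_real_, 1, n_reg)
  emp <- matrix(rnorm(n * n_reg, 1, 0.2), n, n_reg,
                dimnames = list(NULL, paste0("g", seq_len(n_reg))))
  alpha <- 0.6
  subj <- alpha * emp + sqrt(1 - alpha^2) *
    matrix(rnorm(n * n_reg, 0, 0.2), n, n_reg)
  colnames(subj) <- colnames(emp)
  model <- fit_empty_room_model(subj, emp)
  expect_gt(min(model$corr), 0.4)
  corrected <- correct_density(subj, emp, model)
  resid_cor <- sapply(seq_len(n_reg), function(j) cor(corrected[, j], emp[, j]))
  expect_lt(max(abs(resid_cor)), 0.05)
})

test_that("a second correction pass changes densities negligibly", {
  set.seed(7)
  n <- 400
  emp <- matrix(rnorm(n * 5, 1, 0.3), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  subj <- 0.5 * emp + matrix(rnorm(n * 5, 1, 0.3), n, 5)
  colnames(subj) <- colnames(emp)
  m1 <- fit_empty_room_model(subj, emp)
  c1 <- correct_density(subj, emp, m1)
  m2 <- fit_empty_room_model(unclass(c1), emp)
  expect_lt(max(abs(m2$corr)), 0.06)
  c2 <- correct_density(unclass(c1), emp, m2)
  expect_lt(max(abs(c2 - c1)), 0.06 * max(abs(emp)))
})

test_that("synthetic cohorts with dark counts show positive empty-room
          correlations", {
  table <- tiny_table()
  spec <- quick_spec(n_subjects_norm = 200L, n_subjects_clin = 0L,
                     followup_fraction = 0, dark_fraction = 0.1,
                     session_quality_sd = 0.3, total_count_mean = 5e4,
                     conditions = c("rest", "empty_room"), seed = 55L)
  coh <- generate_cohort(spec, table)
  subj <- compute_density(counts_matrix(coh, "baseline", "rest"), table)
  emp <- compute_density(counts_matrix(coh, "baseline", "empty_room"), table)
  model <- fit_empty_room_model(subj, emp)
  part <- partition_regions(table)
  corr <- model$corr[match(part, model$region_id)]
  # positive in most regions, and jointly well above chance
  expect_gt(mean(corr > 0), 0.75)
  expect_gt(mean(corr), 2 / sqrt(200))
})

test_that("empty-room model files round-trip", {
  model <- structure(data.frame(region_id = c("a", "b"), corr = c(0.25, -0.1),
                                n_pairs = 12L, stringsAsFactors = FALSE),
                     class = c("empty_room_model", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_empty_room_model(model, f)
  expect_equal(as.data.frame(read_empty_room_model(f)), as.data.frame(model))
})
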