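test_that("generation is reproducible and satisfies the count invariant", {
  spec <- quick_spec()
  table <- tiny_table()
  c1 <- generate_cohort(spec, table)
  c2 <- generate_cohort(spec, table)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$subjects, c2$subjects)
  expect_false(identical(generate_cohort(quick_spec(seed = 12L), table)$counts,
                         c1$counts))
  part <- partition_regions(table)
  expect_identical(as.integer(rowSums(c1$counts[, part])),
                   c1$recordings$count_total)
  expect_true(all(c1$counts >= 0))
  # every subject has a baseline rest and same-day empty-room recording
  rec <- c1$recordings
  for (s in c1$subjects$subject_id) {
    expect_true(paste(s, "baseline", "rest", sep = ":") %in% rec$recording_id)
    expect_true(paste(s, "baseline", "empty_room", sep = ":") %in% rec$recording_id)
  }
})

test_that("zero dark fraction yields silent empty rooms and an identity correction", {
  spec <- quick_spec(dark_fraction = 0, session_quality_sd = 0, dark_latent_sd = 0)
  table <- tiny_table()
  coh <- generate_cohort(spec, table)
  rec <- coh$recordings
  empty <- coh$counts[rec$condition == "empty_room", , drop = FALSE]
  expect_true(all(empty == 0))
  # with all-zero empty rooms every region is degenerate: corr 0, no correction
  subj <- counts_matrix(coh, "baseline", "rest")
  dens <- compute_density(subj, table)
  emp_dens <- matrix(0, nrow(dens), ncol(dens), dimnames = dimnames(dens))
  expect_warning(model <- fit_empty_room_model(dens, emp_dens), "zero variance")
  corrected <- correct_density(dens, emp_dens, model)
  expect_equal(corrected, dens, ignore_attr = TRUE)
})

test_that("survey prevalence matches the spec within binomial error", {
  spec <- quick_spec(n_subjects_norm = 0L, n_subjects_clin = 400L,
                     followup_fraction = 0, conditions = "rest",
                     total_count_mean = 1e3, seed = 21L)
  coh <- generate_cohort(spec, tiny_table())
  st <- dichotomize_scores(coh$subjects)
  for (k in seq_along(spec$symptom_defs)) {
    def <- spec$symptom_defs[[k]]
    rate <- mean(st[[def$name]] == "positive")
    se <- sqrt(def$prevalence * (1 - def$prevalence) / 400)
    expect_lt(abs(rate - def$prevalence), 4 * se)
  }
})

test_that("planted symptom effects move the affected region's densities", {
  spec <- quick_spec(n_subjects_norm = 0L, n_subjects_clin = 150L,
                     followup_fraction = 0, conditions = "rest",
                     total_count_mean = 5e4, seed = 31L,
                     symptom_defs = list(list(
                       name = "insomnia", prevalence = 0.5, cutoff = 15L,
                       effects = c(L_sub = 1.6))))
  table <- tiny_table()
  coh <- generate_cohort(spec, table)
  st <- dichotomize_scores(coh$subjects, cutoffs = c(insomnia = 15L))
  dens <- compute_density(counts_matrix(coh, "baseline", "rest"), table)
  pos <- st$insomnia[match(rownames(dens), st$subject_id)] == "positive"
  tt <- t.test(dens[pos, "L_sub"], dens[!pos, "L_sub"])
  expect_gt(mean(dens[pos, "L_sub"]), mean(dens[!pos, "L_sub"]))
  expect_lt(tt$p.value, 0.01)
})

test_that("score dichotomization uses score >= cutoff with explicit missing", {
  subjects <- data.frame(subject_id = c("a", "b", "c"),
                         insomnia = c(15L, 14L, NA),
                         depression = c(70L, 62L, 63L))
  st <- dichotomize_scores(subjects, cutoffs = c(insomnia = 15L, depression = 63L))
  expect_equal(as.character(st$insomnia), c("positive", "negative", "missing"))
  expect_equal(as.character(st$depression), c("positive", "negative", "positive"))
  expect_error(dichotomize_scores(subjects, cutoffs = c(anxiety = 63L)),
               "anxiety")
})

test_that("cohorts round-trip through TSV files", {
  spec <- quick_spec(n_subjects_norm = 5L, n_subjects_clin = 4L,
                     total_count_mean = 2e3)
  table <- tiny_table()
  coh <- generate_cohort(spec, table)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, table)
  expect_identical(back$counts, coh$counts[rownames(back$counts), ])
  expect_equal(back$subjects, coh$subjects)
  expect_identical(back$recordings$count_total, coh$recordings$count_total)

  # malformed counts are named by row
  bad <- readLines(file.path(dir, "counts.tsv"))
  bad[3] <- sub("\t[0-9]+$", "\t-4", bad[3])
  writeLines(bad, file.path(dir, "counts.tsv"))
  expect_error(read_cohort(dir, table), "malformed count")
})

test_that("an empty cohort writes and reads back empty", {
  spec <- quick_spec(n_subjects_norm = 0L, n_subjects_clin = 0L)
  coh <- generate_cohort(spec, tiny_table())
  expect_equal(nrow(coh$recordings), 0)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, tiny_table())
  expect_equal(nrow(back$subjects), 0)
  expect_equal(nrow(back$counts), 0)
})

test_that("cohort specs round-trip through YAML and reject unknown keys", {
  spec <- quick_spec(dark_fraction = 0.08, retest_rho = 0.6)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, f)
  back <- read_cohort_spec(f)
  expect_equal(unclass(back), unclass(spec))
  # generation from the re-read spec is identical
  expect_identical(generate_cohort(back, tiny_table())$counts,
                   generate_cohort(spec, tiny_table())$counts)
  writeLines("bogus_knob: 3", f)
  expect_error(read_cohort_spec(f), "invalid cohort spec key")
})

test_that("follow-up latents track baseline at the requested stability", {
  # With retest_rho = 1 the latent is identical across sessions, so paired
  # densities correlate near 1; with retest_rho = 0 they do not.
  table <- tiny_table()
  for (rho in c(1, 0)) {
    spec <- quick_spec(n_subjects_norm = 120L, n_subjects_clin = 0L,
                       followup_fraction = 1, retest_rho = rho,
                       dark_fraction = 0, dark_latent_sd = 0,
                       total_count_mean = 1e5,
                       conditions = c("rest", "empty_room"), seed = 41L)
    coh <- generate_cohort(spec, table)
    d1 <- compute_density(counts_matrix(coh, "baseline", "rest"), table)
    d2 <- compute_density(counts_matrix(coh, "followup", "rest"), table)
    r <- median(sapply(partition_regions(table),
                       function(j) cor(d1[, j], d2[, j])))
    if (rho == 1) expect_gt(r, 0.9) else expect_lt(abs(r), 0.3)
  }
})
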