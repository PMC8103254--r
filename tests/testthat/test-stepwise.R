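# Helpers for building small labelled z-matrices with one planted region.
make_groups <- function(n_per_group, p, effect_region = NULL, delta = 0,
                        seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("r", seq_len(p))))
  lab <- factor(rep(c("neg", "pos"), each = n_per_group),
                levels = c("neg", "pos"))
  if (!is.null(effect_region)) {
    X[lab == "pos", effect_region] <- X[lab == "pos", effect_region] + delta
  }
  list(X = X, lab = lab)
}

test_that("exact binomial tail matches enumeration of coin sequences", {
  # independent oracle: count heads over every one of the 2^n sequences
  enum_tail <- function(correct, n, strict = TRUE) {
    x <- 0:(2^n - 1)
    heads <- integer(length(x))
    for (b in 0:(n - 1)) heads <- heads + bitwAnd(bitwShiftR(x, b), 1L)
    if (strict) mean(heads > correct) else mean(heads >= correct)
  }
  for (n in c(4, 7, 12)) {
    for (k in 0:n) {
      expect_equal(binomial_exceedance_p(k, n), enum_tail(k, n),
                   tolerance = 1e-12)
      expect_equal(binomial_exceedance_p(k, n, convention = "at_least"),
                   enum_tail(k, n, strict = FALSE), tolerance = 1e-12)
    }
  }
  expect_equal(binomial_exceedance_p(3, 4), 1 / 16)   # 1 seq of 4 heads
  expect_identical(binomial_exceedance_p(10, 10), 0)  # empty strict tail
  expect_equal(binomial_exceedance_p(10, 10, convention = "at_least"), 0.5^10)
})

test_that("log-space summation holds up in extreme tails", {
  # reference: pbinom, itself accurate in these ranges
  for (case in list(c(42, 54), c(57, 70), c(581, 619), c(48, 62))) {
    expect_equal(binomial_exceedance_p(case[1], case[2]),
                 pbinom(case[1], case[2], 0.5, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # representable far below any naive product of term probabilities
  expect_gt(binomial_exceedance_p(581, 619), 0)
  expect_lt(binomial_exceedance_p(581, 619), 1e-120)
})

test_that("a strongly planted region enters first and Wilks is monotone", {
  g <- make_groups(60, 30, effect_region = "r7", delta = 1.5, seed = 3)
  model <- stepwise_lda(g$X, g$lab)
  expect_equal(model$selected_regions[1], "r7")
  expect_equal(unname(model$signs["r7"]), "+")
  expect_true(all(diff(model$wilks) <= 1e-12))
  expect_true(all(model$wilks > 0 & model$wilks < 1))
  # Wilks' lambda after the selected entries equals 1 - R^2 of the group
  # indicator regressed on the selected set (two-group identity)
  fit <- lm(as.numeric(g$lab == "pos") ~ g$X[, model$selected_regions])
  expect_equal(tail(model$wilks, 1), 1 - summary(fit)$r.squared,
               tolerance = 1e-10)
})

test_that("entry F agrees with the regression partial F", {
  g <- make_groups(40, 6, effect_region = "r2", delta = 1, seed = 9)
  cfg <- stepwise_config(f_to_enter = 3.84, f_to_remove = 2.71)
  model <- stepwise_lda(g$X, g$lab, cfg)
  sel <- model$selected_regions
  expect_gte(length(sel), 1)
  # refit drop-one F for the last entered variable against anova()
  y <- as.numeric(g$lab == "pos")
  full <- lm(y ~ g$X[, sel, drop = FALSE])
  reduced <- if (length(sel) > 1) {
    lm(y ~ g$X[, sel[-length(sel)], drop = FALSE])
  } else {
    lm(y ~ 1)
  }
  f_ref <- anova(reduced, full)$F[2]
  # the last entry passed the threshold with exactly this F
  expect_gte(f_ref, cfg$f_to_enter - 1e-8)
})

test_that("permuted labels give chance-level jackknifed accuracy", {
  g <- make_groups(50, 20, effect_region = "r1", delta = 2, seed = 5)
  set.seed(99)
  lab_perm <- sample(g$lab)
  model <- stepwise_lda(g$X, lab_perm)
  report <- jackknife_classify(g$X, lab_perm, model$selected_regions)
  acc <- sum(diag(report$confusion)) / sum(report$confusion)
  expect_lt(acc, 0.70)
  expect_gt(acc, 0.30)
})

test_that("an exact duplicate of an entered column is blocked by tolerance", {
  g <- make_groups(50, 5, effect_region = "r1", delta = 2, seed = 7)
  X2 <- cbind(g$X, r_dup = g$X[, "r1"])
  model <- stepwise_lda(X2, g$lab)
  expect_true("r1" %in% model$selected_regions ||
                "r_dup" %in% model$selected_regions)
  expect_false(all(c("r1", "r_dup") %in% model$selected_regions))
})

test_that("second-step rerun selects the redundant copy on fresh regions", {
  g <- make_groups(60, 10, seed = 13)
  # r1 carries the signal; r2 is a noisy duplicate of r1
  g$X[g$lab == "pos", "r1"] <- g$X[g$lab == "pos", "r1"] + 2
  g$X[, "r2"] <- g$X[, "r1"] + rnorm(nrow(g$X), 0, 0.3)
  first <- stepwise_lda(g$X, g$lab)
  expect_equal(first$selected_regions[1], "r1")
  second <- second_step_rerun(g$X, g$lab, stepwise_config(), first)
  expect_length(intersect(second$model$selected_regions,
                          first$selected_regions), 0)
  expect_true("r2" %in% second$model$selected_regions)
  # null data: second model on pure noise usually selects nothing strong;
  # disjointness is guaranteed by construction either way
  expect_true(all(!second$model$selected_regions %in% first$selected_regions))
})

test_that("jackknife matches a brute-force leave-one-out re-fit", {
  for (seed in 1:5) {
    g <- make_groups(20, 4, effect_region = "r3", delta = 1, seed = seed)
    regions <- c("r1", "r3")
    rep1 <- jackknife_classify(g$X, g$lab, regions)
    n <- nrow(g$X)
    brute <- vapply(seq_len(n), function(i) {
      tr <- g$X[-i, regions, drop = FALSE]
      f <- g$lab[-i]
      mu1 <- colMeans(tr[f == "neg", , drop = FALSE])
      mu2 <- colMeans(tr[f == "pos", , drop = FALSE])
      Sp <- ((sum(f == "neg") - 1) * cov(tr[f == "neg", , drop = FALSE]) +
               (sum(f == "pos") - 1) * cov(tr[f == "pos", , drop = FALSE])) /
        (n - 3)
      d1 <- mahalanobis(g$X[i, regions], mu1, Sp)
      d2 <- mahalanobis(g$X[i, regions], mu2, Sp)
      if (d1 <= d2) "neg" else "pos"
    }, character(1))
    expect_identical(as.vector(rep1$confusion),
                     as.vector(table(g$lab, factor(brute, levels = c("neg", "pos")))))
  }
})

test_that("jackknifed accuracy does not beat resubstitution on average", {
  diffs <- vapply(1:10, function(seed) {
    g <- make_groups(15, 6, effect_region = "r1", delta = 0.8, seed = seed)
    model <- stepwise_lda(g$X, g$lab,
                          stepwise_config(f_to_enter = 2, f_to_remove = 1))
    if (length(model$selected_regions) == 0) return(0)
    jk <- jackknife_classify(g$X, g$lab, model$selected_regions)
    rs <- resubstitution_classify(g$X, g$lab, model$selected_regions)
    (sum(diag(rs$confusion)) - sum(diag(jk$confusion))) / sum(jk$confusion)
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("full-sample classification agrees with an independent LDA", {
  for (seed in c(2, 11)) {
    g <- make_groups(40, 6, effect_region = "r4", delta = 1.2, seed = seed)
    regions <- c("r2", "r4", "r6")
    ours <- resubstitution_classify(g$X, g$lab, regions)
    ref <- MASS::lda(g$X[, regions], g$lab, prior = c(0.5, 0.5))
    pred <- predict(ref, g$X[, regions])$class
    expect_identical(as.vector(ours$confusion),
                     as.vector(table(g$lab, pred)))
  }
})

test_that("an empty model classifies everyone to the documented tie-break group", {
  g <- make_groups(10, 3, seed = 2)
  report <- jackknife_classify(g$X, g$lab, character(0))
  expect_equal(unname(report$confusion[, 1]), c(10L, 10L))
  expect_equal(unname(report$confusion[, 2]), c(0L, 0L))
})

test_that("report percentages and p-values match the published conventions", {
  rep1 <- classification_report(matrix(c(42L, 11L, 12L, 37L), 2, 2,
                                       dimnames = list(c("neg", "pos"),
                                                       c("neg", "pos"))))
  expect_equal(unname(rep1$pct_correct), c(77.8, 77.1))
  expect_equal(unname(rep1$p_value), c(7.0065287e-06, 3.0848204e-05),
               tolerance = 1e-6)
  # rounding is half away from zero, not half to even
  expect_equal(round_half_up(76.25, 1), 76.3)
  expect_equal(round_half_up(-76.25, 1), -76.3)
  expect_equal(round_half_up(c(77.75, 93.85), 1), c(77.8, 93.9))
})

test_that("Welch score test matches the hand-evaluated formula", {
  scores <- c(0, 0, 1, 1, 10, 10, 11, 11)
  lab <- factor(rep(c("neg", "pos"), each = 4), levels = c("neg", "pos"))
  res <- score_group_test(scores, lab)
  # independent hand computation of the Welch statistic and df
  v1 <- var(scores[1:4]) / 4
  v2 <- var(scores[5:8]) / 4
  t_hand <- (mean(scores[5:8]) - mean(scores[1:4])) / sqrt(v1 + v2)
  df_hand <- (v1 + v2)^2 / (v1^2 / 3 + v2^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)     # = 24.4949
  expect_equal(res$df_adjusted, df_hand, tolerance = 1e-12)  # = 6
  expect_equal(res$df_adjusted, 6)
  expect_lt(res$p, 1e-6)
  # identical distributions in both groups: t = 0, one-sided p = 0.5
  res0 <- score_group_test(c(1, 2, 3, 1, 2, 3),
                           factor(rep(c("neg", "pos"), each = 3)))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
  expect_error(score_group_test(rep(1, 6), factor(rep(c("a", "b"), each = 3))),
               "zero variance")
})

test_that("Levene's check rejects near the nominal rate under equal variances", {
  set.seed(17)
  rejections <- mean(replicate(300, {
    x <- rnorm(60)
    lab <- factor(rep(c("a", "b"), each = 30))
    score_group_test(x, lab)$levene_p < 0.05
  }))
  expect_gt(rejections, 0.01)
  expect_lt(rejections, 0.12)
})

test_that("coincidence rates and score correlations behave", {
  status <- data.frame(s1 = c("positive", "positive", "negative", "positive"),
                       s2 = c("positive", "negative", "negative", "positive"),
                       s3 = rep("positive", 4))
  scores <- cbind(c1 = c(1, 2, 3, 4), c2 = c(2, 4, 6, 8), c3 = c(4, 3, 2, 1))
  res <- coincidence_and_correlation(status, scores)
  expect_equal(res$coincidence["s1", "s2"], 0.5)
  expect_equal(res$coincidence["s3", "s3"], 1)
  expect_equal(unname(diag(res$score_correlations)), rep(1, 3))
  expect_equal(res$score_correlations["c1", "c2"], 1)
  expect_equal(res$score_correlations["c1", "c3"], -1)
  # independent coin-flip symptoms co-occur at about prevalence^2
  set.seed(23)
  big <- data.frame(a = sample(c("positive", "negative"), 2000, TRUE),
                    b = sample(c("positive", "negative"), 2000, TRUE))
  res2 <- coincidence_and_correlation(big, cbind(x = rnorm(2000), y = rnorm(2000)))
  expect_lt(abs(res2$coincidence["a", "b"] - 0.25), 4 * sqrt(0.25 * 0.75 / 2000))
})

test_that("discriminant scores have unit pooled spread and the right direction", {
  g <- make_groups(40, 5, effect_region = "r2", delta = 1.5, seed = 21)
  s <- discriminant_scores(g$X, g$lab, c("r2", "r4"))
  expect_gt(mean(s[g$lab == "pos"]), mean(s[g$lab == "neg"]))
  pooled_var <- (var(s[g$lab == "neg"]) * 39 + var(s[g$lab == "pos"]) * 39) / 78
  expect_equal(pooled_var, 1, tolerance = 1e-10)
})

test_that("model and report files are written in the documented layout", {
  g <- make_groups(30, 4, effect_region = "r1", delta = 2, seed = 31)
  model <- stepwise_lda(g$X, g$lab)
  dir <- withr::local_tempdir()
  write_classifier_model(model, file.path(dir, "model.tsv"))
  m <- read.delim(file.path(dir, "model.tsv"), comment.char = "#")
  expect_equal(names(m), c("region_id", "entry_order", "coefficient_group0",
                           "coefficient_group1", "sign"))
  expect_equal(m$region_id, model$selected_regions)
  report <- jackknife_classify(g$X, g$lab, model$selected_regions)
  write_classification_report(report, file.path(dir, "report.tsv"))
  r <- read.delim(file.path(dir, "report.tsv"), comment.char = "#")
  expect_equal(names(r), c("group", "n_classified_negative",
                           "n_classified_positive", "pct_correct", "p_value"))
})
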