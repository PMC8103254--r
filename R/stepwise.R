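# Stepwise two-group linear discriminant classification.
#
# Variables (regional z-scores) enter one at a time, each step admitting the
# candidate that minimizes Wilks' lambda, provided its partial F-to-enter
# passes the threshold and it survives a tolerance (collinearity) test;
# entered variables whose partial F-to-remove falls below a second threshold
# are removed again.  For two groups, Wilks' lambda over a variable set S
# equals 1 - R^2 of the regression of the group indicator on S, and the
# discriminant partial F equals the regression partial F, so the whole
# search runs on one symmetric sweep of the centered cross-product matrix
# of [features, indicator] -- the classical computing scheme for stepwise
# discriminant analysis.  Classification uses Fisher's linear
# classification functions on the selected set; accuracy is assessed by
# leave-one-out jackknife with the variable set held fixed and tested
# against the fair coin with an exact binomial tail.

#' Stepwise selection thresholds
#'
#' Defaults follow the long-standing conventions of stepwise discriminant
#' programs: F-to-enter 3.84 and F-to-remove 2.71 (the chi-square 5% and 10%
#' critical values on 1 df), a tolerance of 0.001 against near-collinear
#' candidates, and at most two sweeps per candidate variable.
#'
#' @param f_to_enter minimum partial F for a candidate to enter.
#' @param f_to_remove entered variables fall out below this partial F.
#' @param tolerance minimum 1 - R^2 of a candidate against the entered set.
#' @param max_steps cap on entry/removal sweeps (default 2 x candidates).
#' @param max_regions cap on the number of entered regions; the default
#'   `NULL` means one region per five subjects (an events-per-variable
#'   guard: with a fixed F-to-enter and many null candidates, stepwise
#'   selection otherwise keeps admitting noise variables until the error
#'   degrees of freedom are exhausted and the within-group covariance
#'   becomes numerically singular).
#' @param priors "equal" (default) or "proportional" group priors for the
#'   classification functions.
#' @return object of class `stepwise_config`.
#' @export
stepwise_config <- function(f_to_enter = 3.84, f_to_remove = 2.71,
                            tolerance = 0.001, max_steps = NULL,
                            max_regions = NULL,
                            priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  stopifnot(f_to_enter > f_to_remove, f_to_remove > 0,
            tolerance > 0, tolerance < 1)
  structure(list(f_to_enter = f_to_enter, f_to_remove = f_to_remove,
                 tolerance = tolerance, max_steps = max_steps,
                 max_regions = max_regions, priors = priors),
            class = "stepwise_config")
}

as_two_groups <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two groups")
  if (any(table(f) < 2)) stop("need at least 2 subjects per group")
  f
}

# Symmetric sweep of row/column k of matrix A.
sweep_op <- function(A, k) {
  d <- A[k, k]
  if (!is.finite(d) || abs(d) < .Machine$double.eps) {
    stop("sweep pivot is numerically zero (singular system)")
  }
  Ak <- A[, k]
  A <- A - outer(Ak, Ak) / d
  A[k, ] <- Ak / d
  A[, k] <- Ak / d
  A[k, k] <- -1 / d
  A
}

#' Stepwise linear discriminant analysis on regional z-scores
#'
#' @param z_matrix numeric matrix subjects x regions (column names are the
#'   candidate region ids).
#' @param labels two-level grouping (factor or character), one per row; the
#'   second factor level is the "positive" group.
#' @param cfg a [stepwise_config()].
#' @param excluded_regions region ids withheld from the candidate set (used
#'   for second-step reruns).
#' @return object of class `classifier_model` with the entry-ordered
#'   `selected_regions`, Fisher classification-function `coefficients`
#'   (regions x 2 groups) and `constants`, per-region `signs` ("+" when the
#'   positive group's mean is the higher), the Wilks' lambda trace along the
#'   entry sequence, and the group labels and priors.
#' @export
stepwise_lda <- function(z_matrix, labels, cfg = stepwise_config(),
                         excluded_regions = character()) {
  f <- as_two_groups(labels)
  stopifnot(nrow(z_matrix) == length(f))
  candidates <- setdiff(colnames(z_matrix), excluded_regions)
  X <- z_matrix[, candidates, drop = FALSE]
  n <- nrow(X)
  p_all <- ncol(X)
  y <- as.numeric(f == levels(f)[2])
  C <- cbind(X, .y = y)
  C <- scale(C, center = TRUE, scale = FALSE)
  A <- crossprod(C)
  yi <- p_all + 1L
  # Within-groups scatter of the candidates, for the tolerance test (the
  # discriminant convention: collinearity is judged within groups, which
  # also guards the classification-function covariance inverse).
  Xw <- X
  for (g in levels(f)) {
    idx <- f == g
    Xw[idx, ] <- scale(X[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  W <- crossprod(Xw)
  orig_diag <- diag(A)[seq_len(p_all)]
  orig_wdiag <- diag(W)
  eligible <- orig_diag > 0 & orig_wdiag > 0  # constant columns can never enter
  tss_y <- A[yi, yi]
  if (tss_y <= 0) stop("labels have no variation")

  entered <- logical(p_all)
  entry_order <- integer(0)
  wilks_trace <- numeric(0)
  max_steps <- cfg$max_steps %||% (2L * p_all)
  max_regions <- cfg$max_regions %||% max(1L, n %/% 5L)
  steps <- 0L

  entry_F <- function() {
    p <- sum(entered)
    df2 <- n - p - 2L
    Fs <- rep(NA_real_, p_all)
    if (df2 < 1) return(Fs)
    for (j in which(!entered & eligible)) {
      tol_j <- W[j, j] / orig_wdiag[j]
      if (!is.finite(tol_j) || tol_j < cfg$tolerance) next
      r2 <- A[j, yi]^2 / (A[j, j] * A[yi, yi])
      if (!is.finite(r2)) next
      r2 <- min(r2, 1 - 1e-12)
      Fs[j] <- df2 * r2 / (1 - r2)
    }
    Fs
  }
  removal_F <- function() {
    p <- sum(entered)
    df2 <- n - p - 1L
    Fs <- rep(NA_real_, p_all)
    for (j in which(entered)) {
      d_rss <- A[j, yi]^2 / (-A[j, j])
      Fs[j] <- d_rss / (A[yi, yi] / df2)
    }
    Fs
  }

  repeat {
    # removal phase
    repeat {
      if (!any(entered) || steps >= max_steps) break
      rF <- removal_F()
      worst <- which.min(rF)
      if (length(worst) == 0 || is.na(rF[worst]) || rF[worst] >= cfg$f_to_remove) break
      A <- sweep_op(A, worst)           # reverse sweep removes the variable
      W <- sweep_op(W, worst)
      entered[worst] <- FALSE
      entry_order <- setdiff(entry_order, worst)
      steps <- steps + 1L
    }
    if (steps >= max_steps || sum(entered) >= max_regions) break
    eF <- entry_F()
    if (all(is.na(eF))) break
    best <- which.max(eF)
    if (is.na(eF[best]) || eF[best] < cfg$f_to_enter) break
    A <- sweep_op(A, best)
    W <- sweep_op(W, best)
    entered[best] <- TRUE
    entry_order <- c(entry_order, best)
    steps <- steps + 1L
    wilks_trace <- c(wilks_trace, A[yi, yi] / tss_y)
  }

  selected <- candidates[entry_order]
  fisher <- fisher_functions(z_matrix[, selected, drop = FALSE], f, cfg$priors)
  signs <- character(0)
  if (length(selected)) {
    m_pos <- colMeans(z_matrix[f == levels(f)[2], selected, drop = FALSE])
    m_neg <- colMeans(z_matrix[f == levels(f)[1], selected, drop = FALSE])
    signs <- ifelse(m_pos > m_neg, "+", "-")
    names(signs) <- selected
  }
  structure(list(selected_regions = selected,
                 coefficients = fisher$coefficients,
                 constants = fisher$constants,
                 group_labels = levels(f),
                 signs = signs,
                 wilks = wilks_trace,
                 priors = cfg$priors,
                 n_per_group = as.integer(table(f)),
                 excluded_regions = excluded_regions),
            class = "classifier_model")
}

# Fisher two-group linear classification functions from raw data.
fisher_functions <- function(X, f, priors = "equal") {
  lev <- levels(f)
  n <- nrow(X)
  pri <- if (priors == "equal") c(0.5, 0.5) else as.numeric(table(f)) / n
  p <- ncol(X)
  if (p == 0) {
    return(list(coefficients = matrix(numeric(0), 0, 2, dimnames = list(NULL, lev)),
                constants = stats::setNames(log(pri), lev)))
  }
  X1 <- X[f == lev[1], , drop = FALSE]
  X2 <- X[f == lev[2], , drop = FALSE]
  mu <- cbind(colMeans(X1), colMeans(X2))
  Sp <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X2) - 1) * stats::cov(X2)) / (n - 2)
  coef <- tryCatch(solve(Sp, mu),
                   error = function(e) stop("singular within-group covariance: ",
                                            conditionMessage(e)))
  coef <- matrix(coef, p, 2, dimnames = list(colnames(X), lev))
  consts <- -0.5 * colSums(mu * coef) + log(pri)
  list(coefficients = coef, constants = stats::setNames(consts, lev))
}

#' Classify subjects with a fitted model
#'
#' A model with no selected regions falls back to the priors; with equal
#' priors the deterministic tie-break assigns every subject to the first
#' group label.
#'
#' @param model a `classifier_model`.
#' @param z_matrix subjects x regions; must contain the selected regions.
#' @return character vector of predicted group labels.
#' @export
classify <- function(model, z_matrix) {
  lev <- model$group_labels
  if (length(model$selected_regions) == 0) {
    pick <- if (model$constants[2] > model$constants[1]) lev[2] else lev[1]
    return(rep(pick, nrow(z_matrix)))
  }
  Z <- z_matrix[, model$selected_regions, drop = FALSE]
  sc <- Z %*% model$coefficients
  sc <- sweep(sc, 2, model$constants, `+`)
  lev[max.col(sc, ties.method = "first")]
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %s vs %s, %d region(s) selected\n",
              x$group_labels[1], x$group_labels[2], length(x$selected_regions)))
  if (length(x$selected_regions)) {
    cat("  entry order:", paste0(x$selected_regions, " (", x$signs, ")",
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a Table-style classification report from a confusion matrix
#'
#' @param confusion 2x2 integer matrix, rows = true group, columns =
#'   classified group (same order).
#' @param group_labels the two group labels (row order).
#' @param jackknifed logical flag recorded in the report.
#' @param convention binomial tail convention, see
#'   [binomial_exceedance_p()].
#' @return object of class `classification_report`: the confusion matrix,
#'   per-group percent correct (one decimal, half away from zero) and exact
#'   fair-coin p-values.
#' @export
classification_report <- function(confusion, group_labels = rownames(confusion),
                                  jackknifed = TRUE, convention = "strict") {
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(group_labels, group_labels))
  n_g <- rowSums(confusion)
  correct <- diag(confusion)
  pct <- round_half_up(100 * correct / n_g, 1)
  p <- vapply(1:2, function(g) binomial_exceedance_p(correct[g], n_g[g],
                                                     convention = convention),
              numeric(1))
  structure(list(confusion = confusion,
                 pct_correct = stats::setNames(pct, group_labels),
                 p_value = stats::setNames(p, group_labels),
                 jackknifed = jackknifed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  lab <- rownames(x$confusion)
  cat(sprintf("%s classification\n", if (x$jackknifed) "jackknifed" else "resubstitution"))
  for (g in 1:2) {
    cat(sprintf("  %-12s %5d %5d  %5.1f%%  %.2g\n", lab[g],
                x$confusion[g, 1], x$confusion[g, 2], x$pct_correct[g], x$p_value[g]))
  }
  invisible(x)
}

#' Jackknifed (leave-one-out) classification
#'
#' The variable set is the one selected on the full sample; only the
#' classification-function coefficients are re-estimated with each subject
#' held out, and the held-out subject is then classified.
#'
#' @param z_matrix subjects x regions.
#' @param labels two-level grouping, one per row.
#' @param model_regions character vector of regions to use (typically
#'   `model$selected_regions`).
#' @param cfg a [stepwise_config()] (for the priors).
#' @param convention binomial tail convention for the report p-values.
#' @return a [classification_report()] with `jackknifed = TRUE`.
#' @export
jackknife_classify <- function(z_matrix, labels, model_regions,
                               cfg = stepwise_config(), convention = "strict") {
  f <- as_two_groups(labels)
  lev <- levels(f)
  n <- nrow(z_matrix)
  pred <- character(n)
  if (length(model_regions) == 0) {
    pri <- if (cfg$priors == "equal") c(0.5, 0.5) else as.numeric(table(f)) / n
    pred[] <- if (pri[2] > pri[1]) lev[2] else lev[1]
  } else {
    Z <- z_matrix[, model_regions, drop = FALSE]
    for (i in seq_len(n)) {
      fi <- fisher_functions(Z[-i, , drop = FALSE], droplevels(f[-i]), cfg$priors)
      sc <- drop(Z[i, ] %*% fi$coefficients) + fi$constants
      pred[i] <- lev[which.max(sc)]
    }
  }
  confusion <- table(factor(f, levels = lev), factor(pred, levels = lev))
  classification_report(unclass(confusion), group_labels = lev,
                        jackknifed = TRUE, convention = convention)
}

#' Resubstitution classification (fit and classify on the full sample)
#'
#' @inheritParams jackknife_classify
#' @return a [classification_report()] with `jackknifed = FALSE`.
#' @export
resubstitution_classify <- function(z_matrix, labels, model_regions,
                                    cfg = stepwise_config(), convention = "strict") {
  f <- as_two_groups(labels)
  lev <- levels(f)
  if (length(model_regions) == 0) {
    pred <- rep(lev[1], nrow(z_matrix))
  } else {
    fi <- fisher_functions(z_matrix[, model_regions, drop = FALSE], f, cfg$priors)
    sc <- z_matrix[, model_regions, drop = FALSE] %*% fi$coefficients
    sc <- sweep(sc, 2, fi$constants, `+`)
    pred <- lev[max.col(sc, ties.method = "first")]
  }
  confusion <- table(factor(f, levels = lev), factor(pred, levels = lev))
  classification_report(unclass(confusion), group_labels = lev,
                        jackknifed = FALSE, convention = convention)
}

#' Exact fair-coin binomial tail probability
#'
#' The probability of getting more than (strict convention, the default) or
#' at least (`"at_least"`) `correct` heads in `n` flips of a fair coin,
#' summed in log space so that tails far below double underflow of the
#' individual terms remain accurate.
#'
#' @param correct number of correctly classified subjects, 0..n.
#' @param n group size.
#' @param convention `"strict"` (P(X > correct); reproduces classical
#'   published classification-table p-values) or `"at_least"`
#'   (P(X >= correct)).
#' @return the tail probability; 0 for an empty tail.
#' @export
binomial_exceedance_p <- function(correct, n,
                                  convention = c("strict", "at_least")) {
  convention <- match.arg(convention)
  stopifnot(length(correct) == 1, length(n) == 1, correct >= 0, correct <= n)
  lo <- if (convention == "strict") correct + 1 else correct
  if (lo > n) return(0)
  k <- lo:n
  logterms <- lchoose(n, k) - n * log(2)
  m <- max(logterms)
  exp(m + log(sum(exp(logterms - m))))
}

#' Second-step rerun: exclude the first model's regions and refit
#'
#' @param z_matrix subjects x regions.
#' @param labels two-level grouping.
#' @param cfg a [stepwise_config()].
#' @param first_model the `classifier_model` from the first run.
#' @param convention binomial tail convention for the report.
#' @return list with the second-step `model` and jackknifed `report`.
#' @export
second_step_rerun <- function(z_matrix, labels, cfg = stepwise_config(),
                              first_model, convention = "strict") {
  if (length(first_model$selected_regions) == 0) {
    stop("first model selected no regions; nothing to exclude")
  }
  excl <- union(first_model$excluded_regions, first_model$selected_regions)
  model <- stepwise_lda(z_matrix, labels, cfg, excluded_regions = excl)
  report <- jackknife_classify(z_matrix, labels, model$selected_regions, cfg,
                               convention = convention)
  list(model = model, report = report)
}

#' Canonical discriminant scores for a set of regions
#'
#' The single canonical variate of a two-group discriminant, scaled to unit
#' pooled within-group variance and oriented so the positive (second-level)
#' group scores higher on average.
#'
#' @param z_matrix subjects x regions.
#' @param labels two-level grouping.
#' @param regions regions to use.
#' @return numeric vector of scores, one per subject.
#' @export
discriminant_scores <- function(z_matrix, labels, regions) {
  f <- as_two_groups(labels)
  if (length(regions) == 0) stop("need at least one region for scores")
  Z <- z_matrix[, regions, drop = FALSE]
  lev <- levels(f)
  X1 <- Z[f == lev[1], , drop = FALSE]
  X2 <- Z[f == lev[2], , drop = FALSE]
  Sp <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X2) - 1) * stats::cov(X2)) /
    (nrow(Z) - 2)
  w <- solve(Sp, colMeans(X2) - colMeans(X1))
  drop(Z %*% w) / sqrt(drop(t(w) %*% Sp %*% w))
}

#' Welch test on classifier scores between groups, with Levene's check
#'
#' Compares mean discriminant scores between the clinically negative and
#' positive groups with Welch's unequal-variance t statistic and
#' Welch-Satterthwaite adjusted degrees of freedom (the conservative df
#' choice), one-sided in the direction of the positive group. Levene's F
#' (center = mean; a one-way ANOVA of absolute deviations) tests for a
#' difference in score variability.
#'
#' @param scores numeric vector of per-subject discriminant scores.
#' @param labels two-level grouping (second level = positive).
#' @return list with `t`, `df_adjusted`, `p` (one-sided), `levene_F`,
#'   `levene_p`.
#' @export
score_group_test <- function(scores, labels) {
  f <- as_two_groups(labels)
  lev <- levels(f)
  x_neg <- scores[f == lev[1]]
  x_pos <- scores[f == lev[2]]
  if (stats::var(x_neg) == 0 && stats::var(x_pos) == 0) {
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(x_pos, x_neg, alternative = "greater", var.equal = FALSE)
  # Levene (center = mean): one-way ANOVA of absolute deviations, computed
  # directly so the degenerate all-equal-deviations case stays defined.
  d <- abs(scores - stats::ave(scores, f))
  n <- length(d)
  m_g <- tapply(d, f, mean)
  n_g <- tabulate(f)
  ssb <- sum(n_g * (m_g - mean(d))^2)
  ssw <- sum((d - m_g[f])^2)
  if (ssw <= 1e-12 * max(d^2, 1)) {
    lev_F <- if (ssb <= 1e-12 * max(d^2, 1)) 0 else Inf
  } else {
    lev_F <- (ssb / 1) / (ssw / (n - 2))
  }
  lev_p <- stats::pf(lev_F, 1, n - 2, lower.tail = FALSE)
  list(t = unname(tt$statistic), df_adjusted = unname(tt$parameter),
       p = tt$p.value, levene_F = unname(lev_F), levene_p = unname(lev_p))
}

#' Symptom coincidence rates and classifier-score correlations
#'
#' @param symptom_status data.frame or matrix of per-subject symptom status
#'   (values "positive"/"negative", or logical), one column per symptom;
#'   "missing" or `NA` entries are dropped pairwise.
#' @param scores matrix subjects x classifiers of discriminant scores.
#' @return list with `coincidence` (symmetric matrix of both-positive
#'   fractions; the diagonal holds single-symptom prevalences) and
#'   `score_correlations` (Pearson).
#' @export
coincidence_and_correlation <- function(symptom_status, scores) {
  st <- as.data.frame(symptom_status)
  if ("subject_id" %in% names(st)) st$subject_id <- NULL
  if (ncol(st) < 2) stop("need at least 2 symptoms")
  pos <- sapply(st, function(x) {
    if (is.logical(x)) x else ifelse(as.character(x) == "missing", NA,
                                     as.character(x) == "positive")
  })
  k <- ncol(pos)
  co <- matrix(NA_real_, k, k, dimnames = list(colnames(pos), colnames(pos)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- !is.na(pos[, i]) & !is.na(pos[, j])
    co[i, j] <- mean(pos[ok, i] & pos[ok, j])
  }
  list(coincidence = co,
       score_correlations = stats::cor(scores, use = "pairwise.complete.obs"))
}

#' Write a classifier model as TSV
#' @param model a `classifier_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_classifier_model <- function(model, path) {
  sel <- model$selected_regions
  df <- data.frame(region_id = sel,
                   entry_order = seq_along(sel),
                   coefficient_group0 = num_chr(model$coefficients[sel, 1]),
                   coefficient_group1 = num_chr(model$coefficients[sel, 2]),
                   sign = unname(model$signs[sel]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header_comments = c(
    sprintf("groups: %s %s", model$group_labels[1], model$group_labels[2]),
    sprintf("constants: %s %s", num_chr(model$constants[1]), num_chr(model$constants[2])),
    sprintf("priors: %s", model$priors)))
}

#' Write a classification report as TSV (confusion-table layout)
#' @param report a `classification_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_classification_report <- function(report, path) {
  lab <- rownames(report$confusion)
  df <- data.frame(group = lab,
                   n_classified_negative = report$confusion[, 1],
                   n_classified_positive = report$confusion[, 2],
                   pct_correct = sprintf("%.1f", report$pct_correct),
                   p_value = formatC(report$p_value, digits = 2, format = "g"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header_comments = sprintf(
    "jackknifed: %s", tolower(as.character(report$jackknifed))))
}
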