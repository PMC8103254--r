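# Test-retest reliability of regional z-scores.
#
# Short-term reliability pairs the resting and task recordings of the same
# sitting; long-term reliability pairs baseline and follow-up resting
# recordings.  Both are summarized per region by the Pearson correlation
# across paired subjects and by the mean difference (second minus first) in
# z-score units, with a paired two-sided t-test on the differences.

# Two-sided one-sample t on paired differences, tolerant of differences
# that are constant to machine precision (shift-only changes).
paired_p <- function(x) {
  if (stats::sd(x) <= 1e-12 * max(abs(x), 1)) {
    return(c(t = NA_real_, p = if (isTRUE(all.equal(mean(x), 0))) 1 else 0))
  }
  h <- stats::t.test(x)
  c(t = unname(h$statistic), p = h$p.value)
}

#' Per-region test-retest reliability
#'
#' @param z_first,z_second matrices subjects x regions of z-scores from the
#'   first and second recording of each pair; rows must be the same
#'   subjects in the same order (checked via rownames when present).
#' @param term label recorded in the report: "short" (same sitting) or
#'   "long" (baseline vs. follow-up).
#' @return object of class `reliability_report`: data.frame with
#'   `region_id`, `term`, `pearson_r` (NA with a warning where a session has
#'   zero variance), `mean_diff` (second minus first), `n_pairs`, and
#'   `p_diff` from the paired two-sided t-test.
#' @export
test_retest <- function(z_first, z_second, term = c("long", "short")) {
  term <- match.arg(term)
  if (!identical(dim(z_first), dim(z_second)) ||
      !identical(colnames(z_first), colnames(z_second))) {
    stop("paired z-score matrices must have identical shape and regions")
  }
  if (!is.null(rownames(z_first)) && !is.null(rownames(z_second)) &&
      !identical(rownames(z_first), rownames(z_second))) {
    stop("rows of the two sessions are not paired by subject")
  }
  n <- nrow(z_first)
  if (n < 3) stop("need at least 3 paired subjects")
  sd1 <- apply(z_first, 2, stats::sd)
  sd2 <- apply(z_second, 2, stats::sd)
  degenerate <- sd1 == 0 | sd2 == 0
  r <- rep(NA_real_, ncol(z_first))
  for (j in which(!degenerate)) r[j] <- stats::cor(z_first[, j], z_second[, j])
  if (any(degenerate)) {
    warning("zero variance in a session for ", sum(degenerate),
            " region(s); pearson_r undefined there")
  }
  d <- z_second - z_first
  mean_diff <- colMeans(d)
  p_diff <- apply(d, 2, function(x) paired_p(x)["p"])
  structure(data.frame(region_id = colnames(z_first), term = term,
                       pearson_r = r, mean_diff = unname(mean_diff),
                       n_pairs = n, p_diff = unname(p_diff),
                       stringsAsFactors = FALSE),
            class = c("reliability_report", "data.frame"))
}

#' Paired-t significance of the test-retest mean differences
#'
#' Recomputes (or fills in) the per-region two-sided paired t-test p-value
#' for mean_diff != 0.
#'
#' @param report a `reliability_report` (region order must match).
#' @param z_first,z_second the paired z-score matrices.
#' @return the report with `p_diff` (and `t_diff`) columns.
#' @export
reliability_difference_significance <- function(report, z_first, z_second) {
  stopifnot(identical(report$region_id, colnames(z_first)))
  d <- z_second - z_first
  tt <- apply(d, 2, paired_p)
  report$t_diff <- unname(tt["t", ])
  report$p_diff <- unname(tt["p", ])
  report
}

#' Write a reliability report as TSV
#' @param report a `reliability_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reliability_report <- function(report, path) {
  df <- as.data.frame(report)
  for (cl in c("pearson_r", "mean_diff", "p_diff")) df[[cl]] <- num_chr(df[[cl]])
  write_tsv(df, path)
}
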