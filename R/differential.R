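# Cortex vs. adjacent white-matter-rim differential activity.
#
# For each cortical parcel and its paired rim, the observed current counts
# are compared with the counts expected if activity were proportional to
# volume, using the 2-cell Pearson goodness-of-fit chi-square on 1 df
# (no continuity correction: the counts run to thousands). Tail
# probabilities are kept in log space so p-values far below double
# underflow remain representable.  Raw counts are used: the chi-square
# requires integer counts.

#' Chi-square differential for one cortex/rim pair
#'
#' @param c_ctx,c_wm observed counts in the cortical region and its rim.
#' @param v_ctx,v_wm their volumes (mm3).
#' @param threshold_p significance threshold (default 1e-8, a conservative
#'   level for tens of thousands of simultaneous pairs).
#' @param min_total pairs with fewer than this many total counts are
#'   reported untestable rather than tested (default 10).
#' @return list with the observed and expected counts, `chi2`, `log10_p`,
#'   `p`, `direction` ("cortex_higher", "wm_higher" or "none"),
#'   `significant`, and `testable`.
#' @export
pair_chi2 <- function(c_ctx, c_wm, v_ctx, v_wm, threshold_p = 1e-8,
                      min_total = 10) {
  stopifnot(c_ctx >= 0, c_wm >= 0, v_ctx > 0, v_wm > 0)
  total <- c_ctx + c_wm
  out <- list(c_ctx = c_ctx, c_wm = c_wm,
              e_ctx = NA_real_, e_wm = NA_real_, chi2 = NA_real_,
              log10_p = NA_real_, p = NA_real_, direction = "none",
              significant = FALSE, testable = total >= min_total && total > 0)
  if (total == 0) return(out)
  e_ctx <- total * v_ctx / (v_ctx + v_wm)
  e_wm <- total - e_ctx
  chi2 <- (c_ctx - e_ctx)^2 / e_ctx + (c_wm - e_wm)^2 / e_wm
  log_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  dens_diff <- c_ctx / v_ctx - c_wm / v_wm
  out$e_ctx <- e_ctx
  out$e_wm <- e_wm
  out$chi2 <- chi2
  out$log10_p <- log_p / log(10)
  out$p <- exp(log_p)
  out$direction <- if (chi2 == 0 || dens_diff == 0) "none"
    else if (dens_diff > 0) "cortex_higher" else "wm_higher"
  out$significant <- out$testable && out$log10_p < log10(threshold_p)
  out
}

#' Cohort-wide cortex vs. rim differential summary
#'
#' Runs [pair_chi2()] for every subject recording x cortex/rim pair and
#' tallies the significant pairs by direction.
#'
#' @param cohort a `meg_cohort`.
#' @param table a [region_table()] providing the cortex/rim pairing.
#' @param threshold_p significance threshold (default 1e-8).
#' @param session,condition which recordings to test (default baseline
#'   rest).
#' @param min_total minimum pair count to be testable.
#' @return list with `n_pairs_total`, `n_testable`, `n_cortex_higher`,
#'   `n_wm_higher`, `frac_cortex_higher`, `frac_wm_higher` (fractions of all
#'   pairs), and the per-pair `results` data.frame (subject_id, ctx_region,
#'   wm_region, c_ctx, c_wm, chi2, log10_p, direction, significant).
#' @export
cohort_differential_summary <- function(cohort, table, threshold_p = 1e-8,
                                        session = "baseline", condition = "rest",
                                        min_total = 10) {
  ctx <- table[table$reg_class == "cortical", ]
  if (nrow(ctx) == 0) stop("region table has no cortical regions")
  m <- counts_matrix(cohort, session = session, condition = condition)
  vols <- stats::setNames(table$volume_mm3, table$region_id)
  subjects <- rownames(m)
  n_pair <- nrow(ctx)
  res <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    c_ctx <- as.numeric(m[s, ctx$region_id])
    c_wm <- as.numeric(m[s, ctx$paired_region_id])
    v_ctx <- vols[ctx$region_id]
    v_wm <- vols[ctx$paired_region_id]
    total <- c_ctx + c_wm
    e_ctx <- total * v_ctx / (v_ctx + v_wm)
    e_wm <- total - e_ctx
    chi2 <- ifelse(total > 0, (c_ctx - e_ctx)^2 / pmax(e_ctx, .Machine$double.xmin) +
                     (c_wm - e_wm)^2 / pmax(e_wm, .Machine$double.xmin), NA_real_)
    log10_p <- ifelse(is.na(chi2), NA_real_,
                      stats::pchisq(chi2, 1, lower.tail = FALSE, log.p = TRUE) / log(10))
    dens_diff <- c_ctx / v_ctx - c_wm / v_wm
    testable <- total >= min_total
    direction <- ifelse(is.na(chi2) | chi2 == 0 | dens_diff == 0, "none",
                        ifelse(dens_diff > 0, "cortex_higher", "wm_higher"))
    significant <- testable & !is.na(log10_p) & log10_p < log10(threshold_p)
    res[[s]] <- data.frame(subject_id = subjects[s],
                           ctx_region = ctx$region_id,
                           wm_region = ctx$paired_region_id,
                           c_ctx = c_ctx, c_wm = c_wm, chi2 = chi2,
                           log10_p = log10_p, direction = direction,
                           significant = significant,
                           stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  n_total <- length(subjects) * n_pair
  n_ch <- sum(results$significant & results$direction == "cortex_higher")
  n_wh <- sum(results$significant & results$direction == "wm_higher")
  list(n_pairs_total = n_total,
       n_testable = sum(results$chi2 >= 0 & !is.na(results$chi2) &
                          (results$c_ctx + results$c_wm) >= min_total),
       n_cortex_higher = n_ch, n_wm_higher = n_wh,
       frac_cortex_higher = n_ch / n_total, frac_wm_higher = n_wh / n_total,
       results = results)
}

#' Write per-pair differential results as TSV
#' @param summary a [cohort_differential_summary()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_differential_results <- function(summary, path) {
  df <- summary$results
  for (cl in c("chi2", "log10_p")) df[[cl]] <- num_chr(df[[cl]])
  write_tsv(df, path)
}
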