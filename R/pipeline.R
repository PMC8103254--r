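# End-to-end orchestration: densities -> empty-room correction -> atlas ->
# z-scores -> classifiers / reliability / differential, plus thin
# file-based subcommands and a CLI dispatcher.

#' Pipeline configuration
#'
#' @param apply_correction subtract the correlation-weighted empty-room
#'   density from every subject density (default TRUE).
#' @param correction_before_atlas build the normative atlas from corrected
#'   densities (default TRUE); FALSE builds it on raw densities, which is
#'   the regime in which the z-score floor is exact.
#' @param share_norm_er_model use the normative cohort's empty-room
#'   correlations for the clinical cohort too (default FALSE: each cohort's
#'   correlations are estimated within that cohort).
#' @param binomial_convention "strict" (P(X > k), the convention matching
#'   published classification tables) or "at_least".
#' @param priors "equal" or "proportional" classification priors.
#' @param cutoffs named integer vector of symptom survey cut-offs (default:
#'   insomnia 15, the three distress scales 63).
#' @param chi2_alpha significance threshold for the cortex/rim differential.
#' @param f_to_enter,f_to_remove,tolerance stepwise thresholds, see
#'   [stepwise_config()].
#' @param seed root seed recorded with every run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(apply_correction = TRUE,
                            correction_before_atlas = TRUE,
                            share_norm_er_model = FALSE,
                            binomial_convention = c("strict", "at_least"),
                            priors = c("equal", "proportional"),
                            cutoffs = c(insomnia = 15L, somatization = 63L,
                                        depression = 63L, anxiety = 63L),
                            chi2_alpha = 1e-8,
                            f_to_enter = 3.84, f_to_remove = 2.71,
                            tolerance = 0.001,
                            seed = 1L) {
  binomial_convention <- match.arg(binomial_convention)
  priors <- match.arg(priors)
  stopifnot(all(cutoffs >= 1), chi2_alpha > 0, chi2_alpha < 1)
  structure(list(apply_correction = apply_correction,
                 correction_before_atlas = correction_before_atlas,
                 share_norm_er_model = share_norm_er_model,
                 binomial_convention = binomial_convention,
                 priors = priors, cutoffs = cutoffs, chi2_alpha = chi2_alpha,
                 f_to_enter = f_to_enter, f_to_remove = f_to_remove,
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Unknown keys fail fast; absent keys keep their defaults.
#'
#' @param path YAML file of flat key: value pairs (`cutoffs` may be a map).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$cutoffs)) raw$cutoffs <- unlist(raw$cutoffs)
  do.call(pipeline_config, raw)
}

stepwise_config_of <- function(config) {
  stepwise_config(f_to_enter = config$f_to_enter,
                  f_to_remove = config$f_to_remove,
                  tolerance = config$tolerance, priors = config$priors)
}

# Densities for every recording plus per-cohort empty-room models and the
# corrected densities (recordings without a same-day empty-room recording
# are an error when correction is requested).
cohort_densities <- function(cohort, table, config = pipeline_config()) {
  dens <- compute_density(cohort$counts, table)
  rec <- cohort$recordings
  er_models <- NULL
  corrected <- dens
  if (config$apply_correction) {
    if (!any(rec$condition == "empty_room")) {
      stop("correction requested but the cohort has no empty-room recordings")
    }
    fit_for <- function(grp) {
      sel_s <- rec$condition == "rest" & rec$session == "baseline" & rec$cohort == grp
      sub_ids <- rec$subject_id[sel_s]
      emp_key <- paste(sub_ids, "baseline", "empty_room", sep = ":")
      if (!all(emp_key %in% rec$recording_id)) {
        stop("missing same-day empty-room recording for subject(s): ",
             paste(utils::head(sub_ids[!(emp_key %in% rec$recording_id)]), collapse = ", "))
      }
      ds <- dens[rec$recording_id[sel_s], , drop = FALSE]
      de <- dens[emp_key, , drop = FALSE]
      rownames(ds) <- rownames(de) <- sub_ids
      fit_empty_room_model(ds, de)
    }
    groups <- unique(rec$cohort)
    er_models <- list()
    for (g in groups) {
      er_models[[g]] <- if (config$share_norm_er_model && "norm" %in% groups) {
        fit_for("norm")
      } else fit_for(g)
    }
    subj_rows <- which(rec$condition != "empty_room")
    for (i in subj_rows) {
      emp_key <- paste(rec$subject_id[i], rec$session[i], "empty_room", sep = ":")
      if (!(emp_key %in% rec$recording_id)) {
        stop("missing same-day empty-room recording: ", emp_key)
      }
      model <- er_models[[rec$cohort[i]]]
      corrected[i, ] <- dens[i, ] - model$corr[match(colnames(dens), model$region_id)] *
        dens[emp_key, ]
    }
  }
  list(raw = dens, corrected = corrected, er_models = er_models)
}

# Subject-rowed density matrix for one session/condition.
density_slice <- function(dens, recordings, session, condition, cohort_group = NULL) {
  sel <- recordings$session == session & recordings$condition == condition
  if (!is.null(cohort_group)) sel <- sel & recordings$cohort %in% cohort_group
  m <- dens[sel, , drop = FALSE]
  rownames(m) <- recordings$subject_id[sel]
  m
}

#' Run the full regional analysis on a cohort
#'
#' Computes densities, fits per-cohort empty-room models and applies the
#' dark-count correction, builds the normative atlas from the normative
#' cohort's baseline resting recordings, z-scores everything, trains and
#' jackknifes the symptom classifiers (cortical + subcortical features,
#' clinical cohort, baseline and follow-up pooled), the cohort classifiers
#' (cortical + subcortical, and deep tracts) with second-step reruns,
#' assesses short- and long-term test-retest reliability, and tallies the
#' cortex vs. rim chi-square differential.
#'
#' @param cohort a `meg_cohort`.
#' @param table a [region_table()].
#' @param config a [pipeline_config()].
#' @return a list with `atlas`, `er_models`, `zscores` (per
#'   session/condition), `symptom` (per symptom: model, report, second step,
#'   scores, score test), `coincidence`, `cohort_classifier`,
#'   `deep_classifier`, `reliability` (short/long), and `differential`.
#' @export
analyze_cohort <- function(cohort, table, config = pipeline_config()) {
  cd <- cohort_densities(cohort, table, config)
  rec <- cohort$recordings
  use <- if (config$apply_correction && config$correction_before_atlas) cd$corrected else cd$raw

  ref <- density_slice(use, rec, "baseline", "rest", "norm")
  if (nrow(ref) < 3) stop("need at least 3 normative baseline resting recordings")
  atlas <- build_atlas(ref)

  zs <- list()
  for (s in c("baseline", "followup")) {
    for (cond in setdiff(unique(rec$condition), "empty_room")) {
      m <- density_slice(use, rec, s, cond)
      if (nrow(m)) zs[[paste(s, cond, sep = ":")]] <- zscore(m, atlas)
    }
  }

  cs_features <- regions_of_class(table, c("cortical", "subcortical"))
  dt_features <- regions_of_class(table, "deep_tract")
  cfg <- stepwise_config_of(config)
  conv <- config$binomial_convention

  # Symptom classifiers: clinical cohort, baseline + follow-up observations.
  clin_ids <- cohort$subjects$subject_id[cohort$subjects$cohort == "clin"]
  sym_status <- dichotomize_scores(cohort$subjects[cohort$subjects$cohort == "clin", ,
                                                   drop = FALSE],
                                   cutoffs = config$cutoffs)
  z_clin <- rbind(zs[["baseline:rest"]], zs[["followup:rest"]])
  z_clin <- z_clin[rownames(z_clin) %in% clin_ids, , drop = FALSE]
  symptom <- list()
  score_mat <- NULL
  if (nrow(z_clin) >= 8) {
    score_mat <- matrix(NA_real_, nrow(z_clin), length(config$cutoffs),
                        dimnames = list(NULL, names(config$cutoffs)))
    for (sym in names(config$cutoffs)) {
      st <- sym_status[[sym]][match(rownames(z_clin), sym_status$subject_id)]
      keep <- st %in% c("negative", "positive")
      lab <- factor(as.character(st[keep]), levels = c("negative", "positive"))
      zf <- z_clin[keep, cs_features, drop = FALSE]
      model <- stepwise_lda(zf, lab, cfg)
      report <- jackknife_classify(zf, lab, model$selected_regions, cfg, conv)
      second <- if (length(model$selected_regions))
        second_step_rerun(zf, lab, cfg, model, conv) else NULL
      scores <- if (length(model$selected_regions))
        discriminant_scores(zf, lab, model$selected_regions) else NULL
      stest <- if (!is.null(scores)) score_group_test(scores, lab) else NULL
      if (!is.null(scores)) score_mat[keep, sym] <- scores
      symptom[[sym]] <- list(model = model, report = report, second = second,
                             scores = scores, score_test = stest)
    }
  }
  coincidence <- if (!is.null(score_mat)) {
    st <- sym_status[match(rownames(z_clin), sym_status$subject_id),
                     names(config$cutoffs), drop = FALSE]
    coincidence_and_correlation(st, score_mat)
  } else NULL

  # Cohort classifiers on baseline recordings: norm vs clin.
  zb <- zs[["baseline:rest"]]
  cohort_lab <- factor(rec$cohort[match(rownames(zb), rec$subject_id)],
                       levels = c("norm", "clin"))
  run_cohort_clf <- function(features) {
    zf <- zb[, features, drop = FALSE]
    model <- stepwise_lda(zf, cohort_lab, cfg)
    report <- jackknife_classify(zf, cohort_lab, model$selected_regions, cfg, conv)
    second <- if (length(model$selected_regions))
      second_step_rerun(zf, cohort_lab, cfg, model, conv) else NULL
    list(model = model, report = report, second = second)
  }
  cohort_clf <- if (nlevels(droplevels(cohort_lab)) == 2) run_cohort_clf(cs_features) else NULL
  deep_clf <- if (nlevels(droplevels(cohort_lab)) == 2 && length(dt_features))
    run_cohort_clf(dt_features) else NULL

  # Reliability: short = baseline rest vs task; long = baseline vs follow-up rest.
  reliability <- list()
  if (!is.null(zs[["baseline:task"]])) {
    z1 <- zs[["baseline:rest"]]
    z2 <- zs[["baseline:task"]]
    common <- intersect(rownames(z1), rownames(z2))
    if (length(common) >= 3) {
      reliability$short <- test_retest(z1[common, , drop = FALSE],
                                       z2[common, , drop = FALSE], term = "short")
    }
  }
  if (!is.null(zs[["followup:rest"]])) {
    z1 <- zs[["baseline:rest"]]
    z2 <- zs[["followup:rest"]]
    common <- intersect(rownames(z1), rownames(z2))
    if (length(common) >= 3) {
      reliability$long <- test_retest(z1[common, , drop = FALSE],
                                      z2[common, , drop = FALSE], term = "long")
    }
  }

  differential <- cohort_differential_summary(cohort, table,
                                              threshold_p = config$chi2_alpha)

  list(atlas = atlas, er_models = cd$er_models, densities = cd, zscores = zs,
       symptom = symptom, coincidence = coincidence,
       cohort_classifier = cohort_clf, deep_classifier = deep_clf,
       reliability = reliability, differential = differential)
}

# ---------------------------------------------------------------------------
# File-based subcommands (each reads/writes only the documented TSV formats).

#' Simulate a cohort to disk
#' @param out_dir output directory.
#' @param spec a [cohort_spec()] (default spec if NULL).
#' @param seed overrides the spec's seed when given.
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(out_dir, spec = NULL, seed = NULL) {
  if (is.null(spec)) spec <- cohort_spec()
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  table <- default_region_table(seed = spec$seed)
  cohort <- generate_cohort(spec, table)
  write_region_table(table, file.path(out_dir, "region_table.tsv"))
  write_cohort(cohort, out_dir)
  message(sprintf("simulate: %d subjects, %d recordings, seed %d",
                  nrow(cohort$subjects), nrow(cohort$recordings), spec$seed))
  invisible(out_dir)
}

load_cohort_dir <- function(cohort_dir, table_path = NULL) {
  if (is.null(table_path)) table_path <- file.path(cohort_dir, "region_table.tsv")
  table <- load_region_table(table_path)
  cohort <- read_cohort(cohort_dir, table)
  list(cohort = cohort, table = table)
}

#' Build the normative atlas (and empty-room models) from a cohort directory
#' @param cohort_dir directory from [pipeline_simulate()]/[write_cohort()].
#' @param out path of the atlas TSV.
#' @param config a [pipeline_config()].
#' @param table_path region-table TSV (default `region_table.tsv` in
#'   `cohort_dir`).
#' @return `out`, invisibly.
#' @export
pipeline_atlas <- function(cohort_dir, out, config = pipeline_config(),
                           table_path = NULL) {
  x <- load_cohort_dir(cohort_dir, table_path)
  cd <- cohort_densities(x$cohort, x$table, config)
  use <- if (config$apply_correction && config$correction_before_atlas)
    cd$corrected else cd$raw
  ref <- density_slice(use, x$cohort$recordings, "baseline", "rest", "norm")
  atlas <- build_atlas(ref)
  write_atlas(atlas, out)
  if (!is.null(cd$er_models)) {
    for (g in names(cd$er_models)) {
      write_empty_room_model(cd$er_models[[g]],
                             file.path(dirname(out), paste0("empty_room_", g, ".tsv")))
    }
  }
  invisible(out)
}

#' Z-score a cohort's recordings against an atlas
#' @param cohort_dir cohort directory.
#' @param atlas_path atlas TSV from [pipeline_atlas()].
#' @param out output TSV (long form: subject_id, session, condition,
#'   region_id, z).
#' @param config a [pipeline_config()].
#' @param table_path optional region-table path.
#' @return `out`, invisibly.
#' @export
pipeline_zscore <- function(cohort_dir, atlas_path, out,
                            config = pipeline_config(), table_path = NULL) {
  x <- load_cohort_dir(cohort_dir, table_path)
  atlas <- read_atlas(atlas_path)
  cd <- cohort_densities(x$cohort, x$table, config)
  use <- if (config$apply_correction) cd$corrected else cd$raw
  rec <- x$cohort$recordings
  keep <- rec$condition != "empty_room"
  z <- zscore(use[keep, , drop = FALSE], atlas)
  long <- data.frame(subject_id = rep(rec$subject_id[keep], each = ncol(z)),
                     session = rep(rec$session[keep], each = ncol(z)),
                     condition = rep(rec$condition[keep], each = ncol(z)),
                     region_id = rep(colnames(z), times = nrow(z)),
                     z = num_chr(as.numeric(t(z))),
                     stringsAsFactors = FALSE)
  write_tsv(long, out)
  invisible(out)
}

#' Run classifiers and write Table-style reports
#' @param cohort_dir cohort directory.
#' @param out_dir output directory for model and report TSVs.
#' @param config a [pipeline_config()].
#' @param table_path optional region-table path.
#' @return `out_dir`, invisibly.
#' @export
pipeline_classify <- function(cohort_dir, out_dir, config = pipeline_config(),
                              table_path = NULL) {
  x <- load_cohort_dir(cohort_dir, table_path)
  res <- analyze_cohort(x$cohort, x$table, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (sym in names(res$symptom)) {
    s <- res$symptom[[sym]]
    write_classifier_model(s$model, file.path(out_dir, paste0("model_", sym, ".tsv")))
    write_classification_report(s$report, file.path(out_dir, paste0("report_", sym, ".tsv")))
    if (!is.null(s$second)) {
      write_classification_report(s$second$report,
                                  file.path(out_dir, paste0("report_", sym, "_step2.tsv")))
    }
  }
  for (nm in c("cohort_classifier", "deep_classifier")) {
    if (!is.null(res[[nm]])) {
      write_classifier_model(res[[nm]]$model, file.path(out_dir, paste0(nm, "_model.tsv")))
      write_classification_report(res[[nm]]$report,
                                  file.path(out_dir, paste0(nm, "_report.tsv")))
    }
  }
  invisible(out_dir)
}

#' Test-retest reliability report for a cohort directory
#' @param cohort_dir cohort directory.
#' @param out output TSV.
#' @param config a [pipeline_config()].
#' @param table_path optional region-table path.
#' @return `out`, invisibly.
#' @export
pipeline_reliability <- function(cohort_dir, out, config = pipeline_config(),
                                 table_path = NULL) {
  x <- load_cohort_dir(cohort_dir, table_path)
  res <- analyze_cohort(x$cohort, x$table, config)
  rep_all <- do.call(rbind, res$reliability)
  if (is.null(rep_all)) stop("cohort has no recording pairs for reliability")
  write_reliability_report(rep_all, out)
  invisible(out)
}

#' Cortex vs. rim differential results for a cohort directory
#' @param cohort_dir cohort directory.
#' @param out output TSV.
#' @param config a [pipeline_config()].
#' @param table_path optional region-table path.
#' @return `out`, invisibly.
#' @export
pipeline_differential <- function(cohort_dir, out, config = pipeline_config(),
                                  table_path = NULL) {
  x <- load_cohort_dir(cohort_dir, table_path)
  s <- cohort_differential_summary(x$cohort, x$table, threshold_p = config$chi2_alpha)
  write_differential_results(s, out)
  invisible(out)
}

#' Recompute percentages and p-values for a confusion-table file
#'
#' Reads a TSV with columns `group`, `n_classified_negative`,
#' `n_classified_positive` (first row the clinically negative group, second
#' the positive group; the diagonal holds the correct calls) and writes the
#' same table with `pct_correct` and `p_value` columns appended.
#'
#' @param confusion_path input TSV.
#' @param out output TSV.
#' @param convention binomial tail convention.
#' @return the report, invisibly.
#' @export
pipeline_report <- function(confusion_path, out, convention = "strict") {
  df <- read_tsv(confusion_path)
  need <- c("group", "n_classified_negative", "n_classified_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("confusion file missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) != 2) stop("confusion file must have exactly 2 rows")
  confusion <- as.matrix(df[, c("n_classified_negative", "n_classified_positive")])
  rownames(confusion) <- df$group
  colnames(confusion) <- df$group
  report <- classification_report(confusion, group_labels = df$group,
                                  jackknifed = TRUE, convention = convention)
  write_classification_report(report, out)
  invisible(report)
}

# ---------------------------------------------------------------------------
# CLI dispatcher.

parse_cli_args <- function(argv) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1], "--")) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- argv[i + 1]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: simulate, atlas, zscore, classify, reliability,
#' differential, report. Shared flags: `--config <yaml>`, `--seed <int>`,
#' `--out <path>`, `--cohort <dir>`, `--table <tsv>`, `--atlas <tsv>`,
#' `--spec <yaml>` (simulate), `--confusion <tsv>` (report). Identical
#' config and seed reproduce identical output bytes.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
megdens_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message("usage: megdens <simulate|atlas|zscore|classify|reliability|differential|report> [--options]")
    return(invisible(1L))
  }
  cmd <- argv[1]
  opts <- parse_cli_args(argv[-1])
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config) else pipeline_config()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required flag --", key, call. = FALSE)
    opts[[key]]
  }
  message(sprintf("megdens %s (seed %d)", cmd, config$seed))
  switch(cmd,
    simulate = pipeline_simulate(
      need("out"),
      spec = if (!is.null(opts$spec)) read_cohort_spec(opts$spec),
      seed = if (!is.null(opts$seed)) config$seed),
    atlas = pipeline_atlas(need("cohort"), need("out"), config, opts$table),
    zscore = pipeline_zscore(need("cohort"), need("atlas"), need("out"), config, opts$table),
    classify = pipeline_classify(need("cohort"), need("out"), config, opts$table),
    reliability = pipeline_reliability(need("cohort"), need("out"), config, opts$table),
    differential = pipeline_differential(need("cohort"), need("out"), config, opts$table),
    report = pipeline_report(need("confusion"), need("out"),
                             convention = config$binomial_convention),
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
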