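# Synthetic cohort generator.
#
# Emulates the statistical structure of the upstream solver's per-region
# validated-current counts: a recording's counts are multinomial over the
# partition regions with probabilities proportional to volume times a
# subject-stable log-normal activity latent; totals are log-normal (order
# 5e5 currents per recording) times a session-quality factor shared with the
# same-day empty-room recording; an additive "dark count" multinomial layer
# uses the empty-room propensities of the day; deep-tract counts are thinned
# sums over the white-matter rims each tract overlaps.  Group structure is
# planted multiplicatively on chosen regions, per symptom and per cohort.

#' Specification of a synthetic cohort
#'
#' @param n_subjects_norm,n_subjects_clin cohort sizes (defaults: the study
#'   sizes, 619 normative and 63 clinical baseline recordings).
#' @param followup_fraction fraction of each cohort re-recorded at follow-up.
#' @param total_count_mean expected validated-current count per recording
#'   (default 5e5, the typical per-minute yield of the solver).
#' @param total_count_cv coefficient of variation of recording totals.
#' @param region_activity_base named vector of baseline propensity
#'   multipliers per region id (unnamed regions default to 1).
#' @param symptom_defs list of symptom definitions, each a list with fields
#'   `name`, `prevalence` (in the clinical cohort), `cutoff` (survey score at
#'   or above which a subject screens positive), `effects` (named vector of
#'   multiplicative region effects applied to symptom-positive subjects).
#' @param cohort_effect named vector of multiplicative region effects
#'   distinguishing the clinical cohort.
#' @param dark_fraction expected share of a subject recording's counts that
#'   are dark counts (empty-room false validations); 0 disables the layer.
#' @param session_quality_sd log-scale SD of the session-quality factor
#'   shared by a subject recording and its same-day empty-room recording
#'   (multiplies the totals).
#' @param dark_latent_sd log-scale SD of the per-session, per-region
#'   perturbation of the dark-count propensities, shared by the subject and
#'   empty-room recordings of the day. This is what induces the positive
#'   subject vs. empty-room density correlations the correction targets;
#'   a factor on totals alone cannot, because densities are scale invariant.
#' @param subject_noise_sd log-scale SD of the stable per-subject regional
#'   activity deviations (sets the between-subject spread of densities).
#' @param retest_rho latent stability correlation between baseline and
#'   follow-up regional activity (default 0.45, a typical long-interval
#'   test-retest level).
#' @param tract_thin_base baseline thinning probability mapping overlapped
#'   rim counts to deep-tract counts.
#' @param conditions which recordings to simulate per session.
#' @param seed root seed; all randomness flows through named streams derived
#'   from it, so the same spec and seed reproduce the cohort exactly.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_norm = 619L,
                        n_subjects_clin = 63L,
                        followup_fraction = 0.4,
                        total_count_mean = 5e5,
                        total_count_cv = 0.3,
                        region_activity_base = NULL,
                        symptom_defs = default_symptom_defs(),
                        cohort_effect = default_cohort_effect(),
                        dark_fraction = 0.05,
                        session_quality_sd = 0.3,
                        dark_latent_sd = 0.3,
                        subject_noise_sd = 0.2,
                        retest_rho = 0.45,
                        tract_thin_base = 0.3,
                        conditions = c("rest", "task", "empty_room"),
                        seed = 1L) {
  spec <- list(n_subjects_norm = as.integer(n_subjects_norm),
               n_subjects_clin = as.integer(n_subjects_clin),
               followup_fraction = followup_fraction,
               total_count_mean = total_count_mean,
               total_count_cv = total_count_cv,
               region_activity_base = region_activity_base,
               symptom_defs = symptom_defs,
               cohort_effect = cohort_effect,
               dark_fraction = dark_fraction,
               session_quality_sd = session_quality_sd,
               dark_latent_sd = dark_latent_sd,
               subject_noise_sd = subject_noise_sd,
               retest_rho = retest_rho,
               tract_thin_base = tract_thin_base,
               conditions = conditions,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_subjects_norm >= 0, spec$n_subjects_clin >= 0,
            spec$followup_fraction >= 0, spec$followup_fraction <= 1,
            spec$total_count_mean > 0, spec$total_count_cv >= 0,
            spec$dark_fraction >= 0, spec$dark_fraction < 1,
            spec$session_quality_sd >= 0, spec$dark_latent_sd >= 0,
            spec$subject_noise_sd >= 0,
            spec$retest_rho >= 0, spec$retest_rho <= 1,
            spec$tract_thin_base > 0, spec$tract_thin_base <= 1,
            "rest" %in% spec$conditions)
  if (!is.null(spec$region_activity_base) &&
      any(spec$region_activity_base <= 0)) {
    stop("region_activity_base multipliers must be positive")
  }
  if (any(spec$cohort_effect <= 0)) stop("cohort_effect multipliers must be positive")
  for (sd in spec$symptom_defs) {
    stopifnot(is.character(sd$name), sd$prevalence > 0, sd$prevalence < 1,
              sd$cutoff >= 1)
    if (any(sd$effects <= 0)) stop("symptom effect multipliers must be positive: ", sd$name)
  }
  invisible(spec)
}

#' Default symptom definitions
#'
#' Four screened symptoms with the study's survey cut-offs (insomnia severity
#' at 15; the three psychological-distress scales at 63) and clinical-cohort
#' prevalences matching the study's screened-positive rates. Affected regions
#' and effect directions follow the strongest classifier contributors
#' reported for each symptom; the multiplicative magnitudes are the
#' generator's choice.
#'
#' @return list of symptom definitions for [cohort_spec()].
#' @export
default_symptom_defs <- function() {
  list(
    list(name = "insomnia", prevalence = 0.47, cutoff = 15L,
         effects = c(L_hippocampus = 0.70, L_insula = 0.75, R_bankssts = 0.75,
                     R_hippocampus = 1.30)),
    list(name = "somatization", prevalence = 0.43, cutoff = 63L,
         effects = c(L_amygdala = 1.30, L_lateralorbitofrontal = 1.30,
                     L_superiorfrontal = 0.75)),
    list(name = "depression", prevalence = 0.31, cutoff = 63L,
         effects = c(R_thalamus = 1.40, L_inferiorparietal = 0.70,
                     R_lateraloccipital = 0.70)),
    list(name = "anxiety", prevalence = 0.46, cutoff = 63L,
         effects = c(L_rostralanteriorcingulate = 1.40, R_insula = 1.40,
                     L_thalamus = 0.70)))
}

#' Default clinical-cohort region effects
#'
#' Multiplicative regional effects distinguishing the clinical cohort,
#' directions following the strongest cohort-classifier contributors
#' (bilateral thalamic reduction, brain-stem and fusiform elevation, and
#' deep-tract involvement); magnitudes are the generator's choice.
#'
#' @return named vector of multipliers.
#' @export
default_cohort_effect <- function() {
  c(brainstem = 1.40, L_thalamus = 0.70, R_thalamus = 0.70,
    R_cerebellum = 1.35, L_caudate = 0.72, R_hippocampus = 0.72,
    L_fusiform = 1.35, L_isthmuscingulate = 1.35, R_middletemporal = 0.72,
    L_lingual = 1.35,
    L_cst = 1.35, R_ilf = 1.35, R_cst = 1.30, fminor = 1.30)
}

#' Read a cohort spec from a flat YAML (or JSON) file
#'
#' Keys mirror the [cohort_spec()] arguments; `symptom_defs` is a list of
#' maps with `name`, `prevalence`, `cutoff` and an `effects` map;
#' `cohort_effect` and `region_activity_base` are maps region id -> value.
#'
#' @param path config file path.
#' @return a validated [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("invalid cohort spec key(s): ",
                            paste(unknown, collapse = ", "))
  for (key in c("region_activity_base", "cohort_effect")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$symptom_defs)) {
    raw$symptom_defs <- lapply(raw$symptom_defs, function(sd) {
      sd$effects <- unlist(sd$effects)
      sd$cutoff <- as.integer(sd$cutoff)
      sd
    })
  }
  if (!is.null(raw$conditions)) raw$conditions <- unlist(raw$conditions)
  do.call(cohort_spec, raw)
}

#' Write a cohort spec as YAML
#' @param spec a [cohort_spec()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$symptom_defs <- lapply(x$symptom_defs, function(sd) {
    sd$effects <- as.list(sd$effects)
    sd
  })
  for (key in c("region_activity_base", "cohort_effect")) {
    if (!is.null(x[[key]])) x[[key]] <- as.list(x[[key]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

lognormal_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic tract -> rim overlap: tract j overlaps a block of 4 rims in
# table order (cyclic), a stand-in for tracts running beneath several parcels.
tract_overlap_map <- function(table, rims_per_tract = 4L) {
  tracts <- regions_of_class(table, "deep_tract")
  rims <- regions_of_class(table, "wm_rim")
  n <- length(rims)
  out <- lapply(seq_along(tracts), function(j) {
    idx <- ((j - 1L) * rims_per_tract + seq_len(rims_per_tract) - 1L) %% n + 1L
    rims[idx]
  })
  names(out) <- tracts
  out
}

#' Generate a synthetic cohort of recordings
#'
#' @param spec a [cohort_spec()].
#' @param table a [region_table()]; defaults to [default_region_table()]
#'   built from the spec's seed.
#' @return an object of class `meg_cohort`: a list with `subjects`
#'   (data.frame of per-subject metadata and survey scores), `recordings`
#'   (data.frame keyed by `recording_id` with subject, cohort, session,
#'   condition and `count_total` over the partition regions), `counts`
#'   (integer matrix, recordings x regions), `region_ids`, and the `spec`.
#' @export
generate_cohort <- function(spec, table = default_region_table(seed = spec$seed)) {
  validate_cohort_spec(spec)
  seed <- spec$seed
  ids_all <- table$region_id
  part <- partition_regions(table)
  tracts <- regions_of_class(table, "deep_tract")
  overlap <- tract_overlap_map(table)
  vols <- stats::setNames(table$volume_mm3, ids_all)

  n_norm <- spec$n_subjects_norm
  n_clin <- spec$n_subjects_clin
  n_sub <- n_norm + n_clin
  subject_id <- c(sprintf("norm%03d", seq_len(n_norm)),
                  sprintf("clin%03d", seq_len(n_clin)))
  cohort_of <- c(rep("norm", n_norm), rep("clin", n_clin))
  sym_names <- vapply(spec$symptom_defs, `[[`, "", "name")

  base_mult <- rep(1, length(ids_all))
  names(base_mult) <- ids_all
  if (!is.null(spec$region_activity_base)) {
    known <- intersect(names(spec$region_activity_base), ids_all)
    base_mult[known] <- spec$region_activity_base[known]
  }

  # --- surveys stream: symptom latents, status and integer scores ----------
  surveys <- with_stream(seed, "surveys", {
    status <- matrix(FALSE, n_sub, length(sym_names),
                     dimnames = list(subject_id, sym_names))
    scores <- matrix(NA_integer_, n_sub, length(sym_names),
                     dimnames = list(subject_id, sym_names))
    age <- numeric(n_sub)
    for (i in seq_len(n_sub)) {
      age[i] <- if (cohort_of[i] == "norm") stats::runif(1, 18, 87) else stats::runif(1, 21, 60)
      if (cohort_of[i] == "clin") {
        for (k in seq_along(spec$symptom_defs)) {
          sd_k <- spec$symptom_defs[[k]]
          L <- stats::rnorm(1)
          thr <- stats::qnorm(1 - sd_k$prevalence)
          # Integer score sharing the latent: >= cutoff exactly when L >= thr.
          scores[i, k] <- max(0L, as.integer(sd_k$cutoff + floor(6 * (L - thr))))
          status[i, k] <- L >= thr
        }
      }
    }
    list(status = status, scores = scores, age = age)
  })

  # --- latents stream: subject-stable log-activity and session dark jitter -
  lat <- with_stream(seed, "latents", {
    eps_base <- matrix(stats::rnorm(n_sub * length(ids_all), 0, spec$subject_noise_sd),
                       n_sub, length(ids_all), dimnames = list(subject_id, ids_all))
    eps_new <- matrix(stats::rnorm(n_sub * length(ids_all), 0, spec$subject_noise_sd),
                      n_sub, length(ids_all), dimnames = list(subject_id, ids_all))
    rho <- spec$retest_rho
    eps_fu <- rho * eps_base + sqrt(1 - rho^2) * eps_new
    # Per-session dark-propensity perturbation over partition regions.
    delta_base <- matrix(stats::rnorm(n_sub * length(part), 0, spec$dark_latent_sd),
                         n_sub, length(part), dimnames = list(subject_id, part))
    delta_fu <- matrix(stats::rnorm(n_sub * length(part), 0, spec$dark_latent_sd),
                       n_sub, length(part), dimnames = list(subject_id, part))
    list(eps = list(baseline = eps_base, followup = eps_fu),
         delta = list(baseline = delta_base, followup = delta_fu))
  })

  # Fixed multiplicative effects per subject (cohort + symptom), log scale.
  fixed_log <- matrix(rep(log(base_mult), each = n_sub), n_sub, length(ids_all),
                      dimnames = list(subject_id, ids_all))
  ce <- spec$cohort_effect
  if (length(ce) && n_clin > 0) {
    known <- intersect(names(ce), ids_all)
    for (r in known) {
      fixed_log[cohort_of == "clin", r] <- fixed_log[cohort_of == "clin", r] + log(ce[[r]])
    }
  }
  for (k in seq_along(spec$symptom_defs)) {
    eff <- spec$symptom_defs[[k]]$effects
    known <- intersect(names(eff), ids_all)
    pos <- surveys$status[, k]
    for (r in known) fixed_log[pos, r] <- fixed_log[pos, r] + log(eff[[r]])
  }

  # --- totals stream: follow-up membership, session quality, totals --------
  has_empty <- "empty_room" %in% spec$conditions
  has_task <- "task" %in% spec$conditions
  totals <- with_stream(seed, "totals", {
    fu <- stats::runif(n_sub) < spec$followup_fraction
    lp <- lognormal_pars(spec$total_count_mean, max(spec$total_count_cv, 1e-12))
    draw_total <- function(n, q) {
      if (spec$total_count_cv == 0) round(spec$total_count_mean * q)
      else round(stats::rlnorm(n, lp$meanlog, lp$sdlog) * q)
    }
    sess <- list()
    for (s in c("baseline", "followup")) {
      q <- exp(stats::rnorm(n_sub, 0, spec$session_quality_sd))
      sess[[s]] <- list(
        q = q,
        rest = draw_total(n_sub, q),
        task = draw_total(n_sub, q),
        empty = if (spec$dark_fraction > 0)
          round(stats::rlnorm(n_sub, lognormal_pars(
            spec$total_count_mean * spec$dark_fraction,
            max(spec$total_count_cv, 1e-12))$meanlog,
            lp$sdlog) * q)
        else rep(0, n_sub))
    }
    list(fu = fu, sess = sess)
  })

  sessions_of <- function(i) if (totals$fu[i]) c("baseline", "followup") else "baseline"

  # --- multinomials stream: the counts themselves --------------------------
  rec_meta <- list()
  rec_counts <- list()
  with_stream(seed, "multinomials", {
    vols_part <- vols[part]
    for (i in seq_len(n_sub)) {
      for (s in sessions_of(i)) {
        latent <- fixed_log[i, ] + lat$eps[[s]][i, ]
        p_true <- vols_part * exp(latent[part])
        p_true <- p_true / sum(p_true)
        p_dark <- vols_part * exp(lat$delta[[s]][i, ])
        p_dark <- p_dark / sum(p_dark)
        draw_rec <- function(total, condition) {
          counts_part <- integer(length(part))
          if (condition == "empty_room") {
            if (total > 0) counts_part <- as.integer(stats::rmultinom(1, total, p_dark))
          } else {
            n_dark <- if (spec$dark_fraction > 0) stats::rbinom(1, total, spec$dark_fraction) else 0L
            n_true <- total - n_dark
            counts_part <- as.integer(stats::rmultinom(1, n_true, p_true))
            if (n_dark > 0) counts_part <- counts_part +
                as.integer(stats::rmultinom(1, n_dark, p_dark))
          }
          names(counts_part) <- part
          # Deep tracts: thinned sums over the rims each tract overlaps.
          tract_counts <- integer(length(tracts))
          names(tract_counts) <- tracts
          for (j in seq_along(tracts)) {
            pool <- sum(counts_part[overlap[[j]]])
            p_thin <- min(1, spec$tract_thin_base * exp(latent[tracts[j]]))
            if (pool > 0) tract_counts[j] <- stats::rbinom(1, pool, p_thin)
          }
          full <- integer(length(ids_all))
          names(full) <- ids_all
          full[part] <- counts_part
          full[tracts] <- tract_counts
          full
        }
        conds <- c("rest", if (has_task) "task", if (has_empty) "empty_room")
        tot_of <- c(rest = totals$sess[[s]]$rest[i],
                    task = totals$sess[[s]]$task[i],
                    empty_room = totals$sess[[s]]$empty[i])
        for (cond in conds) {
          cnt <- draw_rec(tot_of[[cond]], cond)
          rid <- paste(subject_id[i], s, cond, sep = ":")
          rec_meta[[length(rec_meta) + 1L]] <- data.frame(
            recording_id = rid, subject_id = subject_id[i],
            cohort = cohort_of[i], session = s, condition = cond,
            count_total = sum(cnt[part]), stringsAsFactors = FALSE)
          rec_counts[[length(rec_counts) + 1L]] <- cnt
        }
      }
    }
  })

  if (length(rec_meta) == 0) {
    recordings <- data.frame(recording_id = character(), subject_id = character(),
                             cohort = character(), session = character(),
                             condition = character(), count_total = integer(),
                             stringsAsFactors = FALSE)
    counts <- matrix(integer(), 0, length(ids_all), dimnames = list(NULL, ids_all))
  } else {
    recordings <- do.call(rbind, rec_meta)
    counts <- do.call(rbind, rec_counts)
    rownames(counts) <- recordings$recording_id
    storage.mode(counts) <- "integer"
  }

  subjects <- data.frame(subject_id = subject_id, cohort = cohort_of,
                         age = surveys$age, stringsAsFactors = FALSE)
  for (k in seq_along(sym_names)) subjects[[sym_names[k]]] <- surveys$scores[, k]

  structure(list(subjects = subjects, recordings = recordings, counts = counts,
                 region_ids = ids_all, spec = spec),
            class = "meg_cohort")
}

#' @export
print.meg_cohort <- function(x, ...) {
  cat(sprintf("meg_cohort: %d subjects (%d norm, %d clin), %d recordings, %d regions\n",
              nrow(x$subjects), sum(x$subjects$cohort == "norm"),
              sum(x$subjects$cohort == "clin"), nrow(x$recordings),
              length(x$region_ids)))
  invisible(x)
}

#' Extract a counts matrix for one session/condition
#'
#' @param cohort a `meg_cohort`.
#' @param session "baseline" or "followup".
#' @param condition "rest", "task" or "empty_room".
#' @param cohort_group optionally restrict to "norm" or "clin" subjects.
#' @return integer matrix subjects x regions, rownames = subject ids.
#' @export
counts_matrix <- function(cohort, session = "baseline", condition = "rest",
                          cohort_group = NULL) {
  sel <- cohort$recordings$session == session &
    cohort$recordings$condition == condition
  if (!is.null(cohort_group)) sel <- sel & cohort$recordings$cohort %in% cohort_group
  m <- cohort$counts[sel, , drop = FALSE]
  rownames(m) <- cohort$recordings$subject_id[sel]
  m
}

#' Dichotomize symptom survey scores at clinical cut-offs
#'
#' A subject screens positive when the score is at or above the cut-off
#' (score >= cutoff). Missing scores yield the explicit status "missing".
#'
#' @param subjects data.frame with `subject_id` and one integer score column
#'   per symptom (as in a `meg_cohort`'s `subjects`).
#' @param cutoffs named integer vector, symptom name -> cut-off (default:
#'   insomnia 15, somatization/depression/anxiety 63).
#' @return data.frame with `subject_id` and one status column per symptom,
#'   each a factor with levels negative, positive, missing.
#' @export
dichotomize_scores <- function(subjects,
                               cutoffs = c(insomnia = 15L, somatization = 63L,
                                           depression = 63L, anxiety = 63L)) {
  miss <- setdiff(names(cutoffs), names(subjects))
  if (length(miss)) stop("no score column for symptom: ", paste(miss, collapse = ", "))
  out <- data.frame(subject_id = subjects$subject_id, stringsAsFactors = FALSE)
  for (sym in names(cutoffs)) {
    sc <- subjects[[sym]]
    st <- ifelse(is.na(sc), "missing",
                 ifelse(sc >= cutoffs[[sym]], "positive", "negative"))
    out[[sym]] <- factor(st, levels = c("negative", "positive", "missing"))
  }
  out
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `subjects.tsv` (subject_id, cohort, age, one score column per
#' symptom) and `counts.tsv` (subject_id, cohort, session, condition,
#' region_id, count) in long form.
#'
#' @param cohort a `meg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subj <- cohort$subjects
  subj$age <- num_chr(subj$age)
  write_tsv(subj, file.path(dir, "subjects.tsv"))
  rec <- cohort$recordings
  n_reg <- length(cohort$region_ids)
  long <- data.frame(
    subject_id = rep(rec$subject_id, each = n_reg),
    cohort = rep(rec$cohort, each = n_reg),
    session = rep(rec$session, each = n_reg),
    condition = rep(rec$condition, each = n_reg),
    region_id = rep(cohort$region_ids, times = nrow(rec)),
    count = as.integer(t(cohort$counts)),
    stringsAsFactors = FALSE)
  write_tsv(long, file.path(dir, "counts.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `subjects.tsv` and `counts.tsv`.
#' @param table optional [region_table()] used to fix the region ordering and
#'   recompute `count_total` over the partition regions; when omitted the
#'   region order of the file is kept and `count_total` sums all non-tract
#'   regions cannot be distinguished, so a table is recommended.
#' @return a `meg_cohort` (without a generator `spec`).
#' @export
read_cohort <- function(dir, table = NULL) {
  subj_path <- file.path(dir, "subjects.tsv")
  cnt_path <- file.path(dir, "counts.tsv")
  if (!file.exists(subj_path) || !file.exists(cnt_path)) {
    stop("cohort directory must contain subjects.tsv and counts.tsv: ", dir)
  }
  subjects <- read_tsv(subj_path)
  long <- read_tsv(cnt_path)
  bad <- which(!is.finite(long$count) | long$count < 0 | long$count != floor(long$count))
  if (length(bad)) {
    stop("malformed count at counts.tsv data row ", bad[1],
         " (region ", long$region_id[bad[1]], "): ", long$count[bad[1]])
  }
  if (nrow(long) == 0) {
    return(structure(list(subjects = subjects,
                          recordings = data.frame(), counts = matrix(integer(), 0, 0),
                          region_ids = character(), spec = NULL),
                     class = "meg_cohort"))
  }
  region_ids <- if (is.null(table)) unique(long$region_id) else table$region_id
  key <- paste(long$subject_id, long$session, long$condition, sep = ":")
  rec_ids <- unique(key)
  counts <- matrix(0L, length(rec_ids), length(region_ids),
                   dimnames = list(rec_ids, region_ids))
  counts[cbind(match(key, rec_ids), match(long$region_id, region_ids))] <-
    as.integer(long$count)
  first <- !duplicated(key)
  part_ids <- if (is.null(table)) region_ids else partition_regions(table)
  recordings <- data.frame(recording_id = rec_ids,
                           subject_id = long$subject_id[first],
                           cohort = long$cohort[first],
                           session = long$session[first],
                           condition = long$condition[first],
                           count_total = as.integer(rowSums(counts[, part_ids, drop = FALSE])),
                           stringsAsFactors = FALSE)
  structure(list(subjects = subjects, recordings = recordings, counts = counts,
                 region_ids = region_ids, spec = NULL),
            class = "meg_cohort")
}
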