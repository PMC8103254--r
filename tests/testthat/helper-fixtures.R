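# Shared fixtures: a hand-sized region table and fast cohort specs.

# 12-region table with round volumes so expected densities are hand
# computable: 4 cortical parcels (paired rims), 2 subcortical, 2 tracts.
tiny_table <- function() {
  df <- data.frame(
    region_id = c("L_ctx1", "L_ctx1_wm", "L_ctx2", "L_ctx2_wm",
                  "R_ctx1", "R_ctx1_wm", "R_ctx2", "R_ctx2_wm",
                  "L_sub", "R_sub", "L_tract", "fmid"),
    name = paste("region", 1:12),
    reg_class = c(rep(c("cortical", "wm_rim"), 4),
                  "subcortical", "subcortical", "deep_tract", "deep_tract"),
    hemisphere = c(rep("L", 4), rep("R", 4), "L", "R", "L", "midline"),
    volume_mm3 = c(4000, 1000, 6000, 2000, 5000, 1500, 7000, 2500,
                   3000, 3000, 1200, 800),
    paired_region_id = c("L_ctx1_wm", "L_ctx1", "L_ctx2_wm", "L_ctx2",
                         "R_ctx1_wm", "R_ctx1", "R_ctx2_wm", "R_ctx2",
                         NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  region_table(df)
}

# Small, fast cohort spec; overrides applied on top.
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects_norm = 25L, n_subjects_clin = 15L,
                   followup_fraction = 0.5, total_count_mean = 2e4,
                   total_count_cv = 0.2, seed = 11L)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# Spec with no planted structure and no noise layers: counts are exactly
# volume-proportional multinomials, so group labels are exchangeable and
# the chi-square differential null holds.
null_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects_norm = 25L, n_subjects_clin = 25L,
                   followup_fraction = 0, total_count_mean = 2e4,
                   total_count_cv = 0.2,
                   symptom_defs = list(), cohort_effect = numeric(0),
                   dark_fraction = 0, session_quality_sd = 0,
                   dark_latent_sd = 0, subject_noise_sd = 0,
                   conditions = c("rest", "empty_room"), seed = 5L)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}
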