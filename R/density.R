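# Regional current density, the normative atlas and z-scoring.
#
# Density normalizes a region's count fraction by its volume fraction:
#   rho[r] = (count[r] / count_total) / (vol[r] / vol_total)
# so rho = 1 everywhere when currents are uniformly distributed through the
# brain, and rho is invariant to record length and overall solver yield.
# The atlas holds the per-region mean and sample SD of density in a
# reference cohort; z = (rho - mean) / sd.  Because counts are non-negative,
# an uncorrected z-score can never fall below the "floor" -mean/sd, with
# equality exactly at count zero.

#' Compute regional current densities
#'
#' @param counts named non-negative integer vector (one recording) or a
#'   matrix recordings x regions; missing regions are treated as count 0.
#' @param table a [region_table()]. The denominator `count_total` sums the
#'   partition (cortical + rim + subcortical) regions only; deep-tract
#'   densities use the same whole-brain totals.
#' @return numeric vector or matrix of densities, one column per region of
#'   `table`, same shape class as the input.
#' @export
compute_density <- function(counts, table) {
  one <- is.null(dim(counts))
  m <- if (one) matrix(counts, 1, dimnames = list(NULL, names(counts))) else counts
  if (is.null(colnames(m))) stop("counts must be named by region_id")
  unknown <- setdiff(colnames(m), table$region_id)
  if (length(unknown)) stop("counts name unknown regions: ",
                            paste(unknown, collapse = ", "))
  full <- matrix(0, nrow(m), nrow(table),
                 dimnames = list(rownames(m), table$region_id))
  full[, colnames(m)] <- m
  part <- partition_regions(table)
  count_total <- rowSums(full[, part, drop = FALSE])
  if (any(count_total == 0)) {
    stop("count_total is zero (density undefined) for recording: ",
         paste(utils::head(which(count_total == 0)), collapse = ", "))
  }
  vol_frac <- table$volume_mm3 / vol_total(table)
  rho <- (full / count_total) / rep(vol_frac, each = nrow(full))
  if (one) rho[1, ] else rho
}

#' Build a normative atlas from reference densities
#'
#' @param densities matrix of densities, reference recordings x regions
#'   (rows are typically one cohort's baseline resting recordings).
#' @return object of class `normative_atlas`: data.frame with `region_id`,
#'   `mean_rho`, `sd_rho` (sample SD, n-1 denominator), `n_reference` and
#'   `floor_z` = (0 - mean)/sd, the lowest z attainable from a zero count.
#' @export
build_atlas <- function(densities) {
  if (is.null(dim(densities)) || nrow(densities) < 3) {
    stop("need at least 3 reference densities to build an atlas")
  }
  mean_rho <- colMeans(densities)
  sd_rho <- apply(densities, 2, stats::sd)
  zero_var <- colnames(densities)[sd_rho <= 0 | !is.finite(sd_rho)]
  if (length(zero_var)) {
    stop("zero variance in reference densities for region: ",
         paste(zero_var, collapse = ", "))
  }
  structure(data.frame(region_id = colnames(densities),
                       mean_rho = unname(mean_rho),
                       sd_rho = unname(sd_rho),
                       n_reference = nrow(densities),
                       floor_z = unname(-mean_rho / sd_rho),
                       stringsAsFactors = FALSE),
            class = c("normative_atlas", "data.frame"))
}

#' Transform densities to atlas z-scores
#'
#' @param densities named vector (one recording) or matrix recordings x
#'   regions.
#' @param atlas a [build_atlas()] result covering every region present.
#' @return z-scores with the same shape: z = (rho - mean_rho)/sd_rho.
#' @export
zscore <- function(densities, atlas) {
  one <- is.null(dim(densities))
  m <- if (one) matrix(densities, 1, dimnames = list(NULL, names(densities))) else densities
  missing_r <- setdiff(colnames(m), atlas$region_id)
  if (length(missing_r)) stop("atlas does not cover region: ",
                              paste(missing_r, collapse = ", "))
  i <- match(colnames(m), atlas$region_id)
  z <- sweep(sweep(m, 2, atlas$mean_rho[i]), 2, atlas$sd_rho[i], `/`)
  if (one) z[1, ] else z
}

#' Write a normative atlas as TSV
#' @param atlas a `normative_atlas`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  df <- as.data.frame(atlas)
  for (cl in c("mean_rho", "sd_rho", "floor_z")) df[[cl]] <- num_chr(df[[cl]])
  write_tsv(df, path)
}

#' Read a normative atlas written by [write_atlas()]
#' @param path TSV path.
#' @return a `normative_atlas`.
#' @export
read_atlas <- function(path) {
  df <- read_tsv(path, colClasses = c(region_id = "character"))
  need <- c("region_id", "mean_rho", "sd_rho", "n_reference", "floor_z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atlas file missing columns: ", paste(miss, collapse = ", "))
  structure(df[, need], class = c("normative_atlas", "data.frame"))
}

#' @export
print.normative_atlas <- function(x, ...) {
  cat(sprintf("normative_atlas: %d regions, n_reference = %d, mean floor z = %.2f\n",
              nrow(x), x$n_reference[1], mean(x$floor_z)))
  invisible(x)
}
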