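# Empty-room (dark count) model and correction.
#
# The upstream solver validates a non-trivial number of currents from
# empty-room recordings, and the regional densities it extracts with the
# subject present correlate with the same-day empty-room densities.  The
# correction subtracts the empty-room density weighted by that per-region
# correlation:
#   rho_corrected[r] = rho[r] - corr[r] * rho_empty[r]
# When subject and empty-room densities have equal variance across the
# cohort this coincides exactly with the regression residual, so corrected
# densities are uncorrelated with the empty-room densities in expectation.

#' Fit the per-region subject vs. empty-room correlation model
#'
#' @param subject_densities matrix subjects x regions of densities from
#'   recordings with the subject present.
#' @param empty_densities matrix of the paired same-day empty-room
#'   densities; rows must be the same subjects in the same order (checked
#'   via rownames when present).
#' @return object of class `empty_room_model`: data.frame with `region_id`,
#'   `corr` (Pearson, across pairs) and `n_pairs`. Regions where either
#'   vector has zero variance get `corr = 0` with a warning, so no
#'   correction is applied there.
#' @export
fit_empty_room_model <- function(subject_densities, empty_densities) {
  if (!identical(dim(subject_densities), dim(empty_densities))) {
    stop("subject and empty-room density matrices must have identical shape")
  }
  if (!is.null(rownames(subject_densities)) && !is.null(rownames(empty_densities)) &&
      !identical(rownames(subject_densities), rownames(empty_densities))) {
    stop("subject and empty-room recordings are not paired by subject")
  }
  n <- nrow(subject_densities)
  if (n < 3) stop("need at least 3 paired recordings")
  sd_s <- apply(subject_densities, 2, stats::sd)
  sd_e <- apply(empty_densities, 2, stats::sd)
  degenerate <- sd_s == 0 | sd_e == 0
  corr <- numeric(ncol(subject_densities))
  ok <- !degenerate
  if (any(ok)) {
    corr[ok] <- vapply(which(ok), function(j)
      stats::cor(subject_densities[, j], empty_densities[, j]), numeric(1))
  }
  if (any(degenerate)) {
    warning("zero variance for ", sum(degenerate),
            " region(s); corr set to 0 (no correction applied there)")
  }
  structure(data.frame(region_id = colnames(subject_densities),
                       corr = corr, n_pairs = n, stringsAsFactors = FALSE),
            class = c("empty_room_model", "data.frame"))
}

#' Apply the dark-count correction to densities
#'
#' @param densities named vector or matrix of subject densities.
#' @param empty_densities the paired same-day empty-room densities, same
#'   shape and region names.
#' @param model an [fit_empty_room_model()] result covering the regions.
#' @return corrected densities, same shape. Negative values are permitted;
#'   the result carries an attribute `n_negative` counting them.
#' @export
correct_density <- function(densities, empty_densities, model) {
  one <- is.null(dim(densities))
  m <- if (one) matrix(densities, 1, dimnames = list(NULL, names(densities))) else densities
  e <- if (is.null(dim(empty_densities))) {
    matrix(empty_densities, 1, dimnames = list(NULL, names(empty_densities)))
  } else empty_densities
  if (!identical(dim(m), dim(e)) || !identical(colnames(m), colnames(e))) {
    stop("missing or mismatched same-day empty-room densities")
  }
  i <- match(colnames(m), model$region_id)
  if (anyNA(i)) stop("empty-room model does not cover region: ",
                     paste(colnames(m)[is.na(i)], collapse = ", "))
  out <- m - sweep(e, 2, model$corr[i], `*`)
  attr(out, "n_negative") <- sum(out < 0)
  if (one) {
    v <- out[1, ]
    attr(v, "n_negative") <- attr(out, "n_negative")
    v
  } else out
}

#' Write an empty-room model as TSV
#' @param model an `empty_room_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_empty_room_model <- function(model, path) {
  df <- as.data.frame(model)
  df$corr <- num_chr(df$corr)
  write_tsv(df, path)
}

#' Read an empty-room model written by [write_empty_room_model()]
#' @param path TSV path.
#' @return an `empty_room_model`.
#' @export
read_empty_room_model <- function(path) {
  df <- read_tsv(path, colClasses = c(region_id = "character"))
  miss <- setdiff(c("region_id", "corr", "n_pairs"), names(df))
  if (length(miss)) stop("empty-room model file missing columns: ",
                         paste(miss, collapse = ", "))
  structure(df, class = c("empty_room_model", "data.frame"))
}
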