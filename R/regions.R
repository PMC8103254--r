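# Region table: the parcellation every other module keys on.
#
# The default parcellation mirrors an automated anatomical segmentation:
# 68 cortical parcels (34 per hemisphere), a <=5 mm white-matter rim paired
# with each cortical parcel, 17 subcortical structures, and 18 deep
# white-matter tracts.  The cortical + rim + subcortical set partitions the
# brain volume; the deep tracts overlap white matter and are excluded from
# the partition, although their densities use the whole-brain totals.

REG_CLASSES <- c("cortical", "wm_rim", "subcortical", "deep_tract")
PARTITION_CLASSES <- c("cortical", "wm_rim", "subcortical")

# Desikan-Killiany-style cortical parcel names (34 per hemisphere).
DK_CORTICAL <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

# Subcortical structures: 8 bilateral plus brain stem = 17.
SUBCORTICAL_BILATERAL <- c("accumbens", "amygdala", "caudate", "cerebellum",
                           "hippocampus", "pallidum", "putamen", "thalamus")

# Deep white-matter tracts: 2 commissural plus 8 bilateral = 18.
TRACTS_BILATERAL <- c("atr", "cab", "ccg", "cst", "ilf", "slfp", "slft", "unc")
TRACTS_MIDLINE <- c("fmajor", "fminor")

REGION_COLUMNS <- c("region_id", "name", "reg_class", "hemisphere",
                    "volume_mm3", "paired_region_id")

#' Construct and validate a region table
#'
#' @param regions data.frame with columns `region_id`, `name`, `reg_class`
#'   (one of cortical, wm_rim, subcortical, deep_tract), `hemisphere`
#'   (L, R or midline), `volume_mm3`, `paired_region_id` (`NA` unless the
#'   region is cortical or a white-matter rim).
#' @param vol_total_mm3 whole-brain volume. Defaults to the sum of the
#'   partition regions (cortical + rim + subcortical); if supplied it must
#'   agree with that sum to 1e-9 relative.
#' @return an object of class `region_table`: the validated data.frame with
#'   attribute `vol_total_mm3`.
#' @export
region_table <- function(regions, vol_total_mm3 = NULL) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REGION_COLUMNS, names(regions))
  if (length(missing_cols)) {
    stop("region table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  regions <- regions[, REGION_COLUMNS]
  regions$paired_region_id[!is.na(regions$paired_region_id) &
                             regions$paired_region_id == ""] <- NA_character_

  dup <- regions$region_id[duplicated(regions$region_id)]
  if (length(dup)) stop("duplicate region_id: ", paste(unique(dup), collapse = ", "))
  bad_class <- setdiff(unique(regions$reg_class), REG_CLASSES)
  if (length(bad_class)) stop("unknown reg_class: ", paste(bad_class, collapse = ", "))
  bad_hemi <- setdiff(unique(regions$hemisphere), c("L", "R", "midline"))
  if (length(bad_hemi)) stop("unknown hemisphere: ", paste(bad_hemi, collapse = ", "))
  nonpos <- regions$region_id[!is.finite(regions$volume_mm3) | regions$volume_mm3 <= 0]
  if (length(nonpos)) stop("non-positive volume_mm3 for region: ",
                           paste(nonpos, collapse = ", "))

  paired_cls <- regions$reg_class %in% c("cortical", "wm_rim")
  unpaired <- regions$region_id[paired_cls & is.na(regions$paired_region_id)]
  if (length(unpaired)) stop("cortical/wm_rim region lacks paired_region_id: ",
                             paste(unpaired, collapse = ", "))
  overpaired <- regions$region_id[!paired_cls & !is.na(regions$paired_region_id)]
  if (length(overpaired)) stop("paired_region_id set for non cortical/wm_rim region: ",
                               paste(overpaired, collapse = ", "))

  # Pairing must be a symmetric bijection between the cortical and rim sets.
  idx <- match(regions$paired_region_id[paired_cls], regions$region_id)
  if (anyNA(idx)) {
    bad <- regions$region_id[paired_cls][is.na(idx)]
    stop("paired_region_id not found in table for region: ",
         paste(bad, collapse = ", "))
  }
  partner_class <- regions$reg_class[idx]
  own_class <- regions$reg_class[paired_cls]
  cross <- (own_class == "cortical" & partner_class != "wm_rim") |
    (own_class == "wm_rim" & partner_class != "cortical")
  if (any(cross)) stop("pairing must link cortical with wm_rim regions; offending region: ",
                       paste(regions$region_id[paired_cls][cross], collapse = ", "))
  back <- regions$paired_region_id[idx]
  asym <- back != regions$region_id[paired_cls]
  if (any(asym)) stop("pairing is not symmetric for region: ",
                      paste(regions$region_id[paired_cls][asym], collapse = ", "))

  part_sum <- sum(regions$volume_mm3[regions$reg_class %in% PARTITION_CLASSES])
  if (is.null(vol_total_mm3)) {
    vol_total_mm3 <- part_sum
  } else if (abs(part_sum - vol_total_mm3) > 1e-9 * vol_total_mm3) {
    stop(sprintf(paste0("partition volume violation: cortical+wm_rim+subcortical ",
                        "volumes sum to %.6f mm3 but vol_total_mm3 = %.6f"),
                 part_sum, vol_total_mm3))
  }

  rownames(regions) <- NULL
  structure(regions, vol_total_mm3 = vol_total_mm3, class = c("region_table", "data.frame"))
}

#' Whole-brain volume of a region table
#' @param table a `region_table`.
#' @return the whole-brain volume in mm3 (partition regions only).
#' @export
vol_total <- function(table) attr(table, "vol_total_mm3")

#' Region ids of the partition (cortical + rim + subcortical) regions
#' @param table a `region_table`.
#' @return character vector of region ids.
#' @export
partition_regions <- function(table) {
  table$region_id[table$reg_class %in% PARTITION_CLASSES]
}

#' Region ids by class
#' @param table a `region_table`.
#' @param classes subset of cortical, wm_rim, subcortical, deep_tract.
#' @return character vector of region ids.
#' @export
regions_of_class <- function(table, classes) {
  stopifnot(all(classes %in% REG_CLASSES))
  table$region_id[table$reg_class %in% classes]
}

#' Load a region table from tab-separated text
#'
#' The file must carry a header row with the columns `region_id`, `name`,
#' `reg_class`, `hemisphere`, `volume_mm3`, `paired_region_id` (empty
#' allowed). An optional comment line `# vol_total_mm3: <x>` pins the
#' whole-brain volume used in the partition check.
#'
#' @param path path to the TSV file.
#' @return a validated [region_table()].
#' @export
load_region_table <- function(path) {
  if (!file.exists(path)) stop("region table file not found: ", path)
  header <- readLines(path, n = 5)
  vt <- NULL
  m <- regmatches(header, regexec("^#\\s*vol_total_mm3:\\s*([0-9.eE+-]+)", header))
  hit <- vapply(m, length, 1L) == 2
  if (any(hit)) vt <- as.numeric(m[hit][[1]][2])
  df <- read_tsv(path, colClasses = c(
    region_id = "character", name = "character", reg_class = "character",
    hemisphere = "character", volume_mm3 = "numeric",
    paired_region_id = "character"))
  region_table(df, vol_total_mm3 = vt)
}

#' Write a region table as tab-separated text
#'
#' Volumes are written with 17 significant digits so a write/load round trip
#' reproduces the table bit-exactly.
#'
#' @param table a `region_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_region_table <- function(table, path) {
  df <- as.data.frame(table)
  df$volume_mm3 <- num_chr(df$volume_mm3)
  df$paired_region_id[is.na(df$paired_region_id)] <- ""
  write_tsv(df, path,
            header_comments = sprintf("vol_total_mm3: %s", num_chr(vol_total(table))))
}

#' Default synthetic 171-region parcellation
#'
#' Builds a deterministic-for-seed region table with 68 cortical parcels,
#' 68 paired white-matter rims, 17 subcortical structures and 18 deep tracts.
#' Volumes span roughly 0.5-70 cm3, echoing the range of automated
#' parcellations (accumbens below 1 cm3 up to cerebellar cortex at tens of
#' cm3); each rim is thinner, hence smaller, than its cortical partner.
#'
#' @param scale multiplies every volume (default 1.0).
#' @param seed integer seed; the same seed always yields the same table.
#' @return a [region_table()] with 171 rows.
#' @export
default_region_table <- function(scale = 1.0, seed = 1L) {
  stopifnot(scale > 0)
  # Typical volumes in cm3 for the bilateral subcortical structures.
  sub_vol <- c(accumbens = 0.6, amygdala = 1.7, caudate = 3.6, cerebellum = 55,
               hippocampus = 4.2, pallidum = 1.7, putamen = 5.2, thalamus = 7.5)
  tract_vol <- c(atr = 6, cab = 1.2, ccg = 3.5, cst = 8, ilf = 9,
                 slfp = 7, slft = 9, unc = 5)
  with_stream(seed, "region_table", {
    rows <- list()
    add <- function(id, name, cls, hemi, vol_cm3, pair = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        region_id = id, name = name, reg_class = cls, hemisphere = hemi,
        volume_mm3 = vol_cm3 * 1000 * scale, paired_region_id = pair,
        stringsAsFactors = FALSE)
    }
    for (hemi in c("L", "R")) {
      for (parc in DK_CORTICAL) {
        ctx_id <- paste0(hemi, "_", parc)
        rim_id <- paste0(ctx_id, "_wm")
        # Cortical parcels roughly 1.5-25 cm3 with mild seeded jitter.
        base <- stats::runif(1, 1.5, 25)
        rim_frac <- stats::runif(1, 0.25, 0.55)  # rim thinner than cortex
        add(ctx_id, paste(hemi, parc, "cortex"), "cortical", hemi, base, rim_id)
        add(rim_id, paste(hemi, parc, "white-matter rim"), "wm_rim", hemi,
            base * rim_frac, ctx_id)
      }
      for (s in names(sub_vol)) {
        add(paste0(hemi, "_", s), paste(hemi, s), "subcortical", hemi,
            sub_vol[[s]] * stats::runif(1, 0.9, 1.1))
      }
      for (tr in names(tract_vol)) {
        add(paste0(hemi, "_", tr), paste(hemi, tr, "tract"), "deep_tract", hemi,
            tract_vol[[tr]] * stats::runif(1, 0.9, 1.1))
      }
    }
    add("brainstem", "brain stem", "subcortical", "midline",
        18 * stats::runif(1, 0.9, 1.1))
    add("fmajor", "forceps major", "deep_tract", "midline",
        10 * stats::runif(1, 0.9, 1.1))
    add("fminor", "forceps minor", "deep_tract", "midline",
        12 * stats::runif(1, 0.9, 1.1))
    region_table(do.call(rbind, rows))
  })
}

#' @export
print.region_table <- function(x, ...) {
  cls <- table(x$reg_class)
  cat(sprintf("region_table: %d regions (%s), whole-brain volume %.1f cm3\n",
              nrow(x),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", "),
              vol_total(x) / 1000))
  invisible(x)
}
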