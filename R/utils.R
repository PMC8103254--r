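# Small shared helpers: rounding, RNG streams, TSV I/O.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; classification tables in this
#' package report percentages rounded half away from zero, the convention of
#' classical statistical software printouts.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-bit stream seed derived from a root seed and a stream name,
# so that adding a new named stream never perturbs draws in existing streams.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1977326743L
  as.integer((as.numeric(seed) %% 1977326743 * 31 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a named RNG stream, restoring the caller's RNG state.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  expr
}

# Read a TSV with optional "# key: value" comment header lines.
read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

# Atomic TSV write: write to a temp file in the same directory, then rename.
write_tsv <- function(df, path, header_comments = character()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wt")
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

# Full-precision numeric formatting so numeric columns round-trip bit-exactly.
num_chr <- function(x) formatC(x, digits = 17, format = "g")

`%||%` <- function(a, b) if (is.null(a)) b else a
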