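# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed percentages, so that
#' e.g. 27.586 renders as 27.6 and 27.5 as 28 at integer precision.  Internal
#' computation always runs at full precision; rounding happens only at output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() without the call, with sprintf-style formatting
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Atomic TSV/JSON/text writers: write to a temp file in the target directory,
# then rename, so an interrupted run never leaves a truncated output file.
.write_atomic <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) .err("failed to write '%s'", path)
  invisible(path)
}

#' Write a data frame as a TSV file (atomically)
#'
#' @param df data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  .write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }, path)
}

#' Write an R object as JSON (atomically)
#'
#' @param x object serialisable by jsonlite.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_json_report <- function(x, path) {
  .write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}
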