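# Tabular and track writers. All writers go through a temp-then-rename so
# a failure never leaves a truncated output behind.

.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  .write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Write a sliding-window track as bedGraph
#'
#' One line per window: `contig  start  end  motif_count`, 0-based
#' half-open, the convention genome browsers expect.
#'
#' @param track A `window_track` (or any data frame with `contig_id`,
#'   `start`, `end` and a fourth value column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  value <- track[[setdiff(names(track), c("contig_id", "start", "end"))[1L]]]
  .write_atomic(function(p) {
    writeLines(sprintf("%s\t%d\t%d\t%g", track$contig_id,
                       as.integer(track$start), as.integer(track$end), value), p)
  }, path)
}

#' Write an object as JSON
#' @param x A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  if (inherits(x, c("readset_summary", "clip_summary"))) x <- unclass(x)
  .write_atomic(function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}
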