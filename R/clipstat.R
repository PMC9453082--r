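#' Terminal clipped fraction of one alignment
#'
#' The fraction of a read that the aligner clipped away at its ends:
#' (leading clip + trailing clip) / full read length. Both soft (S) and
#' hard (H) clips count as clipped bases, and hard-clipped bases are added
#' back to the denominator so that it is always the original read length.
#'
#' @param cigar CIGAR string of a mapped primary alignment.
#' @return Clipped fraction in \[0, 1\].
#' @examples
#' clipped_fraction("10S80M10S")  # 0.2
#' clipped_fraction("5H95M")      # 0.05
#' @export
clipped_fraction <- function(cigar) {
  cig <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  if (nrow(cig) == 0L) stop("record has no CIGAR; cannot compute clipped fraction",
                            call. = FALSE)
  clips <- cigar_clips(cig)
  full_len <- cigar_query_length(cig) + clips$hard
  (clips$left + clips$right) / full_len
}

#' Average mapping completeness of a read set against an assembly
#'
#' For every primary mapped alignment, the terminal clipped fraction
#' ([clipped_fraction()]) is computed; mapping completeness is one minus
#' the mean of these fractions. A read that maps end-to-end contributes 0
#' clipped fraction; a read whose ends the aligner could not place against
#' the assembly contributes more, so a completeness near 1 indicates that
#' the assembly can absorb nearly every base of nearly every read.
#' Unmapped reads are excluded from the mean and reported separately;
#' secondary and supplementary alignments are skipped so that each read is
#' counted once.
#'
#' @param recs An `alignments` data frame from [read_alignments()].
#' @return An object of class `clip_summary`: `n_reads_used`,
#'   `mean_clipped_fraction`, `mapping_completeness`
#'   (= 1 − mean clipped fraction), `n_unmapped`, `n_skipped`
#'   (secondary/supplementary/CIGAR-less primaries).
#' @export
mapping_completeness <- function(recs) {
  stopifnot(is.data.frame(recs))
  if (any(recs$is_primary & is.na(recs$cigar))) {
    stop("alignment record without a CIGAR (PAF missing cg:Z: tag); ",
         "re-run the aligner with CIGAR output", call. = FALSE)
  }
  unmapped <- !recs$is_mapped
  eligible <- recs$is_primary & recs$cigar != "*"
  skipped <- !unmapped & !eligible
  if (sum(eligible) == 0L) {
    stop("no eligible (primary, mapped, CIGAR-bearing) alignments", call. = FALSE)
  }
  fr <- vapply(recs$cigar[eligible], clipped_fraction, numeric(1), USE.NAMES = FALSE)
  out <- list(
    n_reads_used = sum(eligible),
    mean_clipped_fraction = mean(fr),
    mapping_completeness = 1 - mean(fr),
    n_unmapped = sum(unmapped),
    n_skipped = sum(skipped)
  )
  class(out) <- "clip_summary"
  out
}

#' @export
print.clip_summary <- function(x, ...) {
  cat("Mapping completeness\n")
  cat(sprintf("  reads used:            %d\n", x$n_reads_used))
  cat(sprintf("  mean clipped fraction: %.4f\n", x$mean_clipped_fraction))
  cat(sprintf("  mapping completeness:  %.4f (%.2f%%)\n",
              x$mapping_completeness, 100 * x$mapping_completeness))
  cat(sprintf("  unmapped reads:        %d\n", x$n_unmapped))
  cat(sprintf("  skipped records:       %d\n", x$n_skipped))
  invisible(x)
}

#' @export
as.data.frame.clip_summary <- function(x, ...) {
  data.frame(n_reads_used = x$n_reads_used,
             mean_clipped_fraction = x$mean_clipped_fraction,
             mapping_completeness = x$mapping_completeness,
             n_unmapped = x$n_unmapped, n_skipped = x$n_skipped)
}
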