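#' Nx statistic of a length distribution
#'
#' The Nx value is the minimum element length such that elements at least
#' that long cumulatively cover x% of the total bases. N50 of a read set
#' and N99 of an assembly are the two instances used in long-read QC:
#' N50 is the minimum read length needed to cover half of the read
#' distribution, N99 the minimum contig length needed to cover 99% of the
#' genome.
#'
#' @param lengths Positive integer lengths (reads or contigs).
#' @param x Percentage in (0, 100].
#' @return The Nx length in bases.
#' @examples
#' nx_value(c(6, 5, 4, 3, 2), 50)  # 5
#' nx_value(c(6, 5, 4, 3, 2), 99)  # 2
#' @export
nx_value <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("'lengths' is empty", call. = FALSE)
  if (any(lengths <= 0) || any(is.na(lengths))) {
    stop("'lengths' must be positive and non-missing", call. = FALSE)
  }
  .check_scalar(x, "x", lower = .Machine$double.eps, upper = 100)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))  # numeric: integer cumsum can overflow
  target <- x / 100 * cum[length(cum)]
  s[which(cum >= target)[1L]]
}

#' Error-probability-averaged read quality
#'
#' Converts each per-base Phred score to an error probability
#' \eqn{p = 10^{-q/10}}, averages the probabilities arithmetically, and
#' converts back to the Phred scale: \eqn{-10 \log_{10}(\bar p)}. This is
#' the convention used by common long-read QC tools; it weights low-quality
#' bases more heavily than a plain mean of Phred scores would.
#'
#' @param quals Integer vector of per-base Phred scores.
#' @return The read-level quality (Phred scale, numeric).
#' @examples
#' read_quality(c(10, 20))  # ~12.6
#' @export
read_quality <- function(quals) {
  if (length(quals) == 0L) stop("'quals' is empty", call. = FALSE)
  if (any(is.na(quals)) || any(quals < 0)) {
    stop("'quals' must be non-negative Phred scores", call. = FALSE)
  }
  -10 * log10(mean(10^(-quals / 10)))
}

#' Filter reads on length and quality
#'
#' Keeps a read iff its length is at least `min_len` and its
#' error-averaged quality ([read_quality()]) is at least `min_q`; both
#' thresholds are inclusive. The defaults reproduce the standard
#' pre-assembly filter for Nanopore fungal sequencing: minimum length
#' 10 kb and minimum quality Q7 (a mean per-base error probability of
#' about 20%, i.e. roughly 80% accuracy).
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param min_len Minimum read length in bases (default 10000).
#' @param min_q Minimum read quality on the Phred scale (default 7).
#' @return A list with `kept` (the filtered `QualityScaledDNAStringSet`),
#'   `n_rejected_length`, and `n_rejected_quality`. A read failing both
#'   criteria is counted against length.
#' @export
filter_reads <- function(reads, min_len = 10000, min_q = 7.0) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  .check_scalar(min_len, "min_len", lower = 0)
  .check_scalar(min_q, "min_q", lower = 0)
  if (length(reads) == 0L) {
    return(list(kept = reads, n_rejected_length = 0L, n_rejected_quality = 0L))
  }
  len_ok <- Biostrings::width(reads) >= min_len
  q <- vapply(read_phred(reads), read_quality, numeric(1))
  q_ok <- q >= min_q
  list(kept = reads[len_ok & q_ok],
       n_rejected_length = sum(!len_ok),
       n_rejected_quality = sum(len_ok & !q_ok))
}

#' Randomly subsample reads to a target coverage
#'
#' Applies a seeded pseudo-random permutation to the reads and takes them
#' in shuffled order until the cumulative base count first reaches
#' `target_cov * genome_size`. Unlike per-read coin flips, this
#' shuffle-then-fill scheme hits the coverage target exactly once reached,
#' and the result is deterministic for a fixed input order and seed.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param genome_size Genome size in bases.
#' @param target_cov Target coverage (fold).
#' @param seed Integer seed for the permutation.
#' @return The selected subset, in shuffled order.
#' @export
subsample_to_coverage <- function(reads, genome_size, target_cov, seed) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  .check_scalar(genome_size, "genome_size", lower = 1)
  .check_scalar(target_cov, "target_cov", lower = .Machine$double.eps)
  target <- target_cov * genome_size
  total <- sum(as.numeric(Biostrings::width(reads)))
  if (total < target) {
    stop(sprintf(
      "insufficient bases for %gx of a %g b genome: %g b available (%.2fx achievable)",
      target_cov, genome_size, total, total / genome_size), call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(length(reads)))
  w <- cumsum(as.numeric(Biostrings::width(reads)[perm]))
  k <- which(w >= target)[1L]
  reads[perm[seq_len(k)]]
}

#' Summary statistics of a read set
#'
#' Computes the standard sequencing-run summary: read count, total bases,
#' N50 of the read-length distribution, and mean read quality. The quality
#' convention is recorded in the result: the primary figure is the
#' arithmetic mean over reads of the per-read error-averaged quality
#' ([read_quality()]); the alternative that pools all bases of the run
#' into a single error average is reported alongside as
#' `pooled_base_q`, since summary tables in the literature rarely state
#' which of the two was used.
#'
#' @param reads A non-empty `QualityScaledDNAStringSet`.
#' @return An object of class `readset_summary`: a list with `n_reads`,
#'   `total_bases`, `n50`, `mean_read_q`, `pooled_base_q`, and
#'   `q_definition`.
#' @export
readset_summary <- function(reads) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  if (length(reads) == 0L) stop("empty read set", call. = FALSE)
  lens <- Biostrings::width(reads)
  phreds <- read_phred(reads)
  per_read_q <- vapply(phreds, read_quality, numeric(1))
  pooled_p <- sum(vapply(phreds, function(q) sum(10^(-q / 10)), numeric(1))) /
    sum(as.numeric(lens))
  out <- list(
    n_reads = length(reads),
    total_bases = sum(as.numeric(lens)),
    n50 = nx_value(lens, 50),
    mean_read_q = mean(per_read_q),
    pooled_base_q = -10 * log10(pooled_p),
    q_definition = "mean over reads of per-read error-averaged Phred Q"
  )
  class(out) <- "readset_summary"
  out
}

#' @export
print.readset_summary <- function(x, ...) {
  cat("Read-set summary\n")
  cat(sprintf("  reads:        %d\n", x$n_reads))
  cat(sprintf("  total bases:  %.0f\n", x$total_bases))
  cat(sprintf("  N50:          %d b\n", x$n50))
  cat(sprintf("  mean read Q:  %.2f (%s)\n", x$mean_read_q, x$q_definition))
  cat(sprintf("  pooled-base Q: %.2f\n", x$pooled_base_q))
  invisible(x)
}

#' @export
as.data.frame.readset_summary <- function(x, ...) {
  data.frame(n_reads = x$n_reads, total_bases = x$total_bases, n50 = x$n50,
             mean_read_q = x$mean_read_q, pooled_base_q = x$pooled_base_q,
             q_definition = x$q_definition, stringsAsFactors = FALSE)
}
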