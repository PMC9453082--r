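#' Mean read depth per contig
#'
#' Mean depth of a contig is the total number of reference-consuming
#' aligned bases (CIGAR M/=/X) of its primary mapped alignments divided by
#' the contig length. Deletion (D) and skip (N) operations advance the
#' reference position but have no read support at those bases, so they
#' contribute no depth.
#'
#' @param recs An `alignments` data frame.
#' @param contig_lengths Named numeric vector of contig lengths; every
#'   mapped target must be present.
#' @return Named numeric vector of mean depths (fold), one per contig in
#'   `contig_lengths` (0 for contigs without alignments).
#' @export
contig_mean_depth <- function(recs, contig_lengths) {
  stopifnot(is.data.frame(recs), !is.null(names(contig_lengths)))
  use <- recs$is_primary & !is.na(recs$cigar) & recs$cigar != "*"
  if (any(recs$is_primary & is.na(recs$cigar))) {
    stop("alignment record without a CIGAR (PAF missing cg:Z: tag)", call. = FALSE)
  }
  depth_bases <- stats::setNames(numeric(length(contig_lengths)),
                                 names(contig_lengths))
  if (any(use)) {
    tgt <- recs$target_id[use]
    unknown <- setdiff(tgt, names(contig_lengths))
    if (length(unknown)) {
      stop("alignment to unknown contig '", unknown[1L], "'", call. = FALSE)
    }
    ref_bases <- vapply(recs$cigar[use],
                        function(ct) cigar_ref_length_aligned(parse_cigar(ct)),
                        numeric(1), USE.NAMES = FALSE)
    agg <- tapply(ref_bases, tgt, sum)
    depth_bases[names(agg)] <- agg
  }
  depth_bases / contig_lengths
}

# reference bases with read support: M, =, X (not D/N)
cigar_ref_length_aligned <- function(cig) sum(cig$len[cig$op %in% c("M", "=", "X")])

#' Coverage plateau of the true nuclear contigs
#'
#' A haploid long-read assembly typically shows three depth groups: small
#' very-high-coverage contigs (mtDNA, rRNA arrays, repeats), a plateau of
#' large contigs at a common depth (the true nuclear contigs), and
#' low-coverage artifact contigs. This estimator locates the plateau as
#' the length-weighted median depth of the long contigs (>= `min_len`),
#' keeps the long contigs whose depth lies within `band` times that
#' median, and returns their length-weighted mean depth.
#'
#' @param lengths,depths Per-contig lengths (bases) and mean depths (fold).
#' @param min_len Minimum contig length to enter plateau estimation
#'   (default 50000 b).
#' @param band Multiplicative band around the weighted median
#'   (default `c(0.5, 1.5)`).
#' @return The plateau mean depth (fold).
#' @examples
#' plateau_mean(c(5e6, 4e6, 2e5, 5e4), c(100, 98, 40, 400))  # ~99.11
#' @export
plateau_mean <- function(lengths, depths, min_len = 50000, band = c(0.5, 1.5)) {
  stopifnot(length(lengths) == length(depths), length(band) == 2L,
            band[1L] < band[2L])
  big <- lengths >= min_len & depths > 0
  if (!any(big)) {
    stop("no contig >= ", min_len, " b with positive depth; ",
         "set the plateau depth manually", call. = FALSE)
  }
  m <- weighted_median(depths[big], lengths[big])
  in_band <- big & depths >= band[1L] * m & depths <= band[2L] * m
  if (!any(in_band)) {
    stop("empty plateau set (no long contig within ", band[1L], "-", band[2L],
         " of the weighted median depth); set the plateau depth manually",
         call. = FALSE)
  }
  sum(depths[in_band] * lengths[in_band]) / sum(lengths[in_band])
}

# smallest value whose cumulative weight reaches half the total
weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(as.numeric(w[o]))
  x[o][which(cw >= sum(as.numeric(w)) / 2)[1L]]
}

#' Classify contigs against the coverage plateau
#'
#' Applies the simple depth-ratio cutoffs: a contig is an `artifact` when
#' its depth falls strictly below `artifact_frac` (default 67%) of the
#' plateau depth, `high_copy` when strictly above `high_copy_mult` times
#' the plateau (candidate mtDNA / rRNA / repeat contigs), and `true`
#' otherwise. A contig exactly at the artifact cutoff is `true`.
#'
#' @param contig_ids,lengths,depths Per-contig identifier, length, depth.
#' @param plateau Plateau depth from [plateau_mean()] (fold, > 0).
#' @param artifact_frac Lower cutoff as a fraction of the plateau
#'   (default 0.67).
#' @param high_copy_mult Upper cutoff as a multiple of the plateau
#'   (default 2).
#' @return An object of class `contig_classes`: data frame `contig_id`,
#'   `length`, `mean_depth`, `label` in \{true, artifact, high_copy\},
#'   with the plateau and cutoffs stored as attributes.
#' @export
classify_contigs <- function(contig_ids, lengths, depths, plateau,
                             artifact_frac = 0.67, high_copy_mult = 2.0) {
  .check_scalar(plateau, "plateau", lower = .Machine$double.eps)
  .check_scalar(artifact_frac, "artifact_frac", lower = 0, upper = 1)
  .check_scalar(high_copy_mult, "high_copy_mult", lower = 1)
  label <- rep("true", length(depths))
  label[depths < artifact_frac * plateau] <- "artifact"
  label[depths > high_copy_mult * plateau] <- "high_copy"
  out <- data.frame(contig_id = contig_ids, length = lengths,
                    mean_depth = depths, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "plateau") <- plateau
  attr(out, "artifact_cutoff") <- artifact_frac * plateau
  attr(out, "high_copy_cutoff") <- high_copy_mult * plateau
  class(out) <- c("contig_classes", class(out))
  out
}

#' Flag bins of unusually high depth along a contig
#'
#' Detects localized coverage spikes (e.g. a terminal rRNA array on an
#' otherwise uniform contig) by flagging bins whose depth exceeds
#' median + `z_threshold` * 1.4826 * MAD of the per-bin depths. The
#' median/MAD scale is robust: a single spiked region does not inflate
#' the threshold the way a standard deviation would. When the scale
#' degenerates to 0 (constant track), only bins strictly above the median
#' can be flagged, so a flat track yields none.
#'
#' @param values Per-bin mean depths (>= 10 bins).
#' @param z_threshold Robust z cutoff (default 3).
#' @return Integer indices of flagged bins.
#' @export
depth_uniformity <- function(values, z_threshold = 3.0) {
  if (length(values) < 10L) {
    stop("need at least 10 bins for uniformity flagging", call. = FALSE)
  }
  med <- stats::median(values)
  scale <- stats::mad(values)  # 1.4826 * MAD
  which(values > med + z_threshold * scale & values > med)
}

#' Percentage of unmapped reads
#'
#' 100 * unmapped / (unmapped + primary mapped) over a record stream that
#' contains one record per read (primary and unmapped records).
#'
#' @param recs An `alignments` data frame.
#' @return Percentage in \[0, 100\].
#' @export
unmapped_fraction <- function(recs) {
  stopifnot(is.data.frame(recs))
  n_un <- sum(!recs$is_mapped)
  n_pri <- sum(recs$is_primary)
  if (n_un + n_pri == 0L) stop("no read-level records in stream", call. = FALSE)
  100 * n_un / (n_un + n_pri)
}
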