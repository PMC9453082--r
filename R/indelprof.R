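#' Global pairwise alignment of two gene-scale sequences
#'
#' Optimal global (end-to-end) alignment under affine gap scoring, used to
#' compare a trusted reference gene (sequence A) against its copy in an
#' assembly (sequence B). The default scoring (+1 match, -2 mismatch,
#' gap of length L costs 4 + 2L) prefers one multi-base gap over several
#' scattered single-base gaps, which matches how consensus indel errors
#' present in assembly-versus-gene comparisons. The dynamic programming is
#' delegated to [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Sequences (character or `DNAString`); `a` is the reference.
#' @param match,mismatch Substitution scores (default +1 / -2).
#' @param gap_open,gap_extend Affine gap penalties as negative scores; a
#'   gap of length L scores `gap_open + L * gap_extend`
#'   (default -4 and -2).
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings, gap character `-`) and
#'   `score`.
#' @examples
#' global_align("ACGT", "AGT")$score  # -3
#' @export
global_align <- function(a, b, match = 1, mismatch = -2,
                         gap_open = -4, gap_extend = -2) {
  a <- .validate_bases(as.character(a), "sequence A")
  b <- .validate_bases(as.character(b), "sequence B")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = -gap_open,
                                       gapExtension = -gap_extend)
  out <- list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = BiocGenerics::score(aln)
  )
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat("A: ", x$aligned_a, "\n", sep = "")
  cat("B: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Extract indel events from a pairwise alignment
#'
#' Maximal gap runs in either row become single events, reported relative
#' to sequence A (the reference): a gap run in A is an insertion (bases
#' present in B but not in A), a gap run in B is a deletion. `ref_pos` is
#' the 0-based position in ungapped A before which the event occurs (for
#' deletions, the position of the first deleted base).
#'
#' @param aln A `pairwise_alignment`.
#' @return Data frame with `kind` ("insertion"/"deletion"), `ref_pos`,
#'   and `seq` (the inserted or deleted bases); zero rows if gapless.
#' @export
extract_indels <- function(aln) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b), !any(a == "-" & b == "-"))
  gap_a <- a == "-"
  gap_b <- b == "-"
  ref_before <- cumsum(!gap_a) - as.integer(!gap_a)  # A bases before column
  events <- list()
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  ra <- runs(gap_a)
  for (k in seq_len(nrow(ra))) {
    events[[length(events) + 1L]] <- data.frame(
      kind = "insertion", ref_pos = ref_before[ra[k, 1L]],
      seq = paste(b[ra[k, 1L]:ra[k, 2L]], collapse = ""), stringsAsFactors = FALSE)
  }
  rb <- runs(gap_b)
  for (k in seq_len(nrow(rb))) {
    events[[length(events) + 1L]] <- data.frame(
      kind = "deletion", ref_pos = ref_before[rb[k, 1L]],
      seq = paste(a[rb[k, 1L]:rb[k, 2L]], collapse = ""), stringsAsFactors = FALSE)
  }
  if (length(events) == 0L) {
    return(data.frame(kind = character(), ref_pos = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out[order(out$ref_pos, out$kind), , drop = FALSE]
}

#' Is an indel event homopolymeric?
#'
#' An event is homopolymeric when its bases are a single repeated base b
#' and the maximal run of b in the reference touching the event position,
#' combined with the event bases, reaches `min_run`. This captures the
#' characteristic Nanopore consensus error mode: length miscalls inside
#' homopolymer runs. Multi-base events with mixed bases are never
#' homopolymeric.
#'
#' @param kind "insertion" or "deletion".
#' @param ref_pos 0-based event position in the ungapped reference.
#' @param seq Event bases.
#' @param ref The ungapped reference sequence (character).
#' @param min_run Minimum combined run length (default 3).
#' @return Logical flag.
#' @export
is_homopolymeric <- function(kind, ref_pos, seq, ref, min_run = 3) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(unique(bases)) != 1L) return(FALSE)
  b <- bases[1L]
  refc <- strsplit(as.character(ref), "", fixed = TRUE)[[1L]]
  # run of b immediately left of the event
  left <- 0L; i <- ref_pos  # 0-based: refc[ref_pos] is the base at index ref_pos+1
  while (i >= 1L && refc[i] == b) { left <- left + 1L; i <- i - 1L }
  # run of b at and right of the event position (includes deleted bases)
  right <- 0L; j <- ref_pos + 1L
  while (j <= length(refc) && refc[j] == b) { right <- right + 1L; j <- j + 1L }
  total <- left + right + if (kind == "insertion") length(bases) else 0L
  total >= min_run
}

#' Count homopolymeric and random indel errors over gene pairs
#'
#' For each (reference gene, assembly gene) pair: align globally, extract
#' indel events, classify each as homopolymeric or random, and sum. This
#' is the standard spot check of consensus accuracy for long-read-only
#' assemblies, run on a few conserved single-copy genes extracted from
#' the assembly against their trusted sequences.
#'
#' @param ref_genes,asm_genes Matched sequence sets (`DNAStringSet`,
#'   character vector, or list), pair i being `ref_genes[[i]]` vs
#'   `asm_genes[[i]]`.
#' @param min_run Homopolymer definition, see [is_homopolymeric()].
#' @param ... Scoring parameters passed to [global_align()].
#' @return An object of class `indel_counts`: list with `per_gene`
#'   (data frame: `gene`, `n_homopolymeric`, `n_random`),
#'   `n_homopolymeric`, `n_random`, and `events` (all events with their
#'   gene and classification).
#' @export
indel_error_counts <- function(ref_genes, asm_genes, min_run = 3, ...) {
  if (length(ref_genes) != length(asm_genes) || length(ref_genes) == 0L) {
    stop("need the same positive number of reference and assembly genes",
         call. = FALSE)
  }
  ids <- names(ref_genes)
  if (is.null(ids)) ids <- paste0("gene", seq_along(ref_genes))
  per_gene <- vector("list", length(ref_genes))
  all_events <- vector("list", length(ref_genes))
  for (i in seq_along(ref_genes)) {
    ref <- as.character(ref_genes[[i]])
    asm <- as.character(asm_genes[[i]])
    if (nchar(ref) == 0L || nchar(asm) == 0L) {
      stop("empty sequence for gene '", ids[i], "'", call. = FALSE)
    }
    aln <- global_align(ref, asm, ...)
    ev <- extract_indels(aln)
    homo <- if (nrow(ev)) {
      vapply(seq_len(nrow(ev)), function(k) {
        is_homopolymeric(ev$kind[k], ev$ref_pos[k], ev$seq[k], ref, min_run)
      }, logical(1))
    } else logical(0)
    per_gene[[i]] <- data.frame(gene = ids[i],
                                n_homopolymeric = sum(homo),
                                n_random = sum(!homo),
                                stringsAsFactors = FALSE)
    if (nrow(ev)) {
      ev$gene <- ids[i]
      ev$homopolymeric <- homo
      all_events[[i]] <- ev
    }
  }
  per_gene <- do.call(rbind, per_gene)
  events <- do.call(rbind, all_events)
  if (is.null(events)) {
    events <- data.frame(kind = character(), ref_pos = integer(),
                         seq = character(), gene = character(),
                         homopolymeric = logical(), stringsAsFactors = FALSE)
  }
  out <- list(per_gene = per_gene,
              n_homopolymeric = sum(per_gene$n_homopolymeric),
              n_random = sum(per_gene$n_random),
              events = events)
  class(out) <- "indel_counts"
  out
}

#' @export
print.indel_counts <- function(x, ...) {
  cat("Indel error profile\n")
  cat(sprintf("  homopolymeric indels: %d\n", x$n_homopolymeric))
  cat(sprintf("  random indels:        %d\n", x$n_random))
  print(x$per_gene, row.names = FALSE)
  invisible(x)
}
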