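# Seeded generators with planted ground truth. Every generator is a pure
# function of (spec, seed): the caller's RNG state is never touched and the
# same seed reproduces the same fixture bytes.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.phred_to_ascii <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

#' Simulate a long-read set
#'
#' Generates reads with log-normal lengths and per-base Phred scores
#' jittered around a per-read mean quality. The defaults emulate a typical
#' Nanopore fungal run after high-accuracy basecalling: a length
#' distribution whose N50 falls in the tens of kilobases and mean read
#' quality near Q12. With `q_sd = 0` every base of every read carries
#' exactly `q_mean` (which should then be an integer).
#'
#' @param n Number of reads.
#' @param log_len_mean,log_len_sd Meanlog/sdlog of the length distribution
#'   (defaults `log(15000)` and 0.6; lengths are rounded, minimum 1).
#' @param q_mean,q_sd Mean and spread of quality: the per-read mean is
#'   drawn from N(`q_mean`, `q_sd`) and per-base scores from
#'   N(read mean, `q_sd`), rounded and clamped to \[1, 50\].
#' @param seed Integer seed.
#' @return List with `reads` (a `QualityScaledDNAStringSet`, ids
#'   `read1..readn`) and `truth` (lengths, per-read mean quality targets,
#'   parameters, seed).
#' @export
simulate_reads <- function(n, log_len_mean = log(15000), log_len_sd = 0.6,
                           q_mean = 12, q_sd = 1.5, seed = 1) {
  .check_scalar(n, "n", lower = 1)
  .check_scalar(log_len_sd, "log_len_sd", lower = 0)
  .check_scalar(q_sd, "q_sd", lower = 0)
  .check_scalar(q_mean, "q_mean", lower = 1, upper = 50)
  with_seed(seed, {
    lens <- pmax(1L, as.integer(round(stats::rlnorm(n, log_len_mean, log_len_sd))))
    read_q <- pmin(50, pmax(1, stats::rnorm(n, q_mean, q_sd)))
    seqs <- vapply(lens, .random_dna, character(1))
    quals <- vapply(seq_len(n), function(i) {
      q <- round(read_q[i] + stats::rnorm(lens[i], 0, q_sd))
      .phred_to_ascii(pmin(50L, pmax(1L, as.integer(q))))
    }, character(1))
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(reads) <- paste0("read", seq_len(n))
    list(reads = reads,
         truth = list(lengths = lens, read_q = read_q,
                      params = list(n = n, log_len_mean = log_len_mean,
                                    log_len_sd = log_len_sd, q_mean = q_mean,
                                    q_sd = q_sd),
                      seed = seed))
  })
}

#' Simulate an assembly with planted telomere arrays
#'
#' Builds contigs of random interior sequence with exact tandem arrays of
#' TTAGGG at the left end and CCCTAA at the right end, as specified per
#' contig. Telomere detection on such a fixture has known truth: an end
#' with `k` planted copies is telomeric for any calling threshold
#' `min_copies <= k`.
#'
#' @param contig_specs Data frame (or list coercible to one) with columns
#'   `length`, `left_copies`, `right_copies`; each length must be at least
#'   `6 * (left_copies + right_copies)`.
#' @param seed Integer seed for the interior sequence.
#' @return List with `contigs` (named `DNAStringSet`, ids `contig1..`) and
#'   `truth` (the specs, expected telomeric-end count per contig for a
#'   threshold within the planted copy numbers, and seed).
#' @export
make_assembly_with_telomeres <- function(contig_specs, seed = 1) {
  specs <- as.data.frame(contig_specs)
  stopifnot(all(c("length", "left_copies", "right_copies") %in% names(specs)),
            nrow(specs) >= 1L)
  need <- 6L * (specs$left_copies + specs$right_copies)
  if (any(specs$length < 2L * need / 2L)) {
    stop("contig ", which(specs$length < need)[1L],
         " too short for the requested telomere arrays", call. = FALSE)
  }
  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(specs)), function(i) {
      left <- strrep("TTAGGG", specs$left_copies[i])
      right <- strrep("CCCTAA", specs$right_copies[i])
      mid <- .random_dna(specs$length[i] - nchar(left) - nchar(right))
      paste0(left, mid, right)
    }, character(1))
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- paste0("contig", seq_len(nrow(specs)))
    list(contigs = contigs,
         truth = list(specs = specs,
                      n_tel_ends = as.integer((specs$left_copies > 0) +
                                              (specs$right_copies > 0)),
                      seed = seed))
  })
}

#' Build alignment records from explicit per-read specifications
#'
#' Low-level constructor for alignment fixtures: each row of `read_specs`
#' becomes one primary mapped record with CIGAR
#' `<clip_left>S <aligned>M <clip_right>S`, plus `n_unmapped` unmapped
#' records.
#'
#' @param read_specs Data frame with columns `length`, `clip_left`,
#'   `clip_right`, `target`, `target_start` (0-based); clips must leave at
#'   least one aligned base.
#' @param n_unmapped Number of unmapped records to append.
#' @return An `alignments` data frame as produced by [read_alignments()].
#' @export
alignments_from_specs <- function(read_specs, n_unmapped = 0) {
  specs <- as.data.frame(read_specs)
  stopifnot(all(c("length", "clip_left", "clip_right", "target",
                  "target_start") %in% names(specs)))
  aligned <- specs$length - specs$clip_left - specs$clip_right
  if (any(aligned < 1L)) {
    stop("read ", which(aligned < 1L)[1L], ": clips leave no aligned bases",
         call. = FALSE)
  }
  cigar <- paste0(ifelse(specs$clip_left > 0, paste0(specs$clip_left, "S"), ""),
                  aligned, "M",
                  ifelse(specs$clip_right > 0, paste0(specs$clip_right, "S"), ""))
  recs <- data.frame(
    query_id = paste0("read", seq_len(nrow(specs))),
    is_mapped = TRUE, is_primary = TRUE,
    is_secondary = FALSE, is_supplementary = FALSE,
    target_id = as.character(specs$target),
    target_start = as.integer(specs$target_start),
    cigar = cigar,
    stored_query_length = as.integer(specs$length),
    stringsAsFactors = FALSE
  )
  if (n_unmapped > 0) {
    un <- data.frame(
      query_id = paste0("unmapped", seq_len(n_unmapped)),
      is_mapped = FALSE, is_primary = FALSE,
      is_secondary = FALSE, is_supplementary = FALSE,
      target_id = NA_character_, target_start = NA_integer_,
      cigar = "*", stored_query_length = 0L,
      stringsAsFactors = FALSE
    )
    recs <- rbind(recs, un)
  }
  class(recs) <- c("alignments", class(recs))
  recs
}

#' Simulate alignments with a planted mean clip fraction
#'
#' Draws a per-read total clipped fraction from Uniform(0, 2 *
#' `mean_clip_frac`), splits it at random between the two read ends, and
#' emits the corresponding soft-clipped records against a single contig.
#' The realized mean clipped fraction (after rounding clips to whole
#' bases) is recorded in the truth, so mapping-completeness estimates can
#' be checked against the plant.
#'
#' @param n Number of mapped reads.
#' @param read_length Read length in bases (all reads equal length).
#' @param mean_clip_frac Planted mean total clipped fraction, in
#'   \[0, 0.5).
#' @param n_unmapped Unmapped records to append.
#' @param seed Integer seed.
#' @return List with `records` (an `alignments` data frame on contig
#'   `ctg1` of length `read_length`), `contig_lengths`, and `truth`
#'   (planted and realized clip fractions, seed).
#' @export
simulate_clipped_alignments <- function(n, read_length = 10000,
                                        mean_clip_frac = 0.1, n_unmapped = 0,
                                        seed = 1) {
  .check_scalar(n, "n", lower = 1)
  .check_scalar(mean_clip_frac, "mean_clip_frac", lower = 0, upper = 0.499)
  with_seed(seed, {
    total_frac <- stats::runif(n, 0, 2 * mean_clip_frac)
    left_share <- stats::runif(n)
    clip_left <- as.integer(round(total_frac * left_share * read_length))
    clip_right <- as.integer(round(total_frac * (1 - left_share) * read_length))
    specs <- data.frame(length = read_length, clip_left = clip_left,
                        clip_right = clip_right, target = "ctg1",
                        target_start = 0L)
    recs <- alignments_from_specs(specs, n_unmapped = n_unmapped)
    realized <- (clip_left + clip_right) / read_length
    list(records = recs,
         contig_lengths = c(ctg1 = read_length),
         truth = list(mean_clip_frac = mean_clip_frac,
                      realized_fractions = realized,
                      realized_mean = mean(realized), seed = seed))
  })
}

#' Simulate alignments that tile contigs to exact depths
#'
#' Lays down abutting full-M reads layer by layer so that every base of
#' every contig is covered exactly `depth` times; the resulting
#' [contig_mean_depth()] is exactly `depth` with no sampling noise.
#'
#' @param contig_lengths Named vector of contig lengths.
#' @param depth Integer number of tiling layers per contig (recycled).
#' @param read_length Tile length (final tile of each layer is truncated).
#' @return List with `records`, `contig_lengths`, and `truth` (the planted
#'   depths).
#' @export
simulate_tiling_alignments <- function(contig_lengths, depth,
                                       read_length = 1000) {
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths >= 1))
  depth <- rep_len(as.integer(depth), length(contig_lengths))
  rows <- list()
  for (i in seq_along(contig_lengths)) {
    L <- contig_lengths[[i]]
    starts <- seq.int(0L, L - 1L, by = read_length)
    lens <- pmin(read_length, L - starts)
    for (d in seq_len(depth[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        length = lens, clip_left = 0L, clip_right = 0L,
        target = names(contig_lengths)[i], target_start = starts)
    }
  }
  specs <- do.call(rbind, rows)
  list(records = alignments_from_specs(specs),
       contig_lengths = contig_lengths,
       truth = list(depths = stats::setNames(depth, names(contig_lengths))))
}

#' Write alignment records as a SAM file
#'
#' Emits a minimal valid SAM file (@HD and one @SQ line per contig) from
#' an `alignments` data frame, so fixtures can round-trip through
#' [read_alignments()] and external tools. Sequences and qualities are
#' written as `*`.
#'
#' @param recs An `alignments` data frame.
#' @param contig_lengths Named vector of target lengths for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(recs, contig_lengths, path) {
  stopifnot(is.data.frame(recs), !is.null(names(contig_lengths)))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  flag <- ifelse(!recs$is_mapped, 4L,
                 ifelse(recs$is_secondary, 256L,
                        ifelse(recs$is_supplementary, 2048L, 0L)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  recs$query_id, flag,
                  ifelse(recs$is_mapped, recs$target_id, "*"),
                  ifelse(recs$is_mapped, recs$target_start + 1L, 0L),
                  ifelse(recs$is_mapped, 60L, 0L),
                  ifelse(is.na(recs$cigar), "*", recs$cigar))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Plant isolated indel errors into a gene-scale sequence
#'
#' Introduces `n_homo` single-base insertions/deletions inside
#' homopolymer runs (length >= 3) and `n_random` 2-base mixed-base
#' insertions/deletions at positions whose local context is free of
#' adjacent repeats, all pairwise separated by at least `min_sep` bases so
#' a global aligner recovers each event in isolation. Re-aligning the
#' original against the mutated sequence must recover exactly
#' (`n_homo`, `n_random`) under the default classifier.
#'
#' @param seq Input sequence (character or `DNAString`).
#' @param n_homo,n_random Number of events of each class to plant.
#' @param seed Integer seed.
#' @param min_sep Minimum separation between events in bases (default 10).
#' @return List with `mutated` (character) and `truth` (data frame of
#'   planted events: `kind`, `pos` 0-based in the input, `seq`, `class`;
#'   plus the seed).
#' @export
plant_indels <- function(seq, n_homo, n_random, seed = 1, min_sep = 10) {
  ref <- .validate_bases(as.character(seq))
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  r <- rle(chars)
  run_end <- cumsum(r$lengths)
  run_start0 <- run_end - r$lengths           # 0-based run starts
  homo_runs <- which(r$lengths >= 3L)
  # interior runs only, away from the sequence ends
  homo_runs <- homo_runs[run_start0[homo_runs] >= 5L &
                         run_end[homo_runs] <= n - 5L]
  # random-event anchors: adjacent-distinct 4-base context, interior
  cand <- which(vapply(5:(n - 6L), function(p0) {      # p0 is 0-based
    c0 <- chars[p0]; c1 <- chars[p0 + 1L]; c2 <- chars[p0 + 2L]; c3 <- chars[p0 + 3L]
    c0 != c1 && c1 != c2 && c2 != c3
  }, logical(1)))
  cand0 <- (5:(n - 6L))[cand]
  with_seed(seed, {
    homo_pool <- sample(homo_runs)
    rand_pool <- sample(cand0)
    chosen <- list()   # each: c(lo, hi) span in 0-based ref coords
    ok <- function(lo, hi) {
      all(vapply(chosen, function(s) lo > s[2L] + min_sep || hi < s[1L] - min_sep,
                 logical(1)))
    }
    homo_sel <- integer(0)
    for (k in homo_pool) {
      if (length(homo_sel) >= n_homo) break
      lo <- run_start0[k]; hi <- run_end[k] - 1L
      if (ok(lo, hi)) { chosen[[length(chosen) + 1L]] <- c(lo, hi); homo_sel <- c(homo_sel, k) }
    }
    rand_sel <- integer(0)
    for (p in rand_pool) {
      if (length(rand_sel) >= n_random) break
      if (ok(p, p + 2L)) { chosen[[length(chosen) + 1L]] <- c(p, p + 2L); rand_sel <- c(rand_sel, p) }
    }
    if (length(homo_sel) < n_homo || length(rand_sel) < n_random) {
      stop("sequence too short or too repeat-poor to plant the requested events",
           call. = FALSE)
    }
    events <- list()
    for (i in seq_along(homo_sel)) {
      k <- homo_sel[i]
      b <- r$values[k]
      pos <- run_start0[k] + 1L  # inside the run
      kind <- if (i %% 2L == 0L) "insertion" else "deletion"
      events[[length(events) + 1L]] <- data.frame(
        kind = kind, pos = pos, seq = b, class = "homopolymeric",
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(rand_sel)) {
      p <- rand_sel[i]  # 0-based anchor; chars[p+1] is the base at p
      if (i %% 2L == 0L) {
        x <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        y <- sample(setdiff(c("A", "C", "G", "T"), c(x, chars[p + 1L])), 1L)
        events[[length(events) + 1L]] <- data.frame(
          kind = "insertion", pos = p, seq = paste0(x, y), class = "random",
          stringsAsFactors = FALSE)
      } else {
        events[[length(events) + 1L]] <- data.frame(
          kind = "deletion", pos = p, seq = paste0(chars[p + 1L], chars[p + 2L]),
          class = "random", stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(events)) {
      do.call(rbind, c(events, list(make.row.names = FALSE)))
    } else {
      data.frame(kind = character(), pos = integer(), seq = character(),
                 class = character(), stringsAsFactors = FALSE)
    }
    # apply right-to-left so earlier positions stay valid
    mutated <- chars
    for (j in order(truth$pos, decreasing = TRUE)) {
      p <- truth$pos[j]
      if (truth$kind[j] == "deletion") {
        w <- nchar(truth$seq[j])
        mutated <- c(mutated[seq_len(p)], mutated[seq.int(p + w + 1L, length(mutated))])
      } else {
        ins <- strsplit(truth$seq[j], "", fixed = TRUE)[[1L]]
        mutated <- append(mutated, ins, after = p)
      }
    }
    list(mutated = paste(mutated, collapse = ""),
         truth = list(events = truth, seed = seed))
  })
}
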