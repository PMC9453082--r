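#' Read long reads from a FASTQ file
#'
#' Reads a (optionally gzip-compressed) Sanger-offset FASTQ file into a
#' [Biostrings::QualityScaledDNAStringSet]. Phred scores are decoded as
#' ASCII − 33; bases are upcased and must come from the alphabet
#' \{A,C,G,T,N\}.
#'
#' @param path Path to a FASTQ file, plain or gzipped (compression is
#'   detected from the file content, not the extension).
#' @return A `QualityScaledDNAStringSet`; names are the read identifiers
#'   (the header token before the first whitespace).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' reads <- read_fastq(fq)
#' read_phred(reads)[[1]]  # 40 40 40 40
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  reads <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
      warning = function(w) {
        # internal coercion drops unused metadata columns; not a user concern
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) {
      idx <- .locate_bad_fastq_record(path)
      if (!is.na(idx)) {
        stop(sprintf("malformed FASTQ record %d in '%s': %s",
                     idx, path, conditionMessage(e)), call. = FALSE)
      }
      stop(sprintf("failed to parse FASTQ '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  names(reads) <- sub("\\s.*$", "", names(reads))
  if (length(reads)) {
    # a short quality line comes back NUL-padded rather than short, and the
    # padding breaks Phred decoding; validate by re-scanning the raw records
    qual_ok <- tryCatch({
      qw <- Biostrings::width(Biostrings::quality(reads))
      qmin <- vapply(read_phred(reads), min, numeric(1))
      all(qw == Biostrings::width(reads)) && all(qmin >= 0)
    }, error = function(e) FALSE)
    if (!qual_ok) {
      idx <- .locate_bad_fastq_record(path)
      stop(sprintf(
        "malformed FASTQ record %s in '%s': sequence and quality lengths differ",
        ifelse(is.na(idx), "?", idx), path), call. = FALSE)
    }
    .check_dna_alphabet(reads, "FASTQ read")
    if (any(!nzchar(names(reads)))) {
      stop("FASTQ record with empty identifier", call. = FALSE)
    }
  }
  reads
}

# on parse failure, scan the raw records to report which one is broken
.locate_bad_fastq_record <- function(path) {
  con <- gzfile(path, "rt")  # gzfile reads plain text transparently
  on.exit(close(con))
  i <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0L) return(NA_integer_)
    i <- i + 1L
    if (length(rec) < 4L || !startsWith(rec[1L], "@") ||
        nchar(rec[2L]) != nchar(rec[4L]) || nchar(rec[2L]) == 0L) {
      return(i)
    }
  }
}

.check_dna_alphabet <- function(x, what) {
  af <- Biostrings::alphabetFrequency(x)
  other <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(other > 0)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}",
                 what, which(other > 0)[1L]), call. = FALSE)
  }
  invisible(x)
}

#' Per-read Phred quality vectors
#'
#' @param reads A `QualityScaledDNAStringSet` as returned by [read_fastq()].
#' @return A list of integer vectors, one per read.
#' @export
read_phred <- function(reads) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  as(methods::as(Biostrings::quality(reads), "IntegerList"), "list")
}

#' Read an assembly from a FASTA file
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A [Biostrings::DNAStringSet]; names are contig identifiers
#'   (header token before the first whitespace) and must be unique.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  contigs <- Biostrings::readDNAStringSet(path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  if (any(Biostrings::width(contigs) == 0L)) {
    stop("empty sequence for contig '",
         names(contigs)[Biostrings::width(contigs) == 0L][1L], "'", call. = FALSE)
  }
  dup <- duplicated(names(contigs))
  if (any(dup)) {
    stop("duplicate contig id '", names(contigs)[dup][1L], "'", call. = FALSE)
  }
  if (length(contigs)) .check_dna_alphabet(contigs, "FASTA record")
  contigs
}

#' Write reads to FASTQ / contigs to FASTA
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param contigs A `DNAStringSet`.
#' @param path Output path. A `.gz` suffix triggers gzip compression.
#' @name seq-writers
NULL

#' @rdname seq-writers
#' @export
write_fastq <- function(reads, path) {
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  # records are formatted directly: the Biostrings FASTQ writer truncates
  # (and can crash on) reads beyond ~20 kb, which ONT read sets exceed
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq_along(reads) * 4L - 3L] <- paste0("@", ids)
  lines[seq_along(reads) * 4L - 2L] <- as.character(reads)
  lines[seq_along(reads) * 4L - 1L] <- "+"
  lines[seq_along(reads) * 4L] <- as.character(Biostrings::quality(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname seq-writers
#' @export
write_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

# ---- CIGAR ----------------------------------------------------------------

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
.QUERY_OPS <- c("M", "I", "S", "=", "X")
.REF_OPS   <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' Parses a SAM-grammar CIGAR string into an ordered operation table and
#' validates clip placement: soft (S) and hard (H) clips may occur only at
#' the ends of the alignment, with H outside S.
#'
#' @param text A CIGAR string, or `"*"` for an absent CIGAR.
#' @return A data frame with columns `op` (character) and `len` (integer);
#'   zero rows for `"*"`.
#' @examples
#' parse_cigar("10S80M10S")
#' @export
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (text == "*") return(data.frame(op = character(), len = integer()))
  if (!grepl("^([0-9]+[A-Za-z=])+$", text)) {
    stop("invalid CIGAR string: '", text, "'", call. = FALSE)
  }
  lens <- as.integer(regmatches(text, gregexpr("[0-9]+", text))[[1L]])
  ops  <- regmatches(text, gregexpr("[A-Za-z=]", text))[[1L]]
  if (any(!ops %in% .CIGAR_OPS)) {
    stop("unknown CIGAR operation '", setdiff(ops, .CIGAR_OPS)[1L], "' in '",
         text, "'", call. = FALSE)
  }
  if (any(lens == 0L)) stop("zero-length CIGAR operation in '", text, "'", call. = FALSE)
  .check_clip_placement(ops, text)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# S/H only at ends, H outside S
.check_clip_placement <- function(ops, text) {
  n <- length(ops)
  lead <- 0L
  if (n > lead && ops[lead + 1L] == "H") lead <- lead + 1L
  if (n > lead && ops[lead + 1L] == "S") lead <- lead + 1L
  trail <- 0L
  if (n - trail > lead && ops[n - trail] == "H") trail <- trail + 1L
  if (n - trail > lead && ops[n - trail] == "S") trail <- trail + 1L
  core <- if (lead + 1L <= n - trail) ops[(lead + 1L):(n - trail)] else character()
  if (any(core %in% c("S", "H"))) {
    stop("interior clip operation in CIGAR '", text, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a parsed CIGAR back to text
#' @param cig A data frame as returned by [parse_cigar()].
#' @return A CIGAR string (`"*"` for zero rows).
#' @export
cigar_string <- function(cig) {
  if (nrow(cig) == 0L) return("*")
  paste0(cig$len, cig$op, collapse = "")
}

#' Lengths implied by a CIGAR
#'
#' `cigar_query_length()` sums query-consuming operations (M, I, S, =, X);
#' `cigar_ref_length()` sums reference-consuming operations (M, D, N, =, X);
#' `cigar_clips()` returns the terminal clipped bases.
#'
#' @param cig Parsed CIGAR data frame.
#' @return For `cigar_clips()`, a list with `left`, `right` (S+H bases at
#'   each end) and `hard` (total hard-clipped bases).
#' @name cigar-lengths
NULL

#' @rdname cigar-lengths
#' @export
cigar_query_length <- function(cig) sum(cig$len[cig$op %in% .QUERY_OPS])

#' @rdname cigar-lengths
#' @export
cigar_ref_length <- function(cig) sum(cig$len[cig$op %in% .REF_OPS])

#' @rdname cigar-lengths
#' @export
cigar_clips <- function(cig) {
  n <- nrow(cig)
  left <- 0L; i <- 1L
  while (i <= n && cig$op[i] %in% c("H", "S")) {
    left <- left + cig$len[i]; i <- i + 1L
  }
  right <- 0L; j <- n
  while (j >= i && cig$op[j] %in% c("H", "S")) {
    right <- right + cig$len[j]; j <- j - 1L
  }
  list(left = left, right = right, hard = sum(cig$len[cig$op == "H"]))
}

# ---- alignment records ----------------------------------------------------

#' Read alignments into a normalized record table
#'
#' Normalizes SAM, BAM, or CIGAR-bearing PAF into one record table used by
#' the clip-statistic and coverage modules. SAM/BAM are read through
#' Rsamtools; PAF is a plain tab-separated format parsed directly, with the
#' `cg:Z:` tag supplying the CIGAR and the unaligned query ends converted
#' into terminal soft clips so that both dialects carry the same clip
#' information. PAF records are primary unless tagged `tp:A:S` (secondary)
#' or `tp:A:I` (inversion/supplementary-like).
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"sam"`, `"bam"`, `"paf"`. `"auto"`
#'   resolves from the file extension.
#' @return A data frame of class `alignments` with columns `query_id`,
#'   `is_mapped`, `is_primary`, `is_secondary`, `is_supplementary`,
#'   `target_id` (NA when unmapped), `target_start` (0-based),
#'   `cigar` (`"*"` when absent in SAM, `NA` for a PAF record without a
#'   `cg:Z:` tag), and `stored_query_length` (bases present in the record,
#'   hard clips excluded).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "paf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, sam = "sam", bam = "bam", paf = "paf",
                     stop("cannot infer alignment format from '", path,
                          "'; pass format=", call. = FALSE))
  }
  recs <- switch(format,
    sam = .read_sam_bam(path, is_sam = TRUE),
    bam = .read_sam_bam(path, is_sam = FALSE),
    paf = .read_paf(path))
  class(recs) <- c("alignments", class(recs))
  recs
}

.read_sam_bam <- function(path, is_sam) {
  if (is_sam) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- x$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  cig <- ifelse(is.na(x$cigar), "*", x$cigar)
  stored <- Biostrings::width(x$seq)
  # seq "*" in the source file comes back width 0; fall back to the CIGAR
  fix <- which(stored == 0L & cig != "*")
  if (length(fix)) {
    stored[fix] <- vapply(cig[fix],
                          function(ct) cigar_query_length(parse_cigar(ct)), 0)
  }
  data.frame(
    query_id = x$qname,
    is_mapped = !unmapped,
    is_primary = !unmapped & !secondary & !supplementary,
    is_secondary = secondary,
    is_supplementary = supplementary,
    target_id = ifelse(unmapped, NA_character_, as.character(x$rname)),
    target_start = ifelse(unmapped, NA_integer_, x$pos - 1L),  # 0-based
    cigar = cig,
    stored_query_length = as.integer(stored),
    stringsAsFactors = FALSE
  )
}

.read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), is_mapped = logical(),
                      is_primary = logical(), is_secondary = logical(),
                      is_supplementary = logical(), target_id = character(),
                      target_start = integer(), cigar = character(),
                      stored_query_length = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) stop("PAF record ", bad[1L], " has fewer than 12 fields",
                        call. = FALSE)
  one <- function(f) {
    qlen <- as.integer(f[2L]); qstart <- as.integer(f[3L]); qend <- as.integer(f[4L])
    tags <- f[-(1:12)]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE)[1L])
    tp <- sub("^tp:A:", "", grep("^tp:A:", tags, value = TRUE)[1L])
    secondary <- !is.na(tp) && tp == "S"
    suppl <- !is.na(tp) && tp == "I"
    cigar <- if (is.na(cg)) NA_character_ else {
      lead <- if (qstart > 0L) paste0(qstart, "S") else ""
      trail <- if (qlen - qend > 0L) paste0(qlen - qend, "S") else ""
      paste0(lead, cg, trail)
    }
    list(query_id = f[1L], is_mapped = TRUE,
         is_primary = !secondary && !suppl,
         is_secondary = secondary, is_supplementary = suppl,
         target_id = f[6L], target_start = as.integer(f[8L]),
         cigar = cigar, stored_query_length = qlen)
  }
  rows <- lapply(parts, one)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Validate alignment-record invariants
#'
#' Checks, for every mapped CIGAR-bearing record, that soft/hard clips sit
#' only at the ends and that the query-consuming CIGAR length equals the
#' stored query length.
#'
#' @param recs An `alignments` data frame.
#' @return Invisibly `TRUE`; stops with the offending record index otherwise.
#' @export
validate_alignments <- function(recs) {
  for (i in seq_len(nrow(recs))) {
    ct <- recs$cigar[i]
    if (is.na(ct) || ct == "*") next
    cig <- parse_cigar(ct)
    if (recs$is_mapped[i] && nrow(cig) == 0L) next
    qlen <- cigar_query_length(cig)
    if (qlen != recs$stored_query_length[i]) {
      stop(sprintf("record %d ('%s'): CIGAR query length %d != stored length %d",
                   i, recs$query_id[i], qlen, recs$stored_query_length[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
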