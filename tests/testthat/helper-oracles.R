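# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package paths
# they verify.

# Nx by explicit cumulative scan
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(s))
  acc <- 0
  for (len in s) {
    acc <- acc + len
    if (acc >= x / 100 * total) return(len)
  }
  stop("unreachable")
}

# clipped fraction by regex over the raw CIGAR text
oracle_clipped_fraction <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  full <- sum(len[op %in% c("M", "I", "S", "=", "X", "H")])
  clip <- 0L
  i <- 1L
  while (i <= length(op) && op[i] %in% c("S", "H")) {
    clip <- clip + len[i]; i <- i + 1L
  }
  j <- length(op)
  while (j >= i && op[j] %in% c("S", "H")) {
    clip <- clip + len[j]; j <- j - 1L
  }
  clip / full
}

# exact motif starts (0-based) by position-by-position comparison
oracle_motif_starts <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  for (p in seq_len(max(0L, n - m + 1L))) {
    if (substr(seq, p, p + m - 1L) == motif) hits <- c(hits, p - 1L)
  }
  hits
}

# global alignment score, single-matrix DP with a linear per-base gap cost
oracle_nw_linear <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  ac <- strsplit(a, "")[[1L]]; bc <- strsplit(b, "")[[1L]]
  na <- length(ac); nb <- length(bc)
  dp <- matrix(0, na + 1L, nb + 1L)
  dp[, 1L] <- (0:na) * gap
  dp[1L, ] <- (0:nb) * gap
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sub <- dp[i, j] + if (ac[i] == bc[j]) match else mismatch
      dp[i + 1L, j + 1L] <- max(sub, dp[i, j + 1L] + gap, dp[i + 1L, j] + gap)
    }
  }
  dp[na + 1L, nb + 1L]
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny in-code FASTQ fixture writer
write_fastq_lines <- function(records, path) {
  writeLines(unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", r$qual)
  })), path)
}
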