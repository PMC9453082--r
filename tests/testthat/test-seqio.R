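test_that("FASTQ records decode with the Sanger offset and keep file order", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_lines(list(
    list(id = "r1", seq = "ACGT", qual = "IIII"),
    list(id = "r2 extra comment", seq = "GGNTA", qual = "!!#5I")
  ), fq)
  reads <- read_fastq(fq)
  expect_equal(names(reads), c("r1", "r2"))
  expect_equal(as.character(reads), c(r1 = "ACGT", r2 = "GGNTA"))
  expect_equal(read_phred(reads), list(c(40, 40, 40, 40), c(0, 0, 2, 20, 40)))
})

test_that("empty FASTQ yields an empty read set", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  expect_length(read_fastq(fq), 0L)
})

test_that("FASTQ sequence/quality length mismatch is a parse error naming the record", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_lines(list(
    list(id = "ok", seq = "ACGT", qual = "IIII"),
    list(id = "bad", seq = "ACGT", qual = "III")
  ), fq)
  expect_error(read_fastq(fq), "record 2")
})

test_that("gzip FASTQ is detected from content and round trips byte-exactly", {
  sim <- simulate_reads(15, log(25000), 0.6, 12, 1.5, seed = 42)
  plain <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(sim$reads, plain)
  write_fastq(sim$reads, gz)
  for (p in c(plain, gz)) {
    back <- read_fastq(p)
    expect_identical(as.character(back), as.character(sim$reads))
    expect_identical(read_phred(back), read_phred(sim$reads))
  }
})

test_that("FASTA parsing concatenates multi-line records and validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 desc", "ACGT", "ACGT", ">c2", "TTTT"), fa)
  contigs <- read_fasta(fa)
  expect_equal(as.character(contigs), c(c1 = "ACGTACGT", c2 = "TTTT"))

  writeLines(c(">c1", "ACGT", ">c1", "TT"), fa)
  expect_error(read_fasta(fa), "duplicate contig id")
  writeLines(c(">c1", ""), fa)
  expect_error(read_fasta(fa), "empty sequence")
})

test_that("CIGAR parsing matches the SAM grammar and validates clip placement", {
  cig <- parse_cigar("10S80M10S")
  expect_equal(cig$op, c("S", "M", "S"))
  expect_equal(cig$len, c(10L, 80L, 10L))
  expect_equal(nrow(parse_cigar("*")), 0L)
  expect_error(parse_cigar("5M3S2M"), "interior clip")
  expect_error(parse_cigar("10Q"), "unknown CIGAR")
  expect_error(parse_cigar("0M10S"), "zero-length")
  expect_error(parse_cigar("3S2H10M"), "interior clip")  # H must be outside S
})

test_that("parse_cigar and cigar_string are inverse on generated CIGARs", {
  withr::local_seed(7)
  for (i in 1:200) {
    n_core <- sample(1:6, 1)
    core_ops <- sample(c("M", "I", "D", "=", "X", "N"), n_core, replace = TRUE)
    ops <- c(if (runif(1) < 0.3) "H", if (runif(1) < 0.5) "S",
             core_ops,
             if (runif(1) < 0.5) "S", if (runif(1) < 0.3) "H")
    lens <- sample(1:500, length(ops), replace = TRUE)
    text <- paste0(lens, ops, collapse = "")
    expect_identical(cigar_string(parse_cigar(text)), text)
  }
})

test_that("SAM reading normalizes flags, coordinates and stored lengths", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ctg1\tLN:1000",
    "r1\t0\tctg1\t11\t60\t10S90M\t*\t0\t0\t*\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r3\t256\tctg1\t1\t0\t100M\t*\t0\t0\t*\t*",
    "r4\t2048\tctg1\t1\t60\t5H95M\t*\t0\t0\t*\t*"
  ), sam)
  recs <- read_alignments(sam)
  expect_equal(recs$is_mapped, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(recs$is_primary, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(recs$is_secondary[3], TRUE)
  expect_equal(recs$is_supplementary[4], TRUE)
  expect_equal(recs$target_start[1], 10L)  # SAM POS is 1-based
  expect_equal(recs$stored_query_length[1], 100L)
  expect_true(validate_alignments(recs))
})

test_that("PAF records normalize clips from query coordinates and flag missing CIGARs", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    "r1\t100\t10\t100\t+\tctg1\t1000\t0\t90\t85\t90\t60\ttp:A:P\tcg:Z:90M",
    "r2\t100\t0\t100\t+\tctg1\t1000\t100\t200\t95\t100\t60\ttp:A:S\tcg:Z:100M",
    "r3\t50\t0\t50\t+\tctg1\t1000\t300\t350\t40\t50\t60"
  ), paf)
  recs <- read_alignments(paf)
  expect_equal(recs$cigar[1], "10S90M")
  expect_true(recs$is_secondary[2])
  expect_true(is.na(recs$cigar[3]))
  # CIGAR-requiring downstream ops must error, not skip silently
  expect_error(mapping_completeness(recs), "cg:Z:")
  expect_error(contig_mean_depth(recs, c(ctg1 = 1000)), "cg:Z:")
})
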