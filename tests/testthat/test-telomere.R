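test_that("motif search finds exact overlapping occurrences; N never matches", {
  occ <- find_motif_occurrences("TTAGGGTTAGGG")
  expect_equal(occ$start[occ$motif == "TTAGGG"], c(0L, 6L))
  expect_equal(nrow(find_motif_occurrences("TTAGGN")), 0L)
  # overlapping starts are permitted
  occ2 <- find_motif_occurrences("AAAA", motifs = "AAA")
  expect_equal(occ2$start, c(0L, 1L))
})

test_that("motif counts agree with a position-by-position oracle on random sequence", {
  withr::local_seed(21)
  seq <- random_dna_string(10000)
  occ <- find_motif_occurrences(seq)
  for (m in c("TTAGGG", "CCCTAA")) {
    expect_identical(occ$start[occ$motif == m], oracle_motif_starts(seq, m))
  }
})

test_that("sliding windows tile the contig and count contained occurrences", {
  arr <- strrep("TTAGGG", 17)  # 102 b
  track <- scan_windows(arr, bin_size = 100, step = 25)
  expect_equal(track$start, c(0L, 25L, 50L, 75L, 100L))
  expect_equal(track$end[1], 100L)
  expect_equal(track$motif_count[1], 16L)  # contained starts 0,6,...,90
  expect_equal(track$end[nrow(track)], 102L)  # truncated final window
  expect_true(all(diff(track$start) == 25L))

  quiet <- scan_windows(strrep("ACGT", 50))
  expect_true(all(quiet$motif_count == 0L))

  # a short contig still yields one (truncated) window
  tiny <- scan_windows("ACG", bin_size = 100, step = 25)
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$motif_count, 0L)
})

test_that("window count totals dominate the distinct-occurrence count", {
  withr::local_seed(4)
  sim <- make_assembly_with_telomeres(
    data.frame(length = 2000, left_copies = 8, right_copies = 8), seed = 4)
  seq <- as.character(sim$contigs[[1]])
  track <- scan_windows(seq)
  n_occ <- nrow(find_motif_occurrences(seq))
  expect_gte(sum(track$motif_count), n_occ)
})

test_that("end classification recovers planted telomere maps exactly", {
  sim <- make_assembly_with_telomeres(data.frame(
    length = c(10000, 10000, 10000),
    left_copies = c(10, 10, 0),
    right_copies = c(10, 0, 0)), seed = 9)
  ends <- vapply(seq_along(sim$contigs),
                 function(i) classify_ends(sim$contigs[[i]]), integer(1))
  expect_identical(ends, sim$truth$n_tel_ends)
  expect_identical(ends, c(2L, 1L, 0L))
})

test_that("random sequence never reaches the telomeric-end threshold", {
  # expected exact-motif count per 1 kb end is ~0.5, far below 5 copies
  withr::local_seed(31)
  for (i in 1:5) {
    expect_identical(classify_ends(random_dna_string(10000)), 0L)
  }
})

test_that("reverse-complementing a contig leaves the end count unchanged", {
  sim <- make_assembly_with_telomeres(
    data.frame(length = 8000, left_copies = 7, right_copies = 0), seed = 2)
  fwd <- sim$contigs[[1]]
  rc <- Biostrings::reverseComplement(fwd)
  expect_identical(classify_ends(fwd), classify_ends(rc))
})

test_that("assembly report satisfies the totals identity and honors exclusions", {
  sim <- make_assembly_with_telomeres(data.frame(
    length = rep(10000, 3),
    left_copies = c(10, 10, 0),
    right_copies = c(10, 0, 0)), seed = 9)
  rep <- assembly_telomere_report(sim$contigs)
  expect_equal(rep$total_tel_regions, 3L)
  expect_equal(rep$n_both_ends, 1L)
  expect_equal(rep$n_one_end, 1L)
  expect_equal(rep$n_no_ends, 1L)
  expect_equal(rep$total_tel_regions, 2L * rep$n_both_ends + rep$n_one_end)

  # excluded contigs are flagged and dropped from the totals
  rep2 <- assembly_telomere_report(sim$contigs, exclude_ids = "contig1")
  expect_true(rep2$per_contig$excluded[1])
  expect_equal(rep2$total_tel_regions, 1L)
  expect_warning(assembly_telomere_report(sim$contigs, exclude_ids = "nope"),
                 "not present")

  # all excluded -> totals all zero
  rep3 <- assembly_telomere_report(sim$contigs,
                                   exclude_ids = names(sim$contigs))
  expect_equal(rep3$total_tel_regions, 0L)
  expect_true(all(rep3$per_contig$excluded))
  expect_error(assembly_telomere_report(sim$contigs[0]), "empty")
})

test_that("totals identity holds across generated assemblies", {
  for (seed in 1:5) {
    specs <- withr::with_seed(seed, data.frame(
      length = sample(5000:20000, 6),
      left_copies = sample(0:12, 6, replace = TRUE),
      right_copies = sample(0:12, 6, replace = TRUE)))
    specs$left_copies[specs$left_copies < 5] <- 0   # below threshold = absent
    specs$right_copies[specs$right_copies < 5] <- 0
    sim <- make_assembly_with_telomeres(specs, seed = seed)
    rep <- assembly_telomere_report(sim$contigs)
    expect_equal(rep$total_tel_regions, 2L * rep$n_both_ends + rep$n_one_end)
    expect_identical(rep$per_contig$n_tel_ends, sim$truth$n_tel_ends)
  }
})
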