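test_that("mean depth sums reference-consuming aligned bases over the contig", {
  recs <- alignments_from_specs(data.frame(
    length = 500, clip_left = 0, clip_right = 0, target = "c1",
    target_start = 0))
  expect_equal(contig_mean_depth(recs, c(c1 = 1000)), c(c1 = 0.5))

  # additivity: two abutting 250M records equal one 500M record
  halves <- alignments_from_specs(data.frame(
    length = c(250, 250), clip_left = 0, clip_right = 0, target = "c1",
    target_start = c(0, 250)))
  expect_equal(contig_mean_depth(halves, c(c1 = 1000)), c(c1 = 0.5))

  # no alignments -> zero depth everywhere
  none <- recs[0, ]
  expect_equal(contig_mean_depth(none, c(c1 = 1000, c2 = 5)),
               c(c1 = 0, c2 = 0))
  expect_error(contig_mean_depth(recs, c(other = 1000)), "unknown contig")
})

test_that("deletions advance the reference without adding depth", {
  recs <- data.frame(query_id = "r", is_mapped = TRUE, is_primary = TRUE,
                     is_secondary = FALSE, is_supplementary = FALSE,
                     target_id = "c1", target_start = 0L,
                     cigar = "100M50D100M", stored_query_length = 200L,
                     stringsAsFactors = FALSE)
  expect_equal(contig_mean_depth(recs, c(c1 = 1000))[["c1"]], 0.2)  # 200/1000
})

test_that("exact tiling fixtures give integer depths exactly", {
  tile <- simulate_tiling_alignments(c(c1 = 5000, c2 = 1234), depth = c(100, 7),
                                     read_length = 800)
  d <- contig_mean_depth(tile$records, tile$contig_lengths)
  expect_identical(unname(d), c(100, 7))
})

test_that("plateau estimation reproduces the worked four-contig example", {
  lengths <- c(5e6, 4e6, 0.2e6, 0.05e6)
  depths <- c(100, 98, 40, 400)
  pm <- plateau_mean(lengths, depths)
  expect_equal(pm, (5 * 100 + 4 * 98) / 9, tolerance = 1e-12)  # ~99.11

  expect_equal(plateau_mean(1e6, 88), 88)          # single contig
  expect_equal(plateau_mean(c(2e6, 3e6), c(55, 55)), 55)  # equal depths
  expect_error(plateau_mean(c(1e4, 2e4), c(100, 100)), "manually")  # all short
})

test_that("contig classification applies strict cutoffs and is scale-invariant", {
  pm <- plateau_mean(c(5e6, 4e6, 0.2e6, 0.05e6), c(100, 98, 40, 400))
  cls <- classify_contigs(LETTERS[1:4], c(5e6, 4e6, 0.2e6, 0.05e6),
                          c(100, 98, 40, 400), pm)
  expect_equal(cls$label, c("true", "true", "artifact", "high_copy"))

  # boundary: exactly at the artifact cutoff stays true (strict <)
  at_cut <- classify_contigs("x", 1e6, 0.67 * 100, plateau = 100)
  expect_equal(at_cut$label, "true")
  below <- classify_contigs("x", 1e6, 0.67 * 100 - 1e-9, plateau = 100)
  expect_equal(below$label, "artifact")

  # scale invariance
  for (c_mult in c(0.01, 3, 1000)) {
    scaled <- classify_contigs(LETTERS[1:4], c(5e6, 4e6, 0.2e6, 0.05e6),
                               c_mult * c(100, 98, 40, 400), c_mult * pm)
    expect_equal(scaled$label, cls$label)
  }
})

test_that("planted true/artifact/high-copy depths are classified exactly", {
  tile <- simulate_tiling_alignments(
    c(nuc1 = 2e5, nuc2 = 15e4, art = 6e4, mito = 5e4),
    depth = c(100, 102, 30, 400), read_length = 5000)
  d <- contig_mean_depth(tile$records, tile$contig_lengths)
  pm <- plateau_mean(tile$contig_lengths, d)
  cls <- classify_contigs(names(d), unname(tile$contig_lengths), unname(d), pm)
  expect_equal(cls$label[match(c("nuc1", "nuc2", "art", "mito"), cls$contig_id)],
               c("true", "true", "artifact", "high_copy"))
})

test_that("depth-uniformity flags only planted spikes, robust to degeneracy", {
  expect_length(depth_uniformity(rep(50, 40)), 0L)       # flat track
  spiked <- c(rep(50, 39), 500)
  expect_identical(depth_uniformity(spiked), 40L)        # planted spike
  expect_length(depth_uniformity(rep(0, 20)), 0L)        # all-zero guard
  expect_error(depth_uniformity(rep(1, 5)), "at least 10")
})

test_that("unmapped fraction is a read-level percentage", {
  recs <- alignments_from_specs(data.frame(
    length = rep(100, 3), clip_left = 0, clip_right = 0, target = "c",
    target_start = 0), n_unmapped = 1)
  expect_equal(unmapped_fraction(recs), 25)
  expect_equal(unmapped_fraction(recs[recs$is_mapped, ]), 0)
  expect_equal(unmapped_fraction(recs[!recs$is_mapped, , drop = FALSE]), 100)
  expect_error(unmapped_fraction(recs[0, ]), "no read-level")
})
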