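test_that("merge_elements obeys the 500 bp boundary exactly", {
  # gap 450 <= 500: merged
  m <- merge_elements(genomic_intervals("chr1", c(100, 650), c(200, 700)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 700))
  # gap 501 > 500: kept apart
  m2 <- merge_elements(genomic_intervals("chr1", c(100, 701), c(200, 800)))
  expect_equal(nrow(m2), 2)
  # gap exactly 500 merges; 500 + 1 does not
  m3 <- merge_elements(genomic_intervals("chr1", c(0, 600), c(100, 700)))
  expect_equal(nrow(m3), 1)
  # identity
  single <- genomic_intervals("chr2", 5, 10)
  expect_equal(merge_elements(single), single)
})

test_that("merged output never leaves a small gap (scan property)", {
  w <- small_world()
  for (tab in list(w$ds$enhancers, w$ds$promoters)) {
    for (ch in unique(tab$chrom)) {
      sub <- tab[chrom == ch][order(start)]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] > 500))
    }
  }
})

test_that("call_positive_epis pairs anchors with merged elements", {
  enh <- genomic_intervals("chr1", c(1000, 1900), c(1500, 2400))
  prom <- genomic_intervals("chr1", 50000, 51000)
  loop1 <- data.table::data.table(chrom = "chr1", start1 = 1200, end1 = 1300,
                                  start2 = 50100, end2 = 50200, score = 1)
  pos <- call_positive_epis(loop1, enh, prom)
  expect_equal(nrow(pos), 1)
  expect_equal(pos$enh_start, 1000)   # the element, not the anchor
  expect_equal(pos$prom_start, 50000)
  expect_equal(pos$distance, abs(1250 - 50500))
  expect_equal(attr(pos, "n_unmatched"), 0)

  # both anchors only over enhancers -> nothing
  loop2 <- data.table::data.table(chrom = "chr1", start1 = 1100, end1 = 1200,
                                  start2 = 2000, end2 = 2100, score = 1)
  none <- call_positive_epis(loop2, enh, prom)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_unmatched"), 1)

  # one anchor over 2 enhancers, other over 1 promoter -> cross product of 2
  wide <- data.table::data.table(chrom = "chr1", start1 = 1100, end1 = 2300,
                                 start2 = 50100, end2 = 50200, score = 1)
  two <- call_positive_epis(wide, enh, prom)
  expect_equal(nrow(two), 2)
  # duplicates across loops collapse
  dup <- call_positive_epis(rbind(loop1, loop1), enh, prom)
  expect_equal(nrow(dup), 1)
})

test_that("enumerate_candidates applies distance bounds and overlap exclusion", {
  enh <- genomic_intervals("chr1", c(0, 100000), c(1000, 101000))
  prom <- genomic_intervals("chr1", c(20000, 190000), c(21000, 191000))
  cand <- enumerate_candidates(enh, prom, 5e3, 2e6)
  expect_equal(nrow(cand), 4)  # 2 x 2 cross product, all in range
  expect_true(all(cand$distance == rtepi:::pair_distance(cand)))

  far <- enumerate_candidates(enh, genomic_intervals("chr1", 5e6, 5e6 + 1000),
                              5e3, 2e6)
  expect_equal(nrow(far), 0)   # beyond max_distance
  near <- enumerate_candidates(enh, genomic_intervals("chr1", 500, 1500),
                               5e3, 2e6)
  expect_false(any(near$enh_start == 0))  # overlapping pair excluded
})

test_that("sample_negatives matches per-bin counts and reports shortfalls", {
  cfg <- dataset_config(seed = 9, distance_bins = c(5e3, 1e5, 2e6))
  mk <- function(n, d0, label) data.table::data.table(
    chrom = "c", enh_start = seq_len(n) * 10, enh_end = seq_len(n) * 10 + 5,
    prom_start = seq_len(n) * 10 + d0, prom_end = seq_len(n) * 10 + d0 + 5,
    distance = rep(d0, n), label = label, source = "t")
  pos <- mk(3, 50000, "positive")
  cand <- mk(100, 50400, "unlabeled")
  neg <- sample_negatives(pos, cand, cfg)
  expect_equal(nrow(neg), 60)          # 3 positives x 20, one bin
  sf <- attr(neg, "shortfall")
  expect_equal(sum(sf$shortfall), 0)

  # insufficient candidates: take all 5, report shortfall of 15
  neg2 <- sample_negatives(mk(1, 50000, "positive"), mk(5, 50400, "unlabeled"), cfg)
  expect_equal(nrow(neg2), 5)
  expect_equal(sum(attr(neg2, "shortfall")$shortfall), 15)

  # determinism
  expect_equal(sample_negatives(pos, cand, cfg), sample_negatives(pos, cand, cfg))
  expect_error(sample_negatives(pos[0], cand, cfg), "no positives")
  expect_error(sample_negatives(pos, cand[0], cfg), "no candidates")
  expect_error(sample_negatives(pos, pos, cfg), "exclude all positive")
})

test_that("distance matching holds per bin across the built dataset", {
  w <- small_world()
  cfg <- dataset_config(seed = 42)
  pos_bin <- rtepi:::assign_distance_bin(w$ds$positives$distance, cfg$distance_bins)
  neg_bin <- rtepi:::assign_distance_bin(w$ds$negatives$distance, cfg$distance_bins)
  sf <- w$ds$shortfall
  for (b in sf$bin) {
    expect_equal(sum(neg_bin == b),
                 cfg$neg_pos_ratio * sum(pos_bin == b) -
                   sf$shortfall[sf$bin == b])
  }
  # no negative coincides with a positive
  expect_length(intersect(rtepi:::pair_key(w$ds$negatives),
                          rtepi:::pair_key(w$ds$positives)), 0)
})

test_that("matched negatives track the positive distance distribution (KS)", {
  # abundant-candidate world: few loops, so every bin fills without shortfall
  ds <- nosf_world()$ds
  expect_equal(sum(ds$shortfall$shortfall), 0)
  expect_equal(nrow(ds$negatives), 20 * nrow(ds$positives))
  expect_lt(ks_stat(ds$positives$distance, ds$negatives$distance), 0.1)
})

test_that("pair tables round-trip through TSV", {
  w <- small_world()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(w$ds$pairs, p)
  back <- read_pair_table(p)
  expect_equal(back, w$ds$pairs, ignore_attr = TRUE)
})
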