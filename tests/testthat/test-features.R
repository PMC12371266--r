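test_that("default scheme emits exactly 482 uniquely named features", {
  scheme <- feature_scheme()
  expect_equal(scheme_dim(scheme), 482L)
  nm <- feature_names(scheme)
  expect_length(nm, 482)
  expect_false(anyDuplicated(nm) > 0)
  # dimensionality formula holds for arbitrary schemes
  for (s in list(feature_scheme(window_sizes = c(500, 5000), bins_per_side = 7),
                 feature_scheme(window_sizes = 1000, bins_per_side = 1,
                                include_anchor_mean = FALSE))) {
    expect_length(feature_names(s), scheme_dim(s))
  }
})

test_that("feature groups partition columns by anchor and scale", {
  scheme <- feature_scheme()
  g <- feature_groups(scheme)
  expect_length(g$promoter, 241)           # 1 + 6 scales x 40
  expect_length(g$enhancer, 241)
  expect_length(g$scale_500, 80)           # 2 anchors x 40
  expect_setequal(c(g$promoter, g$enhancer), feature_names(scheme))
  scale_cols <- unlist(g[startsWith(names(g), "scale_")])
  expect_setequal(scale_cols, feature_names(scheme))
})

test_that("constant profile encodes to a constant vector", {
  prof <- rt_profile(data.table::data.table(
    chrom = "chrF", start = 0, end = 5e6, value = 1.25))
  pair <- data.table::data.table(chrom = "chrF",
                                 enh_start = 2.0e6, enh_end = 2.001e6,
                                 prom_start = 2.5e6, prom_end = 2.501e6)
  v <- encode_pair(pair, prof)
  expect_length(v, 482)
  expect_true(all(v == 1.25))
})

test_that("step profile fills upstream and downstream bins as placed", {
  scheme <- feature_scheme(window_sizes = 500, bins_per_side = 3)
  prof <- step_profile(edge = 100000, left = -1, right = 2, len = 2e5)
  # anchor [100000, 101000) sits at the step edge? no: keep it inside 'right'
  pair <- data.table::data.table(chrom = "chrF",
                                 enh_start = 110000, enh_end = 111000,
                                 prom_start = 150000, prom_end = 151000)
  v <- encode_pair(pair, prof, scheme)
  # all windows right of the edge: everything = 2
  expect_true(all(v == 2))
  # enhancer anchored just right of the edge: its upstream bins read 'left'
  pair2 <- data.table::data.table(chrom = "chrF",
                                  enh_start = 100000, enh_end = 101000,
                                  prom_start = 150000, prom_end = 151000)
  v2 <- encode_pair(pair2, prof, scheme)
  expect_true(all(v2[grep("^enh_up_", names(v2))] == -1))
  expect_true(all(v2[grep("^enh_down_", names(v2))] == 2))
  expect_true(all(v2[grep("^prom_", names(v2))] == 2))
})

test_that("encoding is translation invariant", {
  w <- small_world()
  shift <- 1e6
  prof <- w$sim$profile
  shifted_prof <- rt_profile(data.table::data.table(
    chrom = "chrS",
    start = prof$chroms$chrS$start + shift,
    end = prof$chroms$chrS$end + shift,
    value = prof$chroms$chrS$value))
  pairs <- head(w$ds$pairs, 5)
  shifted_pairs <- data.table::copy(pairs)
  for (col in c("enh_start", "enh_end", "prom_start", "prom_end"))
    shifted_pairs[[col]] <- shifted_pairs[[col]] + shift
  expect_equal(encode_dataset(pairs, prof)$x,
               encode_dataset(shifted_pairs, shifted_prof)$x)
})

test_that("mirroring the genome swaps up/down features within each anchor", {
  scheme <- feature_scheme(window_sizes = c(500, 2000), bins_per_side = 4)
  w <- small_world()
  prof <- w$sim$profile
  L <- 2e7
  bins <- prof$chroms$chrS
  mirrored <- rt_profile(data.table::data.table(
    chrom = "chrS", start = rev(L - bins$end), end = rev(L - bins$start),
    value = rev(bins$value)))
  pair <- head(w$ds$pairs, 3)
  mpair <- data.table::copy(pair)
  mpair$enh_start <- L - pair$enh_end
  mpair$enh_end <- L - pair$enh_start
  mpair$prom_start <- L - pair$prom_end
  mpair$prom_end <- L - pair$prom_start
  v <- encode_dataset(pair, prof, scheme)$x
  mv <- encode_dataset(mpair, mirrored, scheme)$x
  swap <- function(nms) {
    out <- sub("_up_", "_UP_", nms)
    out <- sub("_down_", "_up_", out)
    sub("_UP_", "_down_", out)
  }
  expect_equal(v, mv[, match(colnames(v), swap(colnames(mv)))],
               ignore_attr = TRUE)
})

test_that("encode_dataset keeps row order, is deterministic, errors usefully", {
  w <- small_world()
  pairs <- head(w$ds$pairs, 5)
  fm <- encode_dataset(pairs, w$sim$profile)
  expect_equal(nrow(fm$x), 5)
  expect_equal(fm$meta$distance, pairs$distance)
  expect_equal(fm$x, encode_dataset(pairs, w$sim$profile)$x)

  empty <- encode_dataset(pairs[0], w$sim$profile)
  expect_equal(dim(empty$x), c(0L, 482L))

  off <- data.table::copy(pairs)[1, chrom := "chrZ"]
  expect_error(encode_dataset(off, w$sim$profile), "chrZ")
})

test_that("missing windows are imputed per policy", {
  prof <- step_profile(edge = 10000, left = 1, right = 3, len = 20000)
  scheme <- feature_scheme(window_sizes = 50000, bins_per_side = 2)
  pair <- data.table::data.table(chrom = "chrF", enh_start = 1000,
                                 enh_end = 2000, prom_start = 15000,
                                 prom_end = 16000)
  v <- encode_pair(pair, prof, scheme)
  expect_false(anyNA(v))
  chrom_mean <- (10000 * 1 + 10000 * 3) / 20000
  expect_true(any(v == chrom_mean))   # off-chromosome windows -> imputed
  v0 <- encode_pair(pair, prof, feature_scheme(window_sizes = 50000,
                                               bins_per_side = 2,
                                               imputation = "none"))
  expect_true(anyNA(v0))
})

test_that("schemes and feature matrices round-trip through text files", {
  scheme <- feature_scheme(window_sizes = c(500, 1000), bins_per_side = 3,
                           min_coverage = 0.4)
  p <- withr::local_tempfile(fileext = ".txt")
  write_scheme(scheme, p)
  expect_equal(read_scheme(p), scheme)

  w <- small_world()
  fm <- fm_subset(w$fm, rows = 1:8)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, fp)
  back <- read_feature_matrix(fp)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_equal(back$meta$label, fm$meta$label)
  expect_equal(scheme_fingerprint(back$scheme), scheme_fingerprint(fm$scheme))
})
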