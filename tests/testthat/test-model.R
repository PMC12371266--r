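test_that("training separates a separable toy problem and is deterministic", {
  fm <- make_toy_fm(n = 300, effect = 6, noise = 0.1, seed = 2)
  m1 <- train(fm, seed = 5, num_trees = 60)
  expect_equal(auroc(predict(m1, fm), rtepi:::fm_labels(fm)), 1)
  m2 <- train(fm, seed = 5, num_trees = 60)
  expect_identical(predict(m1, fm), predict(m2, fm))
  m3 <- train(fm, seed = 6, num_trees = 60)
  expect_false(identical(predict(m1, fm), predict(m3, fm)))
})

test_that("single-class input and fingerprint mismatches are refused", {
  fm <- make_toy_fm(n = 50, seed = 3)
  fm$meta$label <- "positive"
  expect_error(train(fm), "single class")

  fm2 <- make_toy_fm(n = 80, seed = 4)
  model <- train(fm2, seed = 1, num_trees = 20)
  other <- fm2
  colnames(other$x)[1] <- "renamed"
  expect_error(predict(model, other), "fingerprint mismatch")
})

test_that("permuted labels score near prevalence out of sample", {
  fm <- make_toy_fm(n = 2000, prevalence = 0.1, effect = 3, seed = 6)
  fm$meta$label <- withr::with_seed(7, sample(fm$meta$label))
  ev <- cross_validate(fm, k = 5, seed = 7, num_trees = 80)
  expect_lt(abs(ev$auprc - ev$baseline), 0.05)
})

test_that("cross_validate partitions samples and stratifies by label", {
  fm <- make_toy_fm(n = 100, seed = 8)
  ev <- cross_validate(fm, k = 5, seed = 8, num_trees = 20)
  # every sample scored exactly once out-of-fold: scores fully populated
  expect_length(ev$scores, 100)
  expect_false(anyNA(ev$scores))
  expect_equal(nrow(ev$per_split), 5)
  expect_equal(ev$baseline, mean(rtepi:::fm_labels(fm)))
  # tiny class cannot be split into k folds
  small <- fm_subset(fm, rows = c(which(rtepi:::fm_labels(fm) == 1)[1:3],
                                  which(rtepi:::fm_labels(fm) == 0)))
  expect_error(cross_validate(small, k = 5, seed = 1), "more data")
})

test_that("resample_evaluate reports per-replicate spread reproducibly", {
  fm <- make_toy_fm(n = 150, seed = 9)
  ev <- resample_evaluate(fm, n_reps = 8, test_fraction = 0.25, seed = 3,
                          num_trees = 20)
  expect_equal(nrow(ev$per_split), 8)
  expect_gte(ev$auprc_sd, 0)
  ev2 <- resample_evaluate(fm, n_reps = 8, test_fraction = 0.25, seed = 3,
                           num_trees = 20)
  expect_equal(ev$auprc_mean, ev2$auprc_mean)
})

test_that("cross_sample_matrix reflects shared vs independent couplings", {
  d1 <- make_toy_fm(n = 250, effect = 3, seed = 10)
  d1b <- make_toy_fm(n = 250, effect = 3, seed = 11)      # same coupling
  d_enh <- make_toy_fm(n = 250, effect = 3, seed = 12,
                       planted_anchor = "enh")             # different coupling
  mat <- cross_sample_matrix(list(a = d1, b = d1b, c = d_enh),
                             seed = 4, num_trees = 40)
  expect_equal(dim(mat), c(3L, 3L))
  # same-coupling transfer stays near within-dataset performance
  expect_gt(mat["a", "b"], 0.8 * mat["a", "a"])
  # independent coupling transfers poorly
  expect_lt(mat["a", "c"], mat["a", "b"])
})

test_that("train_general pools rows and matches single-source training", {
  d <- make_toy_fm(n = 300, effect = 3, seed = 13)
  test_d <- make_toy_fm(n = 300, effect = 3, seed = 14)
  y <- rtepi:::fm_labels(test_d)
  single <- auprc(predict(train(d, seed = 5, num_trees = 60), test_d), y)
  pooled_model <- train_general(list(a = d, b = d, c = d), seed = 5,
                                num_trees = 60)
  pooled <- auprc(predict(pooled_model, test_d), y)
  expect_lt(abs(pooled - single), 0.03)
  expect_equal(pooled_model$provenance, c("a", "b", "c"))

  mismatched <- make_toy_fm(n = 50, seed = 15)
  colnames(mismatched$x)[2] <- "odd"
  expect_error(train_general(list(a = d, b = mismatched)), "mismatched")
})

test_that("pooled model is no worse than the worst single-source model", {
  da <- make_toy_fm(n = 250, effect = 3, seed = 16)
  db <- make_toy_fm(n = 250, effect = 3, seed = 17, planted_anchor = "enh")
  mix <- make_toy_fm(n = 200, effect = 3, seed = 18)
  mix2 <- make_toy_fm(n = 200, effect = 3, seed = 19, planted_anchor = "enh")
  test_mix <- structure(list(x = rbind(mix$x, mix2$x),
                             meta = rbind(mix$meta, mix2$meta),
                             scheme = mix$scheme), class = "epi_fm")
  y <- rtepi:::fm_labels(test_mix)
  singles <- vapply(list(da, db), function(d)
    auprc(predict(train(d, seed = 6, num_trees = 60), test_mix), y), numeric(1))
  pooled <- auprc(predict(train_general(list(a = da, b = db), seed = 6,
                                        num_trees = 60), test_mix), y)
  expect_gte(pooled, min(singles))
})

test_that("models round-trip through save/load", {
  fm <- make_toy_fm(n = 80, seed = 20)
  model <- train(fm, seed = 2, num_trees = 15)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p)
  back <- load_model(p)
  expect_identical(predict(back, fm), predict(model, fm))
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "model file")
})
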