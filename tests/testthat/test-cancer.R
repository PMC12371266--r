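test_that("select_top_epis applies deterministic tie-breaking", {
  sc <- data.table::data.table(
    chrom = "c", enh_start = c(10, 30, 20, 40), enh_end = c(15, 35, 25, 45),
    prom_start = c(100, 300, 200, 400), prom_end = c(105, 305, 205, 405),
    distance = 100, label = "unlabeled", source = "t",
    score = c(0.9, 0.5, 0.5, 0.1))
  top <- select_top_epis(sc, 2)
  expect_equal(nrow(top), 2)
  # tie at 0.5 resolved by coordinates: enh_start 20 before 30
  expect_equal(top$enh_start, c(10, 20))
  expect_equal(nrow(select_top_epis(sc, 100)), 4)
  expect_equal(nrow(select_top_epis(sc, 3)), 3)
})

test_that("sample matrix has one row per profile and respects identity", {
  w <- small_world()
  model <- train(w$fm, seed = 33, num_trees = 60)
  epis <- head(w$ds$positives, 12)
  prof <- w$sim$profile
  p1 <- rt_profile(data.table::data.table(
    chrom = "chrS", start = prof$chroms$chrS$start,
    end = prof$chroms$chrS$end, value = prof$chroms$chrS$value),
    sample_id = "s1", group = "A")
  p2 <- rt_profile(data.table::data.table(
    chrom = "chrS", start = prof$chroms$chrS$start,
    end = prof$chroms$chrS$end, value = prof$chroms$chrS$value),
    sample_id = "s2", group = "B")
  mat <- build_sample_matrix(epis, model, list(p1, p2))
  expect_equal(dim(mat), c(2L, 12L))
  expect_equal(unname(mat[1, ]), unname(mat[2, ]))  # identical profiles
  expect_equal(rownames(mat), c("s1", "s2"))
  expect_equal(attr(mat, "groups"), c("A", "B"))
  expect_true(all(mat >= 0 & mat <= 1))
})

random_prob_matrix <- function(n_samples = 6, n_epis = 15, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_samples * n_epis), n_samples,
                dimnames = list(paste0("s", 1:n_samples),
                                paste0("e", 1:n_epis)))
    attr(m, "groups") <- rep(c("A", "B"), each = n_samples / 2)
    m
  })
}

test_that("group-specific calls partition the EPI set", {
  ones <- random_prob_matrix(seed = 2)
  ones[] <- 1
  all_common <- call_group_specific(ones)
  expect_setequal(all_common$common, colnames(ones))
  expect_length(all_common$a_specific, 0)

  zeros <- ones
  zeros[] <- 0
  all_neither <- call_group_specific(zeros)
  expect_setequal(all_neither$neither, colnames(zeros))

  for (s in 1:10) {
    m <- random_prob_matrix(seed = s)
    calls <- call_group_specific(m)
    sets <- list(calls$a_specific, calls$common, calls$b_specific, calls$neither)
    expect_equal(sum(lengths(sets)), ncol(m))
    expect_setequal(unlist(sets), colnames(m))
    for (i in 1:3) for (j in (i + 1):4)
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    # renaming groups leaves the partition intact (label invariance)
    renamed <- call_group_specific(m, groups = ifelse(
      attr(m, "groups") == "A", "ALL", "normal"))
    expect_setequal(renamed$a_specific, calls$a_specific)
    expect_setequal(renamed$b_specific, calls$b_specific)
    expect_equal(renamed$group_a, "ALL")
    # swapping which samples form each group swaps the specific sets
    swapped <- m[c(4:6, 1:3), , drop = FALSE]
    attr(swapped, "groups") <- attr(m, "groups")
    calls2 <- call_group_specific(swapped)
    expect_setequal(calls2$a_specific, calls$b_specific)
    expect_setequal(calls2$b_specific, calls$a_specific)
    expect_setequal(calls2$common, calls$common)
  }
})

test_that("vote mode differs from mean mode where they should", {
  # group A on e1: mean 0.60 (positive by mean) but only 1/3 votes
  m <- matrix(c(0.45, 0.45, 0.9, 0, 0, 0), ncol = 1,
              dimnames = list(paste0("s", 1:6), "e1"))
  attr(m, "groups") <- rep(c("A", "B"), each = 3)
  by_mean <- call_group_specific(m, mode = "mean")
  by_vote <- call_group_specific(m, mode = "vote")
  expect_equal(by_mean$a_specific, "e1")
  expect_equal(by_vote$neither, "e1")
  expect_error(call_group_specific(m, groups = rep("A", 6)), "two groups")
})

test_that("hierarchical clustering separates block structure deterministically", {
  withr::with_seed(41, {
    blocks <- rbind(matrix(rnorm(40, mean = 0, sd = 0.1), 4),
                    matrix(rnorm(40, mean = 3, sd = 0.1), 4))
    rownames(blocks) <- paste0("s", 1:8)
  })
  cl <- hierarchical_cluster(blocks, k = 2)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 4)), 1)
  # k = n gives singletons
  expect_length(unique(hierarchical_cluster(blocks, k = 8)), 8)
  expect_error(hierarchical_cluster(blocks, k = 9), "exceeds")
  # duplicated samples co-cluster
  dup <- blocks[c(1, 1, 5, 6), ]
  cl2 <- hierarchical_cluster(dup, k = 2)
  expect_equal(cl2[1], cl2[2])
})
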