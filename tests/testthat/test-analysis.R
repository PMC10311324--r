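test_that("Fowlkes-Mallows matches pair-enumeration examples", {
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # truth {1,2},{3,4} vs prediction {1,3},{2,4}: no co-clustered pair agrees
  expect_equal(fowlkes_mallows(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  # truth {1,2,3},{4} vs prediction {1,2},{3,4}: TP=1, FP=1, FN=2
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c("a", "a", "a", "b")),
               1 / sqrt(6))
  # label permutation does not matter
  expect_equal(fowlkes_mallows(c(7, 7, 3, 3), c("b", "b", "a", "a")), 1)
  expect_error(fowlkes_mallows(c(1, 2), c("a", "b", "c")), "length")
  expect_error(fowlkes_mallows(c(x = 1, y = 2), c(a = "u", b = "v")),
               "sample sets")
})

test_that("duplicated-profile clouds separate perfectly on both routes", {
  tr <- toy_t0()
  M <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0),
             c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  rownames(M) <- paste0("s", 1:6); colnames(M) <- tr$ids
  truth <- setNames(rep(c("a", "b"), each = 3), rownames(M))
  km <- cluster_l2_space(M, tr, k = 2, seed = 1)
  expect_equal(fowlkes_mallows(km$assignment, truth), 1)
  pam <- cluster_dmat(pairwise_unifrac(M, tr, "l2"), k = 2, seed = 1)
  expect_equal(fowlkes_mallows(pam$assignment, truth), 1)
})

test_that("k-means edge cases and determinism", {
  fx <- small_cohort(n_leaves = 16, n_env = 2, per_env = 5, seed = 2)
  k1 <- cluster_l2_space(fx$cohort, k = 1, seed = 0)
  expect_true(all(k1$assignment == 1))
  expect_error(cluster_l2_space(fx$cohort, k = 99, seed = 0), "between")
  a <- cluster_l2_space(fx$cohort, k = 2, seed = 7)
  b <- cluster_l2_space(fx$cohort, k = 2, seed = 7)
  expect_identical(a$assignment, b$assignment)
  # objective is non-increasing across Lloyd iterations, converges < 300
  expect_true(all(diff(a$objective_trace) <= 1e-9))
  expect_lt(a$iterations, 300)
})

test_that("PAM route validates input and handles k = n", {
  fx <- small_cohort(n_leaves = 8, n_env = 2, per_env = 3, seed = 3)
  D <- pairwise_unifrac(fx$cohort, metric = "l2")
  n <- nrow(D)
  every <- cluster_dmat(D, k = n, seed = 0)
  expect_identical(sort(unique(unname(every$assignment))), 1:n)
  asym <- unclass(D); asym[1, 2] <- asym[1, 2] + 1
  expect_error(cluster_dmat(asym, k = 2), "symmetric")
  neg <- unclass(D); neg[1, 2] <- neg[2, 1] <- -1
  expect_error(cluster_dmat(neg, k = 2), "negative")
})

test_that("train/test split is stratified, deterministic, and validated", {
  fx <- small_cohort(n_leaves = 8, n_env = 3, per_env = 10, seed = 5)
  sp <- train_test_split(fx$cohort, fraction = 0.8, seed = 1)
  for (e in unique(fx$cohort$labels)) {
    expect_identical(sum(sp$train$labels == e), 8L)
    expect_identical(sum(sp$test$labels == e), 2L)
  }
  sp2 <- train_test_split(fx$cohort, fraction = 0.8, seed = 1)
  expect_identical(rownames(sp$train$profiles), rownames(sp2$train$profiles))
  sp3 <- train_test_split(fx$cohort, fraction = 0.8, seed = 2)
  expect_false(identical(rownames(sp$train$profiles),
                         rownames(sp3$train$profiles)))
  expect_error(train_test_split(fx$cohort, fraction = 1.0), "between")
  tiny <- uf_cohort(fx$cohort$profiles[c(1, 11, 21), ],
                    fx$cohort$labels[c(1, 11, 21)], fx$tree)
  expect_error(train_test_split(tiny, 0.8), "fewer than 2")
})

test_that("nearest-representative classification and tie-breaking", {
  # symmetric tree: equal branch lengths, so the root is equidistant from
  # the two environment representatives; tie goes to the first env name
  tr <- read_newick(text = "((A:1.0,B:1.0)R:0.0);")
  M <- rbind(a1 = c(1, 0, 0), b1 = c(0, 1, 0))
  colnames(M) <- tr$ids
  train <- uf_cohort(M, c(a1 = "enva", b1 = "envb"), tr)
  test_profiles <- rbind(t1 = c(0, 0, 1), t2 = c(1, 0, 0))
  colnames(test_profiles) <- tr$ids
  res <- classify_nearest_representative(train, test_profiles, tr)
  expect_identical(unname(res$predictions["t1"]), "enva")  # tie-break
  expect_identical(unname(res$predictions["t2"]), "enva")

  # a training barycenter classifies to its own environment
  fx <- small_cohort(n_leaves = 16, n_env = 3, per_env = 5, seed = 8)
  reps <- environment_barycenters(fx$cohort)
  Xr <- do.call(rbind, lapply(reps, `[[`, "profile"))
  rownames(Xr) <- paste0("rep_", names(reps))
  res2 <- classify_nearest_representative(fx$cohort, Xr, fx$tree)
  expect_identical(unname(res2$predictions), names(reps))
})

test_that("classification reports accuracy on labeled test cohorts", {
  fx <- small_cohort(n_leaves = 32, n_env = 3, per_env = 10, seed = 21)
  sp <- train_test_split(fx$cohort, 0.8, seed = 0)
  res <- classify_nearest_representative(sp$train, sp$test)
  expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  expect_identical(sum(res$per_class), length(res$predictions))
})

test_that("majority-vote labeling surfaces missing environments", {
  asg <- structure(c(1L, 1L, 2L, 2L), names = paste0("s", 1:4),
                   class = NULL)
  clustering <- structure(list(assignment = asg), class = "uf_clustering")
  labels <- setNames(c("a", "a", "a", "b"), paste0("s", 1:4))
  mv <- majority_vote_labels(clustering, labels)
  expect_identical(unname(mv$predictions),
                   unname(mv$cluster_labels[as.character(asg)]))
  labels2 <- setNames(c("a", "a", "a", "a"), paste0("s", 1:4))
  mv2 <- majority_vote_labels(clustering, labels2)
  expect_identical(mv2$missing_labels, character(0))
  labels3 <- setNames(c("a", "b", "a", "b"), paste0("s", 1:4))
  mv3 <- majority_vote_labels(clustering, labels3)
  expect_identical(mv3$cluster_labels, c(`1` = "a", `2` = "a"))
  expect_identical(mv3$missing_labels, "b")
})

test_that("aggregated-space clustering never touches pairwise distances", {
  fx <- small_cohort(n_leaves = 16, n_env = 2, per_env = 10, seed = 6)
  M <- nrow(fx$cohort$profiles)
  reset_op_counters()
  km <- cluster_l2_space(fx$cohort, k = 2, seed = 0)
  counts <- op_counters()
  expect_equal(counts$pair_norms, 0)
  expect_equal(km$n_pair_computations, 0)
  expect_equal(km$n_aggregations, M)
  reset_op_counters()
  D <- pairwise_unifrac(fx$cohort, metric = "l2")
  counts2 <- op_counters()
  expect_equal(counts2$aggregations, M)
  expect_equal(counts2$pair_norms, M * (M - 1) / 2)
  reset_op_counters()
})
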