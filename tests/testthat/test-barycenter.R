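test_that("toy barycenter matches hand value and a grid-search oracle", {
  tr <- toy_t0()
  rep2 <- l2_barycenter(rbind(c(1, 0, 0), c(0, 1, 0)), tr)
  expect_equal(unname(rep2$profile), c(0.5, 0.5, 0))
  expect_identical(rep2$method, "l2_mean")
  expect_identical(rep2$n_samples, 2L)

  # independent oracle: exhaustive grid over the 3-simplex, step 0.01,
  # minimizing the sum of squared L2-UniFrac distances
  cohort <- rbind(c(1, 0, 0), c(0, 1, 0))
  grid <- expand.grid(a = seq(0, 1, 0.01), b = seq(0, 1, 0.01))
  grid <- grid[grid$a + grid$b <= 1 + 1e-12, ]
  obj <- vapply(seq_len(nrow(grid)), function(i) {
    x <- c(grid$a[i], grid$b[i], 1 - grid$a[i] - grid$b[i])
    l2_unifrac(cohort[1, ], x, tr)^2 + l2_unifrac(cohort[2, ], x, tr)^2
  }, numeric(1))
  best <- grid[which.min(obj), ]
  expect_equal(c(best$a, best$b), c(0.5, 0.5), tolerance = 0.011)

  # degenerate cohorts
  P <- c(0.2, 0.3, 0.5)
  expect_equal(unname(l2_barycenter(rbind(P), tr)$profile), P)
  expect_equal(unname(l2_barycenter(rbind(P, P, P, P), tr)$profile), P)
  expect_error(l2_barycenter(matrix(numeric(0), 0, 3), tr), "empty|sum")
})

test_that("aggregate->mean->inverse equals the component-wise profile mean", {
  for (seed in 1:60) {
    tr <- rand_tree(seed)
    m <- 2 + seed %% 6
    X <- do.call(rbind, lapply(seq_len(m), function(j)
      rand_profile(tr, 1000 * seed + j)))
    bary <- l2_barycenter(X, tr)$profile
    expect_lt(max(abs(bary - colMeans(X))), 1e-10)
    expect_true(all(bary >= 0))
    expect_equal(sum(bary), 1, tolerance = 1e-12)
  }
})

test_that("barycenter minimizes the sum of squared distances", {
  for (seed in 1:5) {
    tr <- random_tree(synthetic_spec(n_leaves = 2, seed = seed))  # 3 nodes
    X <- do.call(rbind, lapply(1:5, function(j)
      rand_profile(tr, 77 * seed + j)))
    bary <- l2_barycenter(X, tr)$profile
    ssd <- function(x) sum(apply(X, 1, function(r) l2_unifrac(r, x, tr)^2))
    target <- ssd(bary)
    set.seed(seed)
    for (cand in 1:200) {
      g <- rgamma(tr$n, 1); g <- g / sum(g)
      expect_gte(ssd(g), target - 1e-10)
    }
    for (j in seq_len(nrow(X))) expect_gte(ssd(X[j, ]), target - 1e-10)
  }
})

test_that("barycenter converges to the environment mean as n grows", {
  # law-of-large-numbers behavior: distance from the barycenter to the true
  # environment base decreases with sample size, in expectation
  sizes <- c(10, 100, 1000)
  errs <- matrix(0, 20, length(sizes))
  spec0 <- synthetic_spec(n_leaves = 16, n_environments = 1, alpha = 20,
                          sparsity = 1, seed = 42)
  tree <- random_tree(spec0)
  lv <- leaves_of(tree)
  base <- numeric(tree$n); base[lv] <- 1 / length(lv)
  for (r in 1:20) {
    for (s in seq_along(sizes)) {
      spec <- synthetic_spec(n_leaves = 16, n_environments = 1,
                             samples_per_environment = sizes[s], alpha = 20,
                             sparsity = 1, seed = 5000 + 31 * r + s)
      co <- sample_cohort(tree, spec)
      bary <- l2_barycenter(co)$profile
      errs[r, s] <- l2_unifrac(bary, base, tree)
    }
  }
  m <- colMeans(errs)
  expect_lt(m[2], m[1])
  expect_lt(m[3], m[2])
})

test_that("L1 median construction behaves as documented", {
  tr <- toy_t0()
  P <- c(0.2, 0.3, 0.5)
  demo <- l1_median_demo(rbind(P, P, P), tr)
  expect_equal(as.numeric(demo$vector), P)
  expect_identical(demo$n_negative, 0L)
  expect_error(l1_median_demo(rbind(P), tr), "two")

  # 2-profile cohort: the lower median equals the aggregated-space minimum;
  # cross-check against direct inverse of the component-wise lower median
  Q <- c(0.6, 0.1, 0.3)
  A <- rbind(as.numeric(aggregate_profile(P, tr, 1)),
             as.numeric(aggregate_profile(Q, tr, 1)))
  expected <- inverse_aggregate(pmin(A[1, ], A[2, ]), tr, 1)
  demo2 <- l1_median_demo(rbind(P, Q), tr)
  expect_equal(as.numeric(demo2$vector), as.numeric(expected))
})

test_that("barycenter_distance equals the pair metric and guards methods", {
  tr <- toy_t0()
  a <- l2_barycenter(rbind(c(1, 0, 0)), tr, environment = "a")
  b <- l2_barycenter(rbind(c(0, 1, 0)), tr, environment = "b")
  expect_equal(barycenter_distance(a, b, tr), sqrt(5))
  expect_equal(barycenter_distance(a, a, tr), 0)
  fake <- structure(list(profile = c(1, 0, 0), method = "l1_median"),
                    class = "uf_representative")
  expect_error(barycenter_distance(a, fake, tr), "l2_mean")
})

test_that("environments with disjoint support have positive separation", {
  fx <- small_cohort(n_leaves = 16, n_env = 2, per_env = 4, seed = 9,
                     sparsity = 0.25)
  reps <- environment_barycenters(fx$cohort)
  expect_gt(barycenter_distance(reps[[1]], reps[[2]], fx$tree), 0)
})
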