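#' Specification for synthetic trees and cohorts
#'
#' Bundles every knob of the generator into one validated object. Defaults
#' describe the stated test world: a 64-leaf random bifurcating tree with
#' exponential(mean 1) branch lengths, 4 environments of 50 samples each,
#' Dirichlet concentration 50 around sparse environment base profiles
#' each supported on a fifth of the leaves — distinct communities sharing
#' few taxa, as body-site cohorts do. Same spec + seed gives bit-identical
#' output; each generator component draws from its own derived RNG stream,
#' so adding a generator never perturbs existing fixtures.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param branch_mean mean of the exponential branch-length distribution.
#' @param n_environments number of environments (>= 1).
#' @param samples_per_environment samples drawn per environment (>= 1).
#' @param alpha Dirichlet concentration; larger = tighter environments.
#' @param sparsity fraction of leaves in each environment's support.
#' @param internal_mass_fraction fraction of each sample's mass moved onto
#'   internal nodes (0 = leaves-only profiles; > 0 exercises the
#'   taxonomic/shotgun pathway where abundance sits at every rank).
#' @param seed integer seed.
#' @return object of class `uf_spec`.
#' @export
synthetic_spec <- function(n_leaves = 64L, branch_mean = 1.0,
                           n_environments = 4L,
                           samples_per_environment = 50L,
                           alpha = 50, sparsity = 0.2,
                           internal_mass_fraction = 0, seed = 0L) {
  stopifnot(n_leaves >= 1, n_environments >= 1,
            samples_per_environment >= 1, alpha > 0, branch_mean > 0,
            sparsity > 0, sparsity <= 1,
            internal_mass_fraction >= 0, internal_mass_fraction < 1)
  structure(list(n_leaves = as.integer(n_leaves), branch_mean = branch_mean,
                 n_environments = as.integer(n_environments),
                 samples_per_environment = as.integer(samples_per_environment),
                 alpha = alpha, sparsity = sparsity,
                 internal_mass_fraction = internal_mass_fraction,
                 seed = as.integer(seed)),
            class = "uf_spec")
}

#' Random bifurcating rooted tree
#'
#' Sequential leaf attachment: starting from a two-leaf cherry at the root,
#' each new leaf splits a uniformly chosen edge with a fresh internal node,
#' giving `2 * n_leaves - 1` nodes. Branch lengths are i.i.d.
#' exponential(mean `branch_mean`) truncated below at `1e-6`. A single
#' leaf yields a 2-node tree (root plus leaf). Deterministic for a fixed
#' seed.
#'
#' @param spec a [synthetic_spec()] (fields `n_leaves`, `branch_mean`,
#'   `seed` used).
#' @return a `uf_tree` with leaf ids `L1..Ln` and internal ids `I1..`.
#' @export
random_tree <- function(spec = synthetic_spec()) {
  with_local_seed(mix_seed(spec$seed, 1L), random_tree_impl(spec))
}

random_tree_impl <- function(spec) {
  n <- spec$n_leaves
  rlen <- function(m) pmax(stats::rexp(m, rate = 1 / spec$branch_mean), 1e-6)
  if (n == 1L)
    return(uf_tree(c("L1", "root"), c(2L, NA), c(rlen(1), NA)))
  # parent/children maps over string ids; children kept in creation order
  parent <- list(L1 = "root", L2 = "root")
  kids <- list(root = c("L1", "L2"))
  edges <- c("L1", "L2")            # edges identified by their child node
  n_int <- 0L
  for (leaf in seq(3L, length.out = n - 2L)) {
    child <- edges[sample.int(length(edges), 1L)]
    n_int <- n_int + 1L
    mid <- paste0("I", n_int)
    newleaf <- paste0("L", leaf)
    pa <- parent[[child]]
    kids[[pa]][kids[[pa]] == child] <- mid   # keep position: determinism
    kids[[mid]] <- c(child, newleaf)
    parent[[child]] <- mid
    parent[[mid]] <- pa
    parent[[newleaf]] <- mid
    edges <- c(edges, mid, newleaf)
  }
  # iterative post-order over the children lists
  post <- character(0)
  stack <- list(list(id = "root", i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    ch <- kids[[top$id]]
    if (is.null(ch) || top$i >= length(ch)) {
      post <- c(post, top$id)
      stack[[length(stack)]] <- NULL
    } else {
      stack[[length(stack)]]$i <- top$i + 1L
      stack[[length(stack) + 1L]] <- list(id = ch[top$i + 1L], i = 0L)
    }
  }
  idx <- stats::setNames(seq_along(post), post)
  par_idx <- rep(NA_integer_, length(post))
  for (j in seq_along(post))
    if (post[j] != "root") par_idx[j] <- idx[[parent[[post[j]]]]]
  lens <- rep(NA_real_, length(post))
  lens[seq_len(length(post) - 1L)] <- rlen(length(post) - 1L)
  uf_tree(post, par_idx, lens)
}

#' Sample an environment-structured cohort on a tree
#'
#' For each environment, a support set of `round(sparsity * n_leaves)`
#' leaves is drawn and the base profile is uniform over it; each sample is
#' then drawn from `Dirichlet(alpha * base + 1e-3)` restricted to the
#' support. With `internal_mass_fraction > 0` that fraction of each
#' sample's mass is moved onto a few random internal nodes, emulating
#' taxonomic shotgun profiles that carry abundance at internal ranks.
#' Deterministic for a fixed seed; each environment has its own RNG stream.
#'
#' @param tree a `uf_tree`, typically from [random_tree()].
#' @param spec a [synthetic_spec()].
#' @return a labeled [uf_cohort()]; sample ids `env<e>_s<j>`, environment
#'   labels `env1..envE`.
#' @export
sample_cohort <- function(tree, spec = synthetic_spec()) {
  leaves <- setdiff(seq_len(tree$n), tree$parent[!is.na(tree$parent)])
  internals <- setdiff(seq_len(tree$n), c(leaves, root_index(tree)))
  nsupp <- max(1L, round(spec$sparsity * length(leaves)))
  env_blocks <- lapply(seq_len(spec$n_environments), function(e)
    with_local_seed(mix_seed(spec$seed, 1000L + e),
                    sample_environment(tree, spec, e, leaves, internals,
                                       nsupp)))
  X <- do.call(rbind, lapply(env_blocks, `[[`, "profiles"))
  labels <- do.call(c, lapply(env_blocks, `[[`, "labels"))
  uf_cohort(X, labels, tree)
}

sample_environment <- function(tree, spec, e, leaves, internals, nsupp) {
  env <- paste0("env", e)
  supp <- sort(sample(leaves, nsupp))
  conc <- spec$alpha * rep(1 / nsupp, nsupp) + 1e-3
  nper <- spec$samples_per_environment
  X <- matrix(0, nper, tree$n, dimnames = list(NULL, tree$ids))
  for (j in seq_len(nper)) {
    x <- numeric(tree$n)
    x[supp] <- rdirichlet1(conc)
    f <- spec$internal_mass_fraction
    if (f > 0 && length(internals)) {
      tgt <- sample(internals, min(3L, length(internals)))
      w <- rdirichlet1(rep(1, length(tgt)))
      x <- x * (1 - f)
      x[tgt] <- x[tgt] + f * w
    }
    X[j, ] <- x
  }
  rownames(X) <- paste0(env, "_s", seq_len(nper))
  list(profiles = X,
       labels = stats::setNames(rep(env, nper), rownames(X)))
}
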