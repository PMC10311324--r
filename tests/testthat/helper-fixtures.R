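# shared fixtures and independent oracles ----------------------------------

# the worked toy tree: leaves A (l = 1) and B (l = 4) under root R
toy_t0 <- function() {
  tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
  set_node_ranks(tr, c(A = "leaf", B = "leaf"))
}

leaves_of <- function(tree)
  setdiff(seq_len(tree$n), tree$parent[!is.na(tree$parent)])

# random tree with <= 64 nodes, via the package generator
rand_tree <- function(seed, max_leaves = 32L) {
  nl <- 2L + (seed %% (max_leaves - 1L))
  random_tree(synthetic_spec(n_leaves = nl, seed = seed))
}

# random profile over all nodes (or leaves only) via normalized gammas
rand_profile <- function(tree, seed, leaves_only = FALSE) {
  set.seed(seed)
  x <- numeric(tree$n)
  idx <- if (leaves_only) leaves_of(tree) else seq_len(tree$n)
  g <- rgamma(length(idx), shape = 1)
  x[idx] <- g / sum(g)
  x
}

# independent descendant sets: walk every node's ancestor chain
descendant_sets <- function(tree) {
  sets <- lapply(seq_len(tree$n), function(i) integer(0))
  for (i in seq_len(tree$n)) {
    j <- i
    repeat {
      sets[[j]] <- c(sets[[j]], i)
      if (is.na(tree$parent[j])) break
      j <- tree$parent[j]
    }
  }
  sets
}

# independent tree-path distance matrix between all nodes (LCA by ancestor
# sets; knows nothing about aggregation)
tree_path_dists <- function(tree) {
  anc <- lapply(seq_len(tree$n), function(i) {
    chain <- i
    while (!is.na(tree$parent[chain[length(chain)]]))
      chain <- c(chain, tree$parent[chain[length(chain)]])
    chain
  })
  depth_len <- numeric(tree$n)
  for (i in seq_len(tree$n)) {
    ch <- anc[[i]]
    depth_len[i] <- sum(tree$length[ch[-length(ch)]])
  }
  D <- matrix(0, tree$n, tree$n)
  for (i in seq_len(tree$n)) for (j in seq_len(tree$n)) {
    if (i == j) next
    lca <- intersect(anc[[i]], anc[[j]])[1L]
    D[i, j] <- depth_len[i] + depth_len[j] - 2 * depth_len[lca]
  }
  D
}

# batch minimum-cost-transport oracle: explicit LP via python/scipy (HiGHS)
transport_lp_oracle <- function(instances) {
  script <- system.file("oracle", "transport_lp.py", package = "l2unifrac")
  stopifnot(nzchar(script))
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(instances, function(z)
      list(cost = z$cost, p = z$p, q = z$q)),
    infile, digits = NA, matrix = "rowmajor")
  out <- system2("python", c(script, infile), stdout = TRUE)
  as.numeric(out)
}

# small default-like cohorts used across tests (scaled-down sizes)
small_cohort <- function(n_leaves = 16, n_env = 2, per_env = 5, alpha = 50,
                         seed = 0, ...) {
  spec <- synthetic_spec(n_leaves = n_leaves, n_environments = n_env,
                         samples_per_environment = per_env, alpha = alpha,
                         seed = seed, ...)
  tree <- random_tree(spec)
  list(tree = tree, cohort = sample_cohort(tree, spec), spec = spec)
}
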