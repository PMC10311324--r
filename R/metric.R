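#' Aggregate a profile up the tree (streaming transform)
#'
#' Single post-order pass implementing the matrix product of the (scaled)
#' subtree-indicator matrix with a profile, in O(N) time and space: each
#' non-root node adds its running subtree mass to its ancestor, then its own
#' entry is scaled by `l(i)^(1/p)` (sqrt of the branch length for p = 2, the
#' branch length itself for p = 1). The root entry is left unscaled and
#' equals the total mass (1 for a valid profile). The result is the
#' coordinate vector of the sample in Lp-UniFrac space.
#'
#' @param x numeric profile vector aligned to `tree` (post-order).
#' @param tree a `uf_tree`.
#' @param p 1 or 2.
#' @return named numeric vector (class `uf_aggregated`, attributes `p`).
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' aggregate_profile(c(1, 0, 0), tr)        # 1 0 1
#' aggregate_profile(c(0, 1, 0), tr)        # 0 2 1
#' @export
aggregate_profile <- function(x, tree, p = 2) {
  stopifnot(p %in% c(1, 2))
  if (length(x) != tree$n)
    stop("vector length ", length(x), " does not match tree with ",
         tree$n, " nodes")
  v <- as.numeric(x)
  s <- edge_scale(tree, p)
  par <- tree$parent
  for (i in seq_len(tree$n - 1L)) {
    v[par[i]] <- v[par[i]] + v[i]   # push mass up, then scale the edge entry
    v[i] <- v[i] * s[i]
  }
  bump_counter("aggregations")
  structure(stats::setNames(v, tree$ids), p = p, class = "uf_aggregated")
}

# matrix form: rows are samples; one post-order pass of column operations
aggregate_matrix <- function(X, tree, p = 2) {
  stopifnot(p %in% c(1, 2))
  s <- edge_scale(tree, p)
  par <- tree$parent
  A <- as.matrix(X)
  for (i in seq_len(tree$n - 1L)) {
    A[, par[i]] <- A[, par[i]] + A[, i]
    A[, i] <- A[, i] * s[i]
  }
  bump_counter("aggregations", nrow(A))
  A
}

#' Invert the aggregation transform exactly
#'
#' Exact algebraic inverse of [aggregate_profile()]: the forward pass is
#' undone in reverse post-order (each entry unscaled by `l(i)^(1/p)`, then
#' subtracted from its ancestor), so
#' `inverse_aggregate(aggregate_profile(P)) == P` to machine precision.
#' For arbitrary vectors that are not the image of a probability profile the
#' result may contain negative entries; it is returned unclamped, with the
#' count of entries below `-1e-12` attached as attribute `n_negative`.
#'
#' @param v aggregated vector (plain numeric or `uf_aggregated`).
#' @param tree a `uf_tree`.
#' @param p 1 or 2; must match the `p` used to aggregate when `v` carries one.
#' @return named numeric vector with attribute `n_negative`.
#' @export
inverse_aggregate <- function(v, tree, p = 2) {
  stopifnot(p %in% c(1, 2))
  if (!is.null(attr(v, "p")) && attr(v, "p") != p)
    stop("aggregated vector was built with p = ", attr(v, "p"),
         ", not p = ", p)
  if (length(v) != tree$n)
    stop("vector length ", length(v), " does not match tree with ",
         tree$n, " nodes")
  x <- as.numeric(v)
  s <- edge_scale(tree, p)
  par <- tree$parent
  for (i in rev(seq_len(tree$n - 1L))) {
    x[i] <- x[i] / s[i]
    x[par[i]] <- x[par[i]] - x[i]
  }
  structure(stats::setNames(x, tree$ids),
            n_negative = sum(x < -1e-12))
}

#' L2-UniFrac distance between two profiles
#'
#' Euclidean norm of the difference of the p = 2 aggregated vectors — the
#' phylogeny-aware distance under which component-wise means of samples are
#' valid probability profiles.
#'
#' @param P,Q profile vectors on the same tree.
#' @param tree a `uf_tree`.
#' @return non-negative scalar.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' l2_unifrac(c(1, 0, 0), c(0, 1, 0), tr)  # sqrt(5)
#' @export
l2_unifrac <- function(P, Q, tree) {
  d <- aggregate_profile(P, tree, 2) - aggregate_profile(Q, tree, 2)
  bump_counter("pair_norms")
  sqrt(sum(d * d))
}

#' Classical (L1) UniFrac distance between two profiles
#'
#' L1 norm of the difference of the p = 1 aggregated vectors; equals the
#' 1-Wasserstein (earth mover's) distance between the two distributions
#' under the tree-path metric.
#'
#' @inheritParams l2_unifrac
#' @return non-negative scalar.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' l1_unifrac(c(1, 0, 0), c(0, 1, 0), tr)  # 5
#' @export
l1_unifrac <- function(P, Q, tree) {
  d <- aggregate_profile(P, tree, 1) - aggregate_profile(Q, tree, 1)
  bump_counter("pair_norms")
  sum(abs(d))
}

#' Pairwise UniFrac distance matrix for a cohort
#'
#' Each sample is aggregated exactly once (a linear pass over samples), then
#' pairwise distances are plain Lp norms of differences of aggregated
#' vectors.
#'
#' @param cohort a [uf_cohort()] or a samples-by-nodes profile matrix.
#' @param tree a `uf_tree`; taken from the cohort when omitted.
#' @param metric `"l2"` (default) or `"l1"`.
#' @return symmetric matrix with zero diagonal (class `uf_dist`), attributes
#'   `metric`, `n_aggregations`, `n_pair_computations`.
#' @export
pairwise_unifrac <- function(cohort, tree = NULL, metric = c("l2", "l1")) {
  metric <- match.arg(metric)
  if (inherits(cohort, "uf_cohort")) {
    if (is.null(tree)) tree <- cohort$tree
    X <- cohort$profiles
  } else X <- as.matrix(cohort)
  if (is.null(tree)) stop("a tree is required")
  if (nrow(X) < 2) stop("need at least 2 samples")
  p <- if (metric == "l2") 2 else 1
  A <- aggregate_matrix(X, tree, p)
  D <- as.matrix(stats::dist(A, method = if (p == 2) "euclidean"
                                         else "manhattan"))
  npairs <- nrow(X) * (nrow(X) - 1) / 2
  bump_counter("pair_norms", npairs)
  structure(D, metric = metric, n_aggregations = nrow(X),
            n_pair_computations = npairs, class = c("uf_dist", "matrix"))
}

#' Write a distance matrix as TSV
#'
#' @param D matrix from [pairwise_unifrac()].
#' @param file output path.
#' @param format `"tsv"` (labeled square, default) or `"phylip"` (square
#'   Phylip with a leading count line).
#' @return `file`, invisibly.
#' @export
write_dist <- function(D, file, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  M <- unclass(D)
  attributes(M) <- attributes(M)[c("dim", "dimnames")]
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- base::file(file, "w"); on.exit(close(con))
    writeLines(sprintf("%d", nrow(M)), con)
    for (i in seq_len(nrow(M)))
      writeLines(paste(c(rownames(M)[i], sprintf("%.12g", M[i, ])),
                       collapse = "\t"), con)
  }
  invisible(file)
}

# ---- operation counters: a probe used to assert the complexity claim that
# clustering in aggregated space needs O(M) aggregations and no pairwise
# norms, versus O(M^2) pair computations for the distance-matrix route.
.uf_counters <- new.env(parent = emptyenv())

bump_counter <- function(what, by = 1) {
  cur <- get0(what, envir = .uf_counters, ifnotfound = 0)
  assign(what, cur + by, envir = .uf_counters)
  invisible(NULL)
}

#' Reset the internal operation counters
#' @return invisibly, the counters before the reset.
#' @export
reset_op_counters <- function() {
  old <- op_counters()
  rm(list = ls(envir = .uf_counters), envir = .uf_counters)
  invisible(old)
}

#' Read the internal operation counters
#' @return list with `aggregations` and `pair_norms`.
#' @export
op_counters <- function() {
  list(aggregations = get0("aggregations", envir = .uf_counters,
                           ifnotfound = 0),
       pair_norms = get0("pair_norms", envir = .uf_counters, ifnotfound = 0))
}
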