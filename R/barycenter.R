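#' L2-UniFrac barycenter (representative sample) of a set of profiles
#'
#' Computes the profile minimizing the sum of squared L2-UniFrac distances
#' to the inputs: aggregate every profile, take the component-wise mean in
#' the aggregated space, and map back with the exact inverse transform.
#' Because the aggregation is linear and invertible, this equals the plain
#' component-wise mean of the input profiles; the identity is re-checked at
#' run time (tolerance 1e-10) as an internal consistency guard. The result
#' is always a valid probability profile — the simplex is closed under
#' means.
#'
#' @param profiles samples-by-nodes matrix, list of profile vectors, or a
#'   [uf_cohort()] (all samples used).
#' @param tree a `uf_tree`; taken from the cohort when omitted.
#' @param environment optional environment label to record.
#' @return object of class `uf_representative`: list with `profile`,
#'   `environment`, `n_samples`, `method = "l2_mean"`.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' l2_barycenter(rbind(c(1, 0, 0), c(0, 1, 0)), tr)$profile  # 0.5 0.5 0
#' @export
l2_barycenter <- function(profiles, tree = NULL, environment = NA_character_) {
  X <- as_profile_matrix(profiles, tree)
  tree <- attr(X, "tree")
  if (nrow(X) < 1L) stop("empty collection: need at least one profile")
  A <- aggregate_matrix(X, tree, 2)
  bary <- inverse_aggregate(colMeans(A), tree, 2)
  direct <- colMeans(X)
  if (max(abs(bary - direct)) > 1e-10)
    stop("internal error: aggregated-space mean does not match the ",
         "component-wise profile mean")
  prof <- stats::setNames(pmax(as.numeric(bary), 0), tree$ids)
  prof <- prof / sum(prof)
  structure(list(profile = prof, environment = environment,
                 n_samples = nrow(X), method = "l2_mean"),
            class = "uf_representative")
}

#' L1 median construction (demonstration of simplex failure)
#'
#' Takes the component-wise median in the p = 1 aggregated space and maps it
#' back with the p = 1 inverse. Unlike the L2 barycenter, this vector is NOT
#' guaranteed to stay on the probability simplex: negative entries routinely
#' appear for heterogeneous cohorts. This operation exists to demonstrate
#' that phenomenon; the returned vector is unclamped and must not be used as
#' an average. For even cohort sizes the lower median is taken, so the
#' construction (and its negativity count) is deterministic.
#'
#' @inheritParams l2_barycenter
#' @return list with `vector` (unclamped, possibly negative), `n_negative`
#'   (count of entries below -1e-12), `method = "l1_median"`.
#' @export
l1_median_demo <- function(profiles, tree = NULL) {
  X <- as_profile_matrix(profiles, tree)
  tree <- attr(X, "tree")
  if (nrow(X) < 2L) stop("need at least two profiles")
  A <- aggregate_matrix(X, tree, 1)
  lower_median <- function(col) sort(col)[floor((length(col) + 1) / 2)]
  med <- apply(A, 2L, lower_median)
  v <- inverse_aggregate(med, tree, 1)
  list(vector = v, n_negative = attr(v, "n_negative"),
       method = "l1_median")
}

#' L2-UniFrac distance between two representative samples
#'
#' Distance between two environments summarized by their barycenters: a
#' single metric evaluation instead of all pairwise sample comparisons.
#'
#' @param a,b `uf_representative` objects with method `l2_mean`.
#' @param tree a `uf_tree`.
#' @return non-negative scalar.
#' @export
barycenter_distance <- function(a, b, tree) {
  for (r in list(a, b))
    if (!inherits(r, "uf_representative") || r$method != "l2_mean")
      stop("barycenter_distance requires l2_mean representatives")
  l2_unifrac(a$profile, b$profile, tree)
}

#' Representative sample per environment
#'
#' @param cohort a labeled [uf_cohort()].
#' @return named list of `uf_representative`, one per environment (sorted by
#'   environment name).
#' @export
environment_barycenters <- function(cohort) {
  if (is.null(cohort$labels)) stop("cohort has no environment labels")
  envs <- sort(unique(cohort$labels))
  out <- lapply(envs, function(e) {
    rows <- names(cohort$labels)[cohort$labels == e]
    l2_barycenter(cohort$profiles[rows, , drop = FALSE], cohort$tree,
                  environment = e)
  })
  stats::setNames(out, envs)
}

# normalize the accepted profile-collection shapes to an M x N matrix with a
# "tree" attribute
as_profile_matrix <- function(profiles, tree) {
  if (inherits(profiles, "uf_cohort")) {
    if (is.null(tree)) tree <- profiles$tree
    profiles <- profiles$profiles
  }
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, lapply(profiles, as.numeric))
  X <- as.matrix(profiles)
  if (is.null(tree)) stop("a tree is required")
  if (ncol(X) != tree$n)
    stop("profiles have ", ncol(X), " columns; tree has ", tree$n, " nodes")
  if (any(X < 0)) stop("profiles contain negative entries")
  sums <- rowSums(X)
  if (any(abs(sums - 1) > 1e-8))
    stop("profiles must sum to 1")
  colnames(X) <- tree$ids
  attr(X, "tree") <- tree
  X
}
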