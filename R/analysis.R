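#' k-means clustering directly in L2-UniFrac (aggregated) space
#'
#' Samples are aggregated once (one linear pass), then Lloyd's k-means with
#' k-means++ initialization runs under the Euclidean norm — which in this
#' space IS the L2-UniFrac distance. No pairwise distance matrix is ever
#' materialized. Deterministic for a fixed seed; `nstart` restarts are run
#' and the solution with the lowest within-cluster sum of squares kept.
#'
#' @param cohort a [uf_cohort()] or samples-by-nodes matrix.
#' @param tree a `uf_tree`; taken from the cohort when omitted.
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @return object of class `uf_clustering`: `assignment` (named integer),
#'   `centers`, `objective`, `iterations`, `method`, `k`, `seed`, and the
#'   complexity-probe counts `n_aggregations`, `n_pair_computations`.
#' @export
cluster_l2_space <- function(cohort, tree = NULL, k, seed = 0L,
                             nstart = 10L, max_iter = 300L) {
  if (inherits(cohort, "uf_cohort")) {
    if (is.null(tree)) tree <- cohort$tree
    X <- cohort$profiles
  } else X <- as.matrix(cohort)
  M <- nrow(X)
  if (k < 1 || k > M) stop("k must be between 1 and the number of samples")
  A <- aggregate_matrix(X, tree, 2)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- with_local_seed(mix_seed(seed, r), lloyd_kmeans(A, k, max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(
    assignment = stats::setNames(best$cluster, rownames(X)),
    centers = best$centers, objective = best$objective,
    iterations = best$iterations, objective_trace = best$trace,
    method = "kmeans_l2_space", k = k, seed = seed,
    n_aggregations = M, n_pair_computations = 0),
    class = "uf_clustering")
}

# Lloyd's algorithm with k-means++ seeding; an emptied cluster is re-seeded
# at the point farthest from its current center (deterministic)
lloyd_kmeans <- function(A, k, max_iter) {
  M <- nrow(A)
  centers <- A[kmeanspp_init(A, k), , drop = FALSE]
  cluster <- integer(M)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D2 <- point_center_dist2(A, centers)
    new_cluster <- max.col(-D2, ties.method = "first")
    obj <- sum(D2[cbind(seq_len(M), new_cluster)])
    trace <- c(trace, obj)
    if (it > 1L && all(new_cluster == cluster)) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      rows <- which(cluster == j)
      if (length(rows)) {
        centers[j, ] <- colMeans(A[rows, , drop = FALSE])
      } else {
        far <- which.max(D2[cbind(seq_len(M), cluster)])
        centers[j, ] <- A[far, ]
        cluster[far] <- j
      }
    }
  }
  list(cluster = cluster, centers = centers, objective = obj,
       iterations = it, trace = trace)
}

kmeanspp_init <- function(A, k) {
  M <- nrow(A)
  idx <- integer(k)
  idx[1L] <- sample.int(M, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(A, 2L, A[idx[1L], ])^2)
    for (j in 2L:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(M, 1L)
      else idx[j] <- sample.int(M, 1L, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(A, 2L, A[idx[j], ])^2))
    }
  }
  idx
}

point_center_dist2 <- function(A, centers) {
  cross <- A %*% t(centers)
  an <- rowSums(A^2); cn <- rowSums(centers^2)
  pmax(outer(an, cn, "+") - 2 * cross, 0)
}

#' k-medoids (PAM) clustering on a precomputed distance matrix
#'
#' The conventional route: build the full pairwise UniFrac matrix, then run
#' PAM (build + swap). PAM itself is deterministic given the matrix; `seed`
#' is accepted for interface symmetry. The edge case `k == n` (every sample
#' its own medoid) is handled directly.
#'
#' @param dmat symmetric non-negative matrix with zero diagonal, e.g. from
#'   [pairwise_unifrac()].
#' @param k number of clusters.
#' @param seed integer seed (unused by PAM; recorded).
#' @return `uf_clustering` with `method = "pam_dmat"` and `medoids`.
#' @export
cluster_dmat <- function(dmat, k, seed = 0L) {
  M <- as.matrix(unclass(dmat))
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-9)
    stop("distance matrix must be symmetric")
  if (any(M < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(M)) > 1e-12)) stop("distance matrix diagonal must be zero")
  n <- nrow(M)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  if (k == n) {
    assignment <- stats::setNames(seq_len(n), rownames(M))
    medoids <- rownames(M)
  } else {
    fit <- cluster::pam(stats::as.dist(M), k = k, diss = TRUE)
    assignment <- stats::setNames(as.integer(fit$clustering), rownames(M))
    medoids <- rownames(M)[fit$id.med]
  }
  structure(list(assignment = assignment, medoids = medoids,
                 method = "pam_dmat", k = k, seed = seed),
            class = "uf_clustering")
}

#' Fowlkes-Mallows score between a clustering and ground truth
#'
#' Pair-counting agreement: `TP / sqrt((TP + FP) * (TP + FN))` over sample
#' pairs, where TP counts pairs co-clustered in both partitions, FP pairs
#' co-clustered only in the prediction and FN only in the truth. 1 for
#' identical partitions; 0 when no pair agrees (or when either partition
#' has no co-clustered pair at all).
#'
#' @param assignment cluster labels (any atomic type), named or in the same
#'   order as `truth`.
#' @param truth reference labels.
#' @return scalar in \[0, 1\].
#' @export
fowlkes_mallows <- function(assignment, truth) {
  if (length(assignment) != length(truth))
    stop("assignment and truth have different lengths")
  if (!is.null(names(assignment)) && !is.null(names(truth))) {
    if (!setequal(names(assignment), names(truth)))
      stop("assignment and truth are over different sample sets")
    truth <- truth[names(assignment)]
  }
  ct <- table(assignment, truth)
  tp <- sum(choose(ct, 2))
  pred_pairs <- sum(choose(rowSums(ct), 2))   # TP + FP
  true_pairs <- sum(choose(colSums(ct), 2))   # TP + FN
  if (pred_pairs == 0 || true_pairs == 0) return(0)
  tp / sqrt(pred_pairs * true_pairs)
}

#' Stratified train/test split of a labeled cohort
#'
#' Within each environment, `floor(fraction * n)` samples (at least 1, at
#' most `n - 1`) are drawn for training; the rest are the test set.
#' Deterministic for a fixed seed.
#'
#' @param cohort a labeled [uf_cohort()].
#' @param fraction training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with `train` and `test`, both `uf_cohort`s.
#' @export
train_test_split <- function(cohort, fraction = 0.8, seed = 0L) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be strictly between 0 and 1")
  if (is.null(cohort$labels)) stop("cohort has no environment labels")
  envs <- sort(unique(cohort$labels))
  train_ids <- character(0)
  for (ei in seq_along(envs)) {
    ids <- names(cohort$labels)[cohort$labels == envs[ei]]
    if (length(ids) < 2)
      stop("environment '", envs[ei],
           "' has fewer than 2 samples; cannot stratify")
    ntr <- min(max(floor(fraction * length(ids)), 1L), length(ids) - 1L)
    picked <- with_local_seed(mix_seed(seed, 100 + ei),
                              sample(ids, ntr))
    train_ids <- c(train_ids, picked)
  }
  test_ids <- setdiff(names(cohort$labels), train_ids)
  subset_cohort <- function(ids) uf_cohort(
    cohort$profiles[ids, , drop = FALSE], cohort$labels[ids], cohort$tree)
  list(train = subset_cohort(train_ids), test = subset_cohort(test_ids))
}

#' Nearest-representative classification
#'
#' Builds one L2-UniFrac barycenter per training environment, then assigns
#' each test sample to the environment whose representative is nearest in
#' L2-UniFrac distance. Ties break to the alphabetically first environment.
#'
#' @param train a labeled [uf_cohort()] (every environment needs at least
#'   one sample).
#' @param test a `uf_cohort` or samples-by-nodes matrix of test profiles.
#' @param tree a `uf_tree`; taken from `train` when omitted.
#' @return object of class `uf_classification`: `predictions` (named
#'   character), `truth` (if test labels were available), `accuracy`,
#'   `per_class` contingency table, `representatives`.
#' @export
classify_nearest_representative <- function(train, test, tree = NULL) {
  if (is.null(tree)) tree <- train$tree
  reps <- environment_barycenters(train)   # sorted by env name
  if (inherits(test, "uf_cohort")) {
    Xt <- test$profiles; truth <- test$labels
  } else { Xt <- as.matrix(test); truth <- NULL }
  At <- aggregate_matrix(Xt, tree, 2)
  Ar <- aggregate_matrix(do.call(rbind, lapply(reps, `[[`, "profile")),
                         tree, 2)
  D <- sqrt(point_center_dist2(At, Ar))
  pred <- names(reps)[max.col(-D, ties.method = "first")]
  names(pred) <- rownames(Xt)
  acc <- NULL; per_class <- NULL
  if (!is.null(truth)) {
    truth <- truth[names(pred)]
    acc <- mean(pred == truth)
    per_class <- table(truth = truth, predicted = pred)
  }
  structure(list(predictions = pred, truth = truth, accuracy = acc,
                 per_class = per_class, representatives = reps,
                 distances = D),
            class = "uf_classification")
}

#' Majority-vote labeling of clusters (comparison harness)
#'
#' Assigns each cluster the most common training label among its members
#' (ties to the alphabetically first label). The known failure mode of this
#' unsupervised route — two clusters voting the same label, leaving some
#' environments unrepresented — is surfaced in the `missing_labels` field
#' rather than silently accepted.
#'
#' @param clustering a `uf_clustering`.
#' @param labels named character vector of true labels for the clustered
#'   samples.
#' @return list with `cluster_labels` (cluster index -> label),
#'   `predictions` (per sample), `missing_labels` (environments never won
#'   by any cluster).
#' @export
majority_vote_labels <- function(clustering, labels) {
  asg <- clustering$assignment
  labels <- labels[names(asg)]
  cl_lab <- vapply(sort(unique(asg)), function(j) {
    tab <- sort(table(labels[asg == j]), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  names(cl_lab) <- as.character(sort(unique(asg)))
  pred <- cl_lab[as.character(asg)]
  names(pred) <- names(asg)
  list(cluster_labels = cl_lab, predictions = pred,
       missing_labels = setdiff(unique(labels), cl_lab))
}
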