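#' Validate a relative-abundance profile vector
#'
#' A profile is a length-N non-negative vector over the tree's nodes (in
#' post-order), summing to 1. Mass on internal nodes is allowed: taxonomic
#' profiles from shotgun data place abundance at every rank.
#'
#' @param x numeric vector.
#' @param tree a `uf_tree`.
#' @param tol tolerance on the sum-to-one check.
#' @return the validated vector, named by node ids.
#' @export
as_profile <- function(x, tree, tol = 1e-8) {
  if (length(x) != tree$n)
    stop("profile length ", length(x), " does not match tree with ",
         tree$n, " nodes")
  if (any(x < 0)) stop("profile has negative entries")
  if (abs(sum(x) - 1) > tol)
    stop("profile does not sum to 1 (sum = ", format(sum(x)),
         "); pass renormalize = TRUE to rescale")
  stats::setNames(as.numeric(x), tree$ids)
}

#' Place named masses on tree nodes and normalize
#'
#' Mass is placed directly on the named node — internal or leaf — with no
#' redistribution to leaves, then the vector is normalized to sum to 1.
#'
#' @param masses named non-negative numeric vector; duplicate names
#'   accumulate.
#' @param tree a `uf_tree`.
#' @return a profile vector aligned to the tree's post-order.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' push_to_nodes(c(A = 1, R = 1), tr)  # 0.5 0 0.5
#' @export
push_to_nodes <- function(masses, tree) {
  if (is.null(names(masses)) || any(!nzchar(names(masses))))
    stop("masses must be a fully named vector")
  if (any(masses < 0)) stop("negative mass for node(s): ",
                            paste(names(masses)[masses < 0], collapse = ", "))
  unknown <- setdiff(names(masses), tree$ids)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  v <- stats::setNames(numeric(tree$n), tree$ids)
  for (k in seq_along(masses))
    v[names(masses)[k]] <- v[names(masses)[k]] + masses[k]
  if (sum(v) <= 0) stop("total mass is zero")
  v / sum(v)
}

#' A labeled cohort of profiles on one tree
#'
#' @param profiles numeric matrix, samples in rows aligned to the tree's
#'   post-order (columns named by node ids), or a list of profile vectors.
#' @param labels named character vector, sample id -> environment; or `NULL`.
#' @param tree a `uf_tree`.
#' @param tol sum-to-one tolerance.
#' @return object of class `uf_cohort`: list with `profiles` (M x N matrix),
#'   `labels`, `tree`.
#' @export
uf_cohort <- function(profiles, labels = NULL, tree, tol = 1e-8) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != tree$n)
    stop("profile matrix has ", ncol(profiles), " columns; tree has ",
         tree$n, " nodes")
  if (is.null(colnames(profiles))) colnames(profiles) <- tree$ids
  if (!identical(colnames(profiles), tree$ids))
    stop("profile columns are not aligned to the tree's post-order")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("s", seq_len(nrow(profiles)))
  if (any(profiles < 0)) stop("profiles contain negative entries")
  bad <- which(abs(rowSums(profiles) - 1) > tol)
  if (length(bad))
    stop("sample(s) do not sum to 1: ",
         paste(rownames(profiles)[bad], collapse = ", "))
  if (!is.null(labels)) {
    missing_lab <- setdiff(rownames(profiles), names(labels))
    if (length(missing_lab))
      stop("no label for sample(s): ", paste(missing_lab, collapse = ", "))
    labels <- labels[rownames(profiles)]
  }
  structure(list(profiles = profiles, labels = labels, tree = tree),
            class = "uf_cohort")
}

#' @export
print.uf_cohort <- function(x, ...) {
  cat("uf_cohort:", nrow(x$profiles), "samples x", ncol(x$profiles),
      "tree nodes\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("environments:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a sample-by-feature abundance table
#'
#' Reads a TSV whose rows are samples (first column `sample_id`) and whose
#' remaining columns are feature/node ids, aligns each row to the tree's
#' post-order (features absent from the table become 0), and optionally
#' renormalizes rows to sum to 1. Alignment is by id, never by position.
#'
#' @param file path to the TSV, or a data.frame.
#' @param tree a `uf_tree`.
#' @param renormalize divide each row by its sum (rows must be accepted
#'   within `1e-8` of 1 otherwise).
#' @param on_unknown `"error"` (default) lists feature ids not present in
#'   the tree; `"drop"` discards them with a warning.
#' @param labels optional path to a two-column TSV (sample_id, environment)
#'   or a named character vector.
#' @return a [uf_cohort()].
#' @export
read_profile_table <- function(file, tree, renormalize = FALSE,
                               on_unknown = c("error", "drop"),
                               labels = NULL) {
  on_unknown <- match.arg(on_unknown)
  df <- if (is.data.frame(file)) file
        else utils::read.delim(file, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (!ncol(df) >= 2) stop("profile table needs a sample_id column and at least one feature")
  ids <- as.character(df[[1L]])
  feat <- colnames(df)[-1L]
  unknown <- setdiff(feat, tree$ids)
  if (length(unknown)) {
    if (on_unknown == "error")
      stop("feature id(s) not in tree: ", paste(unknown, collapse = ", "))
    warning("dropping feature id(s) not in tree: ",
            paste(unknown, collapse = ", "))
    df <- df[, c(colnames(df)[1L], setdiff(feat, unknown)), drop = FALSE]
    feat <- colnames(df)[-1L]
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (any(vals < 0)) stop("negative abundance values in table")
  M <- matrix(0, nrow(vals), tree$n,
              dimnames = list(ids, tree$ids))
  M[, feat] <- vals
  rs <- rowSums(M)
  if (any(rs == 0))
    stop("all-zero sample(s): ", paste(ids[rs == 0], collapse = ", "))
  if (renormalize) M <- M / rs
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  uf_cohort(M, labels = labels, tree = tree)
}

#' Write a cohort or profile matrix as a TSV
#'
#' @param x a `uf_cohort` or a samples-by-nodes matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_profile_table <- function(x, file) {
  M <- if (inherits(x, "uf_cohort")) x$profiles else as.matrix(x)
  df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read sample labels from a two-column TSV
#'
#' @param file TSV with columns sample_id, environment (header optional but
#'   recommended).
#' @return named character vector.
#' @export
read_labels <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file needs two columns: sample_id, environment")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write sample labels as a two-column TSV
#' @param labels named character vector.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_labels <- function(labels, file) {
  utils::write.table(
    data.frame(sample_id = names(labels), environment = unname(labels)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
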