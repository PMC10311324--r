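#' Rooted trees with branch lengths in canonical post-order
#'
#' A `uf_tree` stores a rooted tree as parallel vectors indexed in a fixed
#' post-order (every child precedes its ancestor; the root is last). This is
#' the order in which mass is aggregated rootward, so profile vectors,
#' aggregated vectors and flow vectors are all indexed the same way.
#'
#' @param ids character vector of unique node identifiers, already in
#'   post-order (root last).
#' @param parent integer vector; `parent[i]` is the index of the ancestor of
#'   node `i`, `NA` for the root.
#' @param length numeric vector of branch lengths to the ancestor; `NA` for
#'   the root, strictly positive elsewhere.
#' @param rank optional character vector of rank annotations (e.g. "phylum"),
#'   `NA` where unannotated.
#' @return An object of class `uf_tree` with elements `ids`, `parent`,
#'   `length`, `rank` and `n`.
#' @export
uf_tree <- function(ids, parent, length, rank = NULL) {
  n <- base::length(ids)
  if (is.null(rank)) rank <- rep(NA_character_, n)
  tree <- structure(
    list(ids = as.character(ids), parent = as.integer(parent),
         length = as.numeric(length), rank = as.character(rank), n = n),
    class = "uf_tree"
  )
  validate_uf_tree(tree)
}

validate_uf_tree <- function(tree) {
  n <- tree$n
  if (anyDuplicated(tree$ids))
    stop("duplicate node ids: ",
         paste(unique(tree$ids[duplicated(tree$ids)]), collapse = ", "))
  root <- which(is.na(tree$parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root (one node without ancestor)")
  if (root != n)
    stop("root must be last in post-order")
  nonroot <- seq_len(n)[-n]
  if (n > 1L) {
    if (any(tree$parent[nonroot] <= nonroot, na.rm = TRUE))
      stop("not a post-order: some node does not precede its ancestor")
    bad <- nonroot[is.na(tree$length[nonroot]) | tree$length[nonroot] <= 0]
    if (length(bad))
      stop("non-positive or missing branch length at node(s): ",
           paste(tree$ids[bad], collapse = ", "))
  }
  # connectivity: every ancestor chain ends at the root
  for (i in nonroot) {
    j <- i; steps <- 0L
    while (!is.na(tree$parent[j])) {
      j <- tree$parent[j]; steps <- steps + 1L
      if (steps > n) stop("cycle detected in ancestor links")
    }
    if (j != root) stop("node ", tree$ids[i], " is not connected to the root")
  }
  tree
}

#' @export
print.uf_tree <- function(x, ...) {
  cat("uf_tree with", x$n, "nodes (root:", x$ids[x$n], ")\n")
  cat("leaves:", sum(!seq_len(x$n) %in% x$parent), "\n")
  invisible(x)
}

root_index <- function(tree) tree$n

#' Children lists of a tree
#'
#' @param tree a `uf_tree`.
#' @return list of integer vectors, one per node, children in post-order
#'   index order.
#' @keywords internal
children_of <- function(tree) {
  kids <- vector("list", tree$n)
  for (i in seq_len(tree$n - 1L)) {
    p <- tree$parent[i]
    kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

#' Node depths (root at depth 0)
#' @keywords internal
node_depths <- function(tree) {
  d <- integer(tree$n)
  for (i in rev(seq_len(tree$n - 1L))) d[i] <- d[tree$parent[i]] + 1L
  d
}

#' Edge-scaling factors l(i)^(1/p), 1 at the root
#' @keywords internal
edge_scale <- function(tree, p) {
  stopifnot(p %in% c(1, 2))
  s <- tree$length^(1 / p)
  s[root_index(tree)] <- 1
  s
}

# ape phylo -> uf_tree. Children are visited in cladewise (input) order so
# the post-order is deterministic for a given Newick string. Unnamed internal
# nodes receive synthetic ids "nodeK" where K is the post-order index.
phylo_to_uf_tree <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ntot <- ntip + nnode
  if (is.null(phy$edge.length))
    stop("Newick tree has no branch lengths")
  kids <- vector("list", ntot)
  elen <- rep(NA_real_, ntot)
  for (r in seq_len(nrow(phy$edge))) {
    a <- phy$edge[r, 1L]; b <- phy$edge[r, 2L]
    kids[[a]] <- c(kids[[a]], b)
    elen[b] <- phy$edge.length[r]
  }
  root <- ntip + 1L
  # collapse singleton root whose only child is internal ("root edge ignored")
  while (length(kids[[root]]) == 1L && kids[[root]][1L] > ntip) {
    root <- kids[[root]][1L]
    elen[root] <- NA_real_
  }
  # iterative post-order DFS, children in input order
  post <- integer(0)
  stack <- list(list(node = root, child = 0L))
  order_buf <- integer(ntot); k <- 0L
  visit <- function(node) {
    for (ch in kids[[node]]) visit(ch)
    k <<- k + 1L
    order_buf[k] <<- node
  }
  visit(root)
  post <- order_buf[seq_len(k)]
  idx <- integer(ntot); idx[post] <- seq_along(post)
  labs <- character(length(post))
  for (j in seq_along(post)) {
    v <- post[j]
    lab <- if (v <= ntip) phy$tip.label[v] else {
      nl <- phy$node.label
      if (!is.null(nl) && nzchar(nl[v - ntip])) nl[v - ntip] else ""
    }
    labs[j] <- if (nzchar(lab)) lab else paste0("node", j)
  }
  parent <- rep(NA_integer_, length(post))
  lens <- rep(NA_real_, length(post))
  for (j in seq_along(post)) {
    v <- post[j]
    if (v != root) {
      pa <- phy$edge[match(v, phy$edge[, 2L]), 1L]
      # parent in the collapsed tree: walk up past removed singletons
      parent[j] <- idx[pa]
      lens[j] <- elen[v]
    }
  }
  bad <- which(!is.na(lens) & (is.na(lens) | lens <= 0))
  if (length(bad))
    stop("non-positive branch length at node(s): ",
         paste(labs[bad], collapse = ", "))
  uf_tree(labs, parent, lens)
}

#' Read a rooted Newick tree
#'
#' Parses a Newick string (or file) into a [uf_tree()] with a deterministic
#' post-order: children are visited in the order they appear in the input,
#' and unnamed internal nodes are given synthetic ids by post-order index.
#' A singleton root whose only child is an internal node is collapsed (its
#' edge length discarded), so `"((A:1,B:4)R:0.0);"` yields the 3-node tree
#' rooted at `R`.
#'
#' @param file path to a Newick file, or `NULL` if `text` is given.
#' @param text a Newick string.
#' @return a `uf_tree`.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' tr$ids  # "A" "B" "R"
#' @export
read_newick <- function(file = NULL, text = NULL) {
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(file = file)
    else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("Newick parse error: no tree found in input")
  phylo_to_uf_tree(phy)
}

#' Write a tree as Newick
#'
#' Branch lengths are written with full double precision (`%.17g`) so that
#' read/write round-trips are exact.
#'
#' @param tree a `uf_tree`.
#' @param file output path, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  kids <- children_of(tree)
  fmt <- function(i) {
    lab <- tree$ids[i]
    br <- if (is.na(tree$length[i])) "" else sprintf(":%.17g", tree$length[i])
    if (length(kids[[i]]) == 0L) paste0(lab, br)
    else paste0("(", paste(vapply(kids[[i]], fmt, character(1)),
                           collapse = ","), ")", lab, br)
  }
  s <- paste0(fmt(root_index(tree)), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Build a taxonomic tree from lineage paths
#'
#' Constructs a tree from root-to-leaf lineage strings (e.g.
#' `"root;p__Firmicutes;g__Clostridium"`). Branch lengths follow the
#' reciprocal rule used for taxonomic trees in shotgun-metagenomics UniFrac:
#' a node at depth `d` (children of the root at `d = 1`) gets length `1/d`.
#' The rule is pluggable via `branch_length`.
#'
#' @param lineages character vector of delimited lineage paths, all sharing
#'   the same root token.
#' @param delim path delimiter, default `";"`.
#' @param branch_length function mapping depth (integer >= 1) to a positive
#'   branch length; default `function(d) 1 / d`.
#' @param ranks optional character vector naming the rank at each depth
#'   (`ranks[d]` for depth `d`); defaults to `"depth<d>"`. The root gets
#'   rank `"root"`.
#' @return a `uf_tree` with rank annotations.
#' @examples
#' tr <- tree_from_lineages(c("root;p1;g1", "root;p1;g2"))
#' tr$length[match(c("p1", "g1"), tr$ids)]  # 1, 0.5
#' @export
tree_from_lineages <- function(lineages, delim = ";",
                               branch_length = function(d) 1 / d,
                               ranks = NULL) {
  paths <- strsplit(lineages, delim, fixed = TRUE)
  paths <- lapply(paths, function(p) trimws(p[nzchar(trimws(p))]))
  if (!length(paths)) stop("no lineages given")
  rootid <- paths[[1L]][1L]
  if (any(vapply(paths, function(p) p[1L] != rootid, logical(1))))
    stop("lineages do not share a single root token")
  parent_of <- list()  # id -> parent id
  order_seen <- character(0)
  for (p in paths) {
    for (d in seq_along(p)[-1L]) {
      id <- p[d]; pa <- p[d - 1L]
      if (!is.null(parent_of[[id]])) {
        if (parent_of[[id]] != pa)
          stop("conflicting parentage for node '", id, "': both '",
               parent_of[[id]], "' and '", pa, "'")
      } else {
        parent_of[[id]] <- pa
        order_seen <- c(order_seen, id)
      }
    }
  }
  all_ids <- c(rootid, order_seen)
  # children lists in first-appearance order
  kids <- setNames(vector("list", length(all_ids)), all_ids)
  for (id in order_seen)
    kids[[parent_of[[id]]]] <- c(kids[[parent_of[[id]]]], id)
  depth <- setNames(integer(length(all_ids)), all_ids)
  for (id in order_seen) depth[id] <- depth[parent_of[[id]]] + 1L
  post <- character(0)
  visit <- function(id) {
    for (ch in kids[[id]]) visit(ch)
    post <<- c(post, id)
  }
  visit(rootid)
  idx <- setNames(seq_along(post), post)
  parent <- rep(NA_integer_, length(post))
  lens <- rep(NA_real_, length(post))
  rk <- rep(NA_character_, length(post))
  for (j in seq_along(post)) {
    id <- post[j]
    if (id != rootid) {
      parent[j] <- idx[[parent_of[[id]]]]
      lens[j] <- branch_length(depth[[id]])
      rk[j] <- if (!is.null(ranks) && depth[[id]] <= length(ranks))
        ranks[depth[[id]]] else paste0("depth", depth[[id]])
    } else rk[j] <- "root"
  }
  uf_tree(post, parent, lens, rank = rk)
}

#' Read a lineage table and build a taxonomic tree
#'
#' @param file TSV/text file with one lineage per row (first column used).
#' @inheritParams tree_from_lineages
#' @return a `uf_tree`.
#' @export
read_lineages <- function(file, delim = ";",
                          branch_length = function(d) 1 / d, ranks = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  first_col <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  tree_from_lineages(first_col, delim = delim,
                     branch_length = branch_length, ranks = ranks)
}

#' Attach rank annotations to tree nodes
#'
#' @param tree a `uf_tree`.
#' @param rank_map named character vector, node id -> rank.
#' @return the tree with updated ranks.
#' @export
set_node_ranks <- function(tree, rank_map) {
  unknown <- setdiff(names(rank_map), tree$ids)
  if (length(unknown))
    stop("unknown node id(s) in rank map: ", paste(unknown, collapse = ", "))
  tree$rank[match(names(rank_map), tree$ids)] <- unname(rank_map)
  tree
}

#' Explicit (scaled) subtree-indicator matrix
#'
#' Builds the N x N matrix whose row `j` is the 0/1 indicator of the subtree
#' rooted at `j`, scaled by `l(j)^(1/p)` for non-root `j`; the root row is
#' the unscaled all-ones indicator. For `p = 1` this is the classical
#' UniFrac matrix W; for `p = 2` the sqrt-scaled matrix used by L2-UniFrac.
#' This is the quadratic-cost brute-force oracle against which the
#' linear-time streaming aggregation is verified; it is not used on the hot
#' path.
#'
#' @param tree a `uf_tree`.
#' @param p 1 or 2.
#' @return an N x N numeric matrix with dimnames `tree$ids`.
#' @export
indicator_matrix <- function(tree, p = 2) {
  stopifnot(p %in% c(1, 2))
  n <- tree$n
  M <- matrix(0, n, n, dimnames = list(tree$ids, tree$ids))
  for (i in seq_len(n)) {
    j <- i
    repeat {                       # mark every ancestor-or-self row at col i
      M[j, i] <- 1
      if (is.na(tree$parent[j])) break
      j <- tree$parent[j]
    }
  }
  s <- edge_scale(tree, p)
  M * s
}
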