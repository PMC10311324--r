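#' Differential-abundance (flow) vector between two profiles
#'
#' The entrywise difference of the p = 2 aggregated vectors. Its entry at a
#' node is the signed, sqrt-branch-length-scaled difference in subtree mass
#' — the flux across the edge above that node when moving abundance from `P`
#' to overlap `Q`. Positive entries mean `P`'s subtree mass exceeds `Q`'s.
#' The Euclidean norm of the flow vector equals the L2-UniFrac distance by
#' construction, and the root entry is 0 for two valid profiles
#' (conservation of mass).
#'
#' @param P,Q profile vectors on `tree`.
#' @param tree a `uf_tree`.
#' @param source,target names recorded for the two sides (used in reports).
#' @return named numeric vector of class `uf_flow` with attributes `source`,
#'   `target`.
#' @examples
#' tr <- read_newick(text = "((A:1.0,B:4.0)R:0.0);")
#' differential_abundance(c(1, 0, 0), c(0, 1, 0), tr)  # 1 -2 0
#' @export
differential_abundance <- function(P, Q, tree, source = "P", target = "Q") {
  f <- as.numeric(aggregate_profile(P, tree, 2)) -
       as.numeric(aggregate_profile(Q, tree, 2))
  structure(stats::setNames(f, tree$ids), source = source, target = target,
            class = "uf_flow")
}

#' Top differentially abundant taxa at a rank
#'
#' Restricts a flow vector to nodes annotated with the given rank and
#' reports, for each, the UNSCALED subtree-mass difference (the flow entry
#' divided by sqrt of the branch length) — directly interpretable as the
#' difference in total subtree abundance between the two sides. Sorted by
#' absolute value, descending; ties broken by node id. `scaled = TRUE`
#' reports the raw flow entries instead (whose squares sum to the squared
#' metric).
#'
#' @param flow a `uf_flow` from [differential_abundance()].
#' @param tree a `uf_tree` with rank annotations (see [set_node_ranks()] or
#'   [tree_from_lineages()]).
#' @param rank rank name to restrict to.
#' @param k number of taxa to report; if larger than the number of rank
#'   nodes, the full list is returned.
#' @param scaled report sqrt-branch-length-scaled flow entries instead of
#'   subtree-abundance differences.
#' @return data.frame with columns `node`, `rank`, `difference`,
#'   `dominant` (the side with more subtree mass, `"none"` on exact ties).
#' @export
top_taxa_at_rank <- function(flow, tree, rank, k = 10L, scaled = FALSE) {
  stopifnot(k >= 1)
  sel <- which(!is.na(tree$rank) & tree$rank == rank)
  if (!length(sel))
    stop("rank '", rank, "' not present in tree annotations")
  s <- edge_scale(tree, 2)
  val <- if (scaled) as.numeric(flow)[sel] else as.numeric(flow)[sel] / s[sel]
  ids <- tree$ids[sel]
  ord <- order(-abs(val), ids)
  ord <- ord[seq_len(min(k, length(ord)))]
  src <- attr(flow, "source"); tgt <- attr(flow, "target")
  data.frame(
    node = ids[ord], rank = rank, difference = val[ord],
    dominant = ifelse(val[ord] > 0, src, ifelse(val[ord] < 0, tgt, "none")),
    stringsAsFactors = FALSE, row.names = NULL)
}
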