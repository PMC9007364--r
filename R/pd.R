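
# internal: per-tip root-path edge indices and edge lengths for a phylo
pd_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  # edge row whose child is node v
  edge_of_child <- integer(ntip + tree$Nnode)
  edge_of_child[edge[, 2L]] <- seq_len(nrow(edge))
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  root <- ntip + 1L
  tip_edges <- purrr::map(seq_len(ntip), function(v) {
    path <- integer()
    while (v != root) {
      path <- c(path, edge_of_child[v])
      v <- parent_of[v]
    }
    path
  })
  names(tip_edges) <- tree$tip.label
  list(edge_len = tree$edge.length, tip_edges = tip_edges, root = root)
}

#' Faith's phylogenetic diversity of a leaf set (rooted)
#'
#' The sum of branch lengths of all edges lying on the union of root-to-leaf
#' paths of the given leaves — the "active" branch length once those leaves
#' are selected. The empty set has PD 0.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param leaves Character vector of tip labels (subset of
#'   `tree$tip.label`).
#' @return Total active branch length, in the tree's units.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
#' pd_of(tr, c("A", "C")) # 1 + 3 + 4
pd_of <- function(tree, leaves) {
  idx <- pd_index(tree)
  pd_of_indexed(idx, leaves)
}

# internal fast path when the index is precomputed
pd_of_indexed <- function(idx, leaves) {
  if (length(leaves) == 0L) return(0)
  unknown <- setdiff(leaves, names(idx$tip_edges))
  if (length(unknown) > 0L) {
    stop_invalid(paste0("unknown leaf label(s): ", paste(unknown, collapse = ", ")))
  }
  active <- rep(FALSE, length(idx$edge_len))
  for (l in leaves) active[idx$tip_edges[[l]]] <- TRUE
  sum(idx$edge_len[active])
}
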