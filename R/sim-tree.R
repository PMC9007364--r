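
# internal: serialize a parent-pointer node table to newick.
# `parent` NA marks the root; `label` NA marks unlabeled internal nodes.
nodes_to_newick <- function(parent, length, label) {
  n <- length(parent)
  kids <- vector("list", n)
  root <- NA_integer_
  for (i in seq_len(n)) {
    p <- parent[i]
    if (is.na(p)) root <- i else kids[[p]] <- c(kids[[p]], i)
  }
  fmt_len <- function(l) formatC(l, format = "g", digits = 12)
  build <- function(i) {
    lab <- if (is.na(label[i])) "" else label[i]
    core <- if (length(kids[[i]]) == 0L) {
      lab
    } else {
      paste0("(", paste(vapply(kids[[i]], build, ""), collapse = ","), ")", lab)
    }
    if (is.na(parent[i])) core else paste0(core, ":", fmt_len(length[i]))
  }
  paste0(build(root), ";")
}

#' Simulate a rooted reference phylogeny
#'
#' Grows a random rooted binary topology by sequential leaf attachment (each
#' new leaf subdivides a uniformly chosen existing edge) and assigns i.i.d.
#' exponential branch lengths with mean `config$branch_length_mean`. This
#' stands in for the fixed reference genome tree a placement tool would use.
#'
#' @param config A [sim_config()].
#' @return An [ape::read.tree()] `phylo` object with `n_leaves` tips labeled
#'   `ref001, ref002, ...`, all branch lengths strictly positive.
#' @export
sim_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_leaves
  if (n < 2L) stop_invalid("`n_leaves` must be >= 2.")
  with_seed(derive_seed(config$seed, 1L), {
    # start from a cherry: root with two leaf children
    parent <- c(NA_integer_, 1L, 1L)
    is_leaf <- c(FALSE, TRUE, TRUE)
    for (i in seq_len(n - 2L)) {
      # pick a uniformly random non-root node: its incoming edge is split
      cand <- which(!is.na(parent))
      tgt <- cand[sample.int(length(cand), 1L)]
      new_internal <- length(parent) + 1L
      new_leaf <- length(parent) + 2L
      parent <- c(parent, parent[tgt], new_internal)
      parent[tgt] <- new_internal
      is_leaf <- c(is_leaf, FALSE, TRUE)
    }
    len <- rexp(length(parent), rate = 1 / config$branch_length_mean)
    len[is.na(parent)] <- NA_real_
    label <- rep(NA_character_, length(parent))
    label[is_leaf] <- sprintf("ref%03d", seq_len(sum(is_leaf)))
    tr <- ape::read.tree(text = nodes_to_newick(parent, len, label))
    tr
  })
}

#' Simulate phylogenetic placements of cells on a reference tree
#'
#' Emulates the single best placement a phylogenetic placement tool reports
#' per query: a uniformly chosen reference-tree edge, a uniform position along
#' it, and an exponential pendant branch length.
#'
#' @param tree A `phylo` reference tree.
#' @param cell_ids Character vector of query (cell) identifiers.
#' @param config A [sim_config()]; `branch_length_mean` sets the mean pendant
#'   length.
#' @return A tibble with columns `sag_id`, `edge_ref` (row index into
#'   `tree$edge`), `distal_position` in `[0, 1]` and `pendant_length`.
#' @export
sim_placements <- function(tree, cell_ids, config) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(cell_ids)
  with_seed(derive_seed(config$seed, 2L), {
    tibble(
      sag_id = as.character(cell_ids),
      edge_ref = sample.int(nrow(tree$edge), n, replace = TRUE),
      distal_position = runif(n),
      pendant_length = rexp(n, rate = 1 / config$branch_length_mean)
    )
  })
}
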