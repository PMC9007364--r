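
#' Graft placed genomes onto a reference tree as pendant edges
#'
#' Each placement splits its reference edge at `distal_position` (fraction of
#' the edge length measured from the rootward end) and attaches a pendant
#' edge of `pendant_length` carrying `sag_id`. Splitting conserves the base
#' branch length exactly, so the grafted tree's total length is the base
#' total plus the sum of pendant lengths. Multiple placements on one edge
#' partition it into segments.
#'
#' @param tree Rooted `phylo` reference tree.
#' @param placements Tibble with columns `sag_id`, `edge_ref` (row index
#'   into `tree$edge`), `pendant_length`, and optionally `distal_position`
#'   (default 0.5).
#' @return An object of class `sag_grafted`: list with `tree` (the grafted
#'   `phylo`), `base` (the input tree) and `placements`.
#' @export
graft_placements <- function(tree, placements) {
  stopifnot(inherits(tree, "phylo"))
  req <- c("sag_id", "edge_ref", "pendant_length")
  stopifnot(all(req %in% names(placements)))
  pl <- as_tibble(placements)
  if (!"distal_position" %in% names(pl)) pl$distal_position <- 0.5
  pl$distal_position[is.na(pl$distal_position)] <- 0.5
  if (anyDuplicated(pl$sag_id)) stop_invalid("duplicate sag_id in placements")
  if (any(pl$sag_id %in% tree$tip.label)) {
    stop_invalid("sag_id collides with an existing tip label")
  }
  if (any(pl$edge_ref < 1 | pl$edge_ref > nrow(tree$edge))) {
    stop_invalid("invalid edge_ref")
  }
  check_fraction(pl$distal_position, "distal_position")
  if (any(pl$pendant_length < 0)) stop_invalid("pendant_length must be >= 0")

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n0 <- ntip + nnode
  parent <- rep(NA_integer_, n0)
  len <- rep(NA_real_, n0)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  len[tree$edge[, 2L]] <- tree$edge.length
  label <- rep(NA_character_, n0)
  label[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    lab[!nzchar(lab)] <- NA_character_
    label[ntip + seq_len(nnode)] <- lab
  }

  nxt <- n0
  for (e in unique(pl$edge_ref)) {
    rows <- pl[pl$edge_ref == e, ]
    rows <- rows[order(rows$distal_position, rows$sag_id), ]
    p <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    L <- tree$edge.length[e]
    prev <- p
    prev_pos <- 0
    for (r in seq_len(nrow(rows))) {
      attach_node <- nxt + 1L
      tip_node <- nxt + 2L
      nxt <- nxt + 2L
      parent[attach_node] <- prev
      len[attach_node] <- (rows$distal_position[r] - prev_pos) * L
      label[attach_node] <- NA_character_
      parent[tip_node] <- attach_node
      len[tip_node] <- rows$pendant_length[r]
      label[tip_node] <- rows$sag_id[r]
      prev <- attach_node
      prev_pos <- rows$distal_position[r]
    }
    parent[child] <- prev
    len[child] <- (1 - prev_pos) * L
  }
  grafted <- ape::read.tree(text = nodes_to_newick(parent, len, label))
  structure(list(tree = grafted, base = tree, placements = pl),
            class = "sag_grafted")
}

#' @export
print.sag_grafted <- function(x, ...) {
  cat(sprintf("<sag_grafted> %d placements on a %d-tip base tree\n",
              nrow(x$placements), length(x$base$tip.label)))
  invisible(x)
}

#' Per-clade phylogenetic gain after grafting
#'
#' For every internal node of the base tree, reports the clade's base branch
#' length (edges strictly inside the subtree; the stem edge is excluded),
#' the branch length added by pendant placements inside the clade, the number
#' of genomes placed below the node, and the phylogenetic gain — the
#' percentage increase in the clade's total branch length:
#' `gain_percent = 100 * added_length / base_length`.
#'
#' @param grafted A `sag_grafted` from [graft_placements()].
#' @return Tibble, one row per internal node of the base tree (root
#'   included): `node_id`, `label`, `n_placed_below`, `base_length`,
#'   `added_length`, `gain_percent`.
#' @export
gain_table <- function(grafted) {
  stopifnot(inherits(grafted, "sag_grafted"))
  tree <- grafted$base
  pl <- grafted$placements
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  elen <- rep(0, n)
  elen[tree$edge[, 2L]] <- tree$edge.length

  # pendant length and count land on the parent node of the placed edge:
  # the whole edge, wherever the split falls, lies inside that node's clade
  pend <- rep(0, n)
  cnt <- rep(0L, n)
  for (r in seq_len(nrow(pl))) {
    p <- tree$edge[pl$edge_ref[r], 1L]
    pend[p] <- pend[p] + pl$pendant_length[r]
    cnt[p] <- cnt[p] + 1L
  }

  base_len <- rep(0, n)
  added <- pend
  n_below <- cnt
  # postorder accumulation over the edge matrix
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    p <- eo[i, 1L]
    c <- eo[i, 2L]
    base_len[p] <- base_len[p] + elen[c] + base_len[c]
    added[p] <- added[p] + added[c]
    n_below[p] <- n_below[p] + n_below[c]
  }
  nodes <- ntip + seq_len(tree$Nnode)
  labels <- if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode) else tree$node.label
  tibble(
    node_id = nodes,
    label = labels,
    n_placed_below = n_below[nodes],
    base_length = base_len[nodes],
    added_length = added[nodes],
    gain_percent = ifelse(base_len[nodes] > 0,
                          100 * added[nodes] / base_len[nodes], NA_real_)
  ) |> arrange(.data$node_id)
}

#' Flag genomes as novel species by average nucleotide identity
#'
#' A genome is novel when it has no reference hit with ANI strictly above
#' `threshold` (default 0.97, the conventional same-species cutoff);
#' genomes absent from the table are novel by definition.
#'
#' @param ani_table Tibble with columns `sag_id`, `reference_id`, `identity`
#'   (fractions in `[0, 1]`).
#' @param threshold Identity cutoff; a hit must exceed it strictly for the
#'   genome to count as known.
#' @param sag_ids Optional character vector defining the full genome set
#'   (genomes without any table row are reported novel).
#' @return Tibble: `sag_id`, `best_identity` (`NA` if no hit),
#'   `best_reference`, `novel`.
#' @export
ani_novelty <- function(ani_table, threshold = 0.97, sag_ids = NULL) {
  stopifnot(all(c("sag_id", "reference_id", "identity") %in% names(ani_table)))
  check_fraction(ani_table$identity, "identity")
  hits <- ani_table |>
    group_by(.data$sag_id) |>
    summarise(
      best_identity = max(.data$identity),
      best_reference = .data$reference_id[which.max(.data$identity)],
      .groups = "drop"
    )
  ids <- if (is.null(sag_ids)) hits$sag_id else as.character(sag_ids)
  tibble(sag_id = ids) |>
    left_join(hits, by = "sag_id") |>
    mutate(novel = is.na(.data$best_identity) | .data$best_identity <= threshold)
}
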