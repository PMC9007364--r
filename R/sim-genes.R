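
# internal: random nucleotide sequence(s)
random_seqs <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# internal: substitute exactly k positions, each to a different base
mutate_to_identity <- function(seq, identity) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- as.integer(round((1 - identity) * length(s)))
  if (k > 0L) {
    pos <- sample.int(length(s), k)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(BASES, b), 1L), "")
  }
  list(sequence = paste(s, collapse = ""),
       realized = 1 - k / length(s))
}

#' Simulate a gene catalog and query genes with controlled identity
#'
#' Builds a reference gene catalog of random sequences, then query genes of
#' two kinds: catalog genes mutated by point substitutions to an exact target
#' nucleotide identity (one batch per value of `config$identity_targets`),
#' and fresh random sequences unrelated to the catalog (true novels).
#'
#' @param config A [sim_config()].
#' @param n_per_target Queries generated per identity target.
#' @param n_fresh Fresh random (truly novel) query genes.
#' @param gene_lengths Pool of gene lengths (bp) sampled per gene.
#' @return A list with
#'   \describe{
#'     \item{catalog}{tibble: `gene_id`, `sequence`.}
#'     \item{queries}{tibble: `gene_id`, `sequence`.}
#'     \item{truth}{tibble: `gene_id`, `parent_id` (`NA` for fresh novels),
#'       `true_identity` (`NA` for fresh novels).}
#'   }
#' @export
sim_gene_sets <- function(config, n_per_target = 20L, n_fresh = 20L,
                          gene_lengths = seq(300L, 1200L, by = 3L)) {
  stopifnot(inherits(config, "sim_config"))
  targets <- config$identity_targets
  if (any(targets <= 0.5 | targets > 1)) {
    stop_invalid("`identity_targets` must lie in (0.5, 1].")
  }
  with_seed(derive_seed(config$seed, 6L), {
    cat_ids <- sprintf("cat%04d", seq_len(config$catalog_size))
    catalog <- tibble(
      gene_id = cat_ids,
      sequence = random_seqs(sample(gene_lengths, config$catalog_size, replace = TRUE))
    )
    rows <- list()
    q <- 0L
    for (tg in targets) {
      for (j in seq_len(n_per_target)) {
        q <- q + 1L
        parent <- sample.int(nrow(catalog), 1L)
        m <- mutate_to_identity(catalog$sequence[parent], tg)
        rows[[q]] <- tibble(
          gene_id = sprintf("qry%04d", q), sequence = m$sequence,
          parent_id = catalog$gene_id[parent], true_identity = m$realized
        )
      }
    }
    for (j in seq_len(n_fresh)) {
      q <- q + 1L
      rows[[q]] <- tibble(
        gene_id = sprintf("qry%04d", q),
        sequence = random_seqs(sample(gene_lengths, 1L)),
        parent_id = NA_character_, true_identity = NA_real_
      )
    }
    all <- bind_rows(rows)
    list(
      catalog = catalog,
      queries = all[, c("gene_id", "sequence")],
      truth = all[, c("gene_id", "parent_id", "true_identity")]
    )
  })
}

#' Simulate functional category annotations for genes
#'
#' Assigns each gene 1-3 COG-style single-letter category labels uniformly at
#' random, for exercising the annotation-enrichment layer.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param categories Pool of category codes.
#' @param seed Integer seed.
#' @return Long tibble: `gene_id`, `category`.
#' @export
sim_annotations <- function(gene_ids,
                            categories = LETTERS[1:15],
                            seed = 1L) {
  with_seed(derive_seed(seed, 7L), {
    bind_rows(purrr::map(gene_ids, function(g) {
      k <- sample(1:3, 1L)
      tibble(gene_id = g, category = sample(categories, k))
    }))
  })
}
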