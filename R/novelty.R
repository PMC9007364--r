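
# internal: blastn-like scoring for nucleotide global alignment
nt_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}

#' Percent nucleotide identity between two sequences
#'
#' Needleman-Wunsch alignment of the shorter sequence (globally) against the
#' longer (locally clipped at the ends), with identity counted over the
#' shorter sequence — the CD-HIT convention for its `-c` cutoff. With
#' `both_strands = TRUE` the reverse complement of `a` is also tried and the
#' better identity returned.
#'
#' @param a,b Nucleotide sequences (character scalars).
#' @param both_strands Also try the reverse complement of `a` (default
#'   `TRUE`).
#' @return Identity as a fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, both_strands = TRUE) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) > nchar(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  pat <- Biostrings::DNAString(a)
  sub <- Biostrings::DNAString(b)
  one <- function(p) {
    al <- Biostrings::pairwiseAlignment(
      p, sub, type = "global-local", substitutionMatrix = nt_submat(),
      gapOpening = 5, gapExtension = 2
    )
    Biostrings::pid(al, type = "PID3") / 100
  }
  id <- one(pat)
  if (both_strands) id <- max(id, one(Biostrings::reverseComplement(pat)))
  id
}

# internal: the set of k-mers of a sequence (forward strand)
kmer_set <- function(seq, k = 8L) {
  L <- nchar(seq)
  if (L < k) return(character())
  unique(substring(seq, seq_len(L - k + 1L), k:L))
}

# internal: inverted k-mer index over reference sequences
kmer_index <- function(seqs, k = 8L) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (w in kmer_set(seqs[i], k)) {
      idx[[w]] <- c(idx[[w]], i)
    }
  }
  idx
}

# internal: reference ids sharing enough k-mers with the query on either
# strand. A single chance 8-mer hit is near-certain between unrelated genes,
# so candidates must share at least `min_frac` of the query's distinct
# k-mers on one strand (true matches at >= 85% identity share far more).
kmer_candidates <- function(seq, idx, k = 8L, both_strands = TRUE,
                            min_frac = 0.05) {
  count_hits <- function(words) {
    hits <- unlist(purrr::map(words, function(w) idx[[w]]), use.names = FALSE)
    if (length(hits) == 0L) return(integer())
    table(hits)
  }
  fwd <- kmer_set(seq, k)
  need <- max(1L, ceiling(min_frac * length(fwd)))
  counts <- count_hits(fwd)
  best <- setNames(as.integer(counts), names(counts))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rcc <- count_hits(kmer_set(rc, k))
    for (nm in names(rcc)) {
      best[nm] <- max(best[nm], rcc[[nm]], na.rm = TRUE)
    }
  }
  sort(as.integer(names(best)[!is.na(best) & best >= need]))
}

#' Label query genes as novel versus a reference gene catalog
#'
#' For each query, the best percent nucleotide identity against catalog
#' sequences passing a shared-k-mer prefilter (word size `word_size`, both
#' strands) is computed with [seq_identity()]; the gene is **novel** when it
#' has no match strictly above `threshold` (default 0.95, so a gene at
#' exactly 95% identity is still novel).
#'
#' @param queries Tibble: `gene_id`, `sequence`.
#' @param catalog Tibble: `gene_id`, `sequence`.
#' @param threshold Identity that a match must exceed for the query to count
#'   as known (default 0.95).
#' @param word_size Prefilter k-mer size (default 8).
#' @return Tibble: `gene_id`, `best_match_id` (`NA` if no candidate),
#'   `best_identity` (`NA` if no candidate), `novel`.
#' @export
label_novelty <- function(queries, catalog, threshold = 0.95, word_size = 8L) {
  stopifnot(all(c("gene_id", "sequence") %in% names(queries)),
            all(c("gene_id", "sequence") %in% names(catalog)))
  check_fraction(threshold, "threshold")
  idx <- kmer_index(catalog$sequence, k = word_size)
  rows <- purrr::map(seq_len(nrow(queries)), function(i) {
    cand <- kmer_candidates(queries$sequence[i], idx, k = word_size)
    if (length(cand) == 0L) {
      return(tibble(gene_id = queries$gene_id[i],
                    best_match_id = NA_character_,
                    best_identity = NA_real_, novel = TRUE))
    }
    ids <- vapply(cand, function(j) {
      seq_identity(queries$sequence[i], catalog$sequence[j])
    }, numeric(1))
    best <- which.max(ids)
    tibble(
      gene_id = queries$gene_id[i],
      best_match_id = catalog$gene_id[cand[best]],
      best_identity = ids[best],
      novel = ids[best] <= threshold
    )
  })
  bind_rows(rows)
}

#' Greedy sequence clustering at an identity cutoff
#'
#' CD-HIT-style dereplication: sequences are sorted by length (longest
#' first, ties by identifier), each sequence joins the first existing
#' cluster whose representative it matches at `identity` or better on either
#' strand, otherwise it founds a new cluster of which it is the
#' representative.
#'
#' @param genes Tibble: `gene_id`, `sequence`.
#' @param identity Clustering identity cutoff (default 0.95).
#' @param word_size Prefilter k-mer size (default 8).
#' @return Tibble: `gene_id`, `cluster`, `representative`,
#'   `is_representative`, in the processing order.
#' @export
dereplicate_genes <- function(genes, identity = 0.95, word_size = 8L) {
  stopifnot(all(c("gene_id", "sequence") %in% names(genes)))
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), cluster = integer(),
                  representative = character(), is_representative = logical()))
  }
  g <- genes[order(-nchar(genes$sequence), genes$gene_id), ]
  reps <- integer() # row indices (into g) of representatives
  idx <- new.env(hash = TRUE, parent = emptyenv())
  cluster <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    cand <- kmer_candidates(g$sequence[i], idx, k = word_size)
    assigned <- NA_integer_
    for (ci in cand) { # candidate cluster numbers in founding order
      if (seq_identity(g$sequence[i], g$sequence[reps[ci]]) >= identity) {
        assigned <- ci
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, i)
      assigned <- length(reps)
      for (w in kmer_set(g$sequence[i], word_size)) {
        idx[[w]] <- unique(c(idx[[w]], assigned))
      }
    }
    cluster[i] <- assigned
  }
  tibble(
    gene_id = g$gene_id,
    cluster = cluster,
    representative = g$gene_id[reps[cluster]],
    is_representative = seq_len(nrow(g)) %in% reps
  )
}

#' Catalog-overlap (Venn) counts for one query set against several catalogs
#'
#' @param label_sets Named list of [label_novelty()] outputs, all for the
#'   same query set.
#' @return List of two tibbles: `per_catalog` (`catalog`, `n_known`,
#'   `n_novel`, `frac_known`, `frac_novel`) and `patterns` (one row per
#'   known/novel profile across catalogs with its count).
#' @export
overlap_counts <- function(label_sets) {
  stopifnot(is.list(label_sets), length(label_sets) >= 1L,
            !is.null(names(label_sets)))
  ids <- purrr::map(label_sets, function(l) sort(l$gene_id))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1L]]))) {
    stop_invalid("all label sets must cover the same query genes")
  }
  known <- purrr::map(label_sets, function(l) {
    setNames(!l$novel, l$gene_id)[ids[[1L]]]
  })
  per_catalog <- bind_rows(purrr::imap(known, function(k, nm) {
    tibble(catalog = nm, n_known = sum(k), n_novel = sum(!k),
           frac_known = mean(k), frac_novel = mean(!k))
  }))
  prof <- do.call(cbind, known)
  pat <- apply(prof, 1L, function(r) {
    paste(ifelse(r, "known", "novel"), collapse = "/")
  })
  patterns <- as_tibble(as.data.frame(table(pattern = pat),
                                      stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq")
  list(per_catalog = per_catalog, patterns = patterns)
}

#' Annotation-category enrichment of novel genes by permutation
#'
#' Tests, per functional category, whether novel genes are over- or
#' under-represented. The null distribution is built by permuting the
#' novelty labels across genes (preserving the total novel count and every
#' gene's category multiset); the two-sided p-value is the permutation rank
#' of the observed novel count around the null mean, with the add-one
#' correction. Benjamini-Hochberg q-values are computed across categories.
#'
#' @param labels Tibble with `gene_id` and `novel` (logical).
#' @param annotations Long tibble: `gene_id`, `category`.
#' @param n_permutations Number of label permutations (>= 1000).
#' @param seed Integer seed for the permutation stream.
#' @param categories Optional category universe; categories with no
#'   annotated gene are dropped with a warning.
#' @return Tibble: `category`, `n_genes`, `observed_novel`,
#'   `expected_novel`, `p_value`, `q_value`, `direction`.
#' @export
enrichment_test <- function(labels, annotations, n_permutations = 2000L,
                            seed = 1L, categories = NULL) {
  stopifnot(all(c("gene_id", "novel") %in% names(labels)),
            all(c("gene_id", "category") %in% names(annotations)))
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  if (n_permutations < 1000L) {
    stop_invalid("`n_permutations` must be >= 1000 for stable p-values")
  }
  ann <- annotations[annotations$gene_id %in% labels$gene_id, ]
  present <- sort(unique(ann$category))
  if (is.null(categories)) {
    categories <- present
  } else {
    missing <- setdiff(categories, present)
    if (length(missing) > 0L) {
      warn(paste0("categories with no annotated gene dropped: ",
                  paste(missing, collapse = ", ")))
    }
    categories <- intersect(categories, present)
  }
  genes <- labels$gene_id
  flag <- as.numeric(labels$novel)
  inc <- matrix(0, nrow = length(categories), ncol = length(genes),
                dimnames = list(categories, genes))
  inc[cbind(match(ann$category, categories), match(ann$gene_id, genes))] <- 1
  obs <- as.numeric(inc %*% flag)
  null <- with_seed(derive_seed(seed, 8L), {
    P <- vapply(seq_len(n_permutations), function(i) sample(flag),
                numeric(length(flag)))
    inc %*% P
  })
  mu <- unname(rowMeans(null))
  p <- vapply(seq_along(categories), function(i) {
    dev <- abs(obs[i] - mu[i])
    (1 + sum(abs(null[i, ] - mu[i]) >= dev - 1e-12)) / (n_permutations + 1)
  }, numeric(1))
  tibble(
    category = categories,
    n_genes = as.integer(rowSums(inc)),
    observed_novel = obs,
    expected_novel = mu,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    direction = ifelse(obs >= mu, "enriched", "depleted")
  )
}
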