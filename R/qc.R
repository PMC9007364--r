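
#' Trim contig ends and drop short contigs
#'
#' Each contig loses `end_trim` bp from both ends; only contigs whose trimmed
#' length is strictly greater than `min_len` are retained (so a 2,200 bp
#' contig trimmed by 100 bp each end, at exactly 2,000 bp, is dropped).
#' Input order is preserved.
#'
#' @param seqs Character vector of contig sequences.
#' @param end_trim Bases removed from each end (default 100).
#' @param min_len Strict minimum post-trim length in bp (default 2000).
#' @return Character vector of surviving trimmed contigs.
#' @export
trim_contigs <- function(seqs, end_trim = 100L, min_len = 2000L) {
  if (end_trim < 0 || min_len < 0) stop_invalid("`end_trim` and `min_len` must be >= 0.")
  lens <- nchar(seqs)
  new_len <- lens - 2L * end_trim
  keep <- new_len > min_len
  substr(seqs[keep], end_trim + 1L, lens[keep] - end_trim)
}

#' Remove low-complexity sequences
#'
#' Retains only sequences in which every one of A, C, G and T occurs at a
#' frequency of at least `min_each_base_fraction` (default 5%); sequences
#' containing less than that of any nucleotide are removed.
#'
#' @param seqs Character vector of sequences.
#' @param min_each_base_fraction Minimum per-base frequency (default 0.05).
#' @return Character vector of retained sequences.
#' @export
filter_low_complexity <- function(seqs, min_each_base_fraction = 0.05) {
  if (length(seqs) == 0L) return(character())
  freq <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs), as.prob = TRUE
  )[, BASES, drop = FALSE]
  seqs[apply(freq >= min_each_base_fraction, 1L, all)]
}

#' Per-assembly quality metrics
#'
#' Computes, for each assembly, the standard single-cell assembly QC panel:
#' number of contigs, total assembled length, longest contig, GC fraction
#' (computed over A/C/G/T positions only; N excluded from numerator and
#' denominator) and whether the assembly passes the minimum-total-length
#' filter (`total_length >= min_assembly_len`; assemblies below the cutoff
#' are excluded downstream).
#'
#' @param contigs Tibble with columns `assembly_id` and `sequence` (one row
#'   per contig), e.g. from [sim_assemblies()].
#' @param min_assembly_len Minimum retained total length in bp (default
#'   20000).
#' @return Tibble, one row per assembly: `assembly_id`, `n_contigs`,
#'   `total_length`, `longest_contig`, `gc_fraction`, `pass_length_filter`.
#' @export
qc_metrics <- function(contigs, min_assembly_len = 20000L) {
  stopifnot(all(c("assembly_id", "sequence") %in% names(contigs)))
  if (nrow(contigs) == 0L) stop_invalid("no contigs supplied")
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(contigs$sequence))
  tibble(
    assembly_id = contigs$assembly_id,
    len = nchar(contigs$sequence),
    gc = freq[, "C"] + freq[, "G"],
    acgt = rowSums(freq[, BASES, drop = FALSE])
  ) |>
    group_by(.data$assembly_id) |>
    summarise(
      n_contigs = dplyr::n(),
      total_length = sum(.data$len),
      longest_contig = max(.data$len),
      gc_fraction = sum(.data$gc) / sum(.data$acgt),
      .groups = "drop"
    ) |>
    mutate(pass_length_filter = .data$total_length >= min_assembly_len)
}

#' Tetranucleotide frequency profiles of assembly windows
#'
#' Splits each contig into non-overlapping windows of `window` bp (a final
#' partial window is kept when it is at least `min_tail` bp; a contig shorter
#' than one window contributes its single window) and returns one
#' 256-entry tetramer frequency vector per window. Tetramers containing N are
#' not counted; each row is normalized to sum to 1. Windows with no valid
#' tetramer are dropped.
#'
#' @param seqs Character vector of contig sequences.
#' @param window Window size in bp (default 5000).
#' @param min_tail Minimum length of a kept partial window (default 1600).
#' @return Numeric matrix (windows x 256 tetramers).
#' @export
tetramer_profile <- function(seqs, window = 5000L, min_tail = 1600L) {
  pieces <- unlist(purrr::map(seqs, function(s) {
    L <- nchar(s)
    starts <- seq(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    wlen <- ends - starts + 1L
    # a contig shorter than one window still contributes its single window
    keep <- wlen == window | wlen >= min_tail |
      (length(starts) == 1L & wlen >= 4L)
    if (!any(keep)) return(character())
    substring(s, starts[keep], ends[keep])
  }))
  if (length(pieces) == 0L) return(matrix(numeric(), ncol = 256L))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(pieces), width = 4L
  )
  tot <- rowSums(counts)
  counts <- counts[tot > 0, , drop = FALSE]
  counts / rowSums(counts)
}

# internal: deterministic 2-means on a small score matrix.
# Initial centers are the two points at maximal Euclidean distance.
two_means <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  centers <- x[c(ij[1L], ij[2L]), , drop = FALSE]
  cl <- rep(1L, n)
  for (iter in 1:50) {
    d1 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- rowSums((x - matrix(centers[2L, ], n, ncol(x), byrow = TRUE))^2)
    new_cl <- ifelse(d2 < d1, 2L, 1L)
    if (all(new_cl == cl) && iter > 1L) break
    cl <- new_cl
    if (length(unique(cl)) < 2L) break
    centers <- rbind(colMeans(x[cl == 1L, , drop = FALSE]),
                     colMeans(x[cl == 2L, , drop = FALSE]))
  }
  cl
}

#' Screen an assembly for multi-cell contamination by tetramer PCA
#'
#' Projects the assembly's window tetramer profiles onto the first
#' `k_components` principal components and measures how strongly the scores
#' split into two groups: windows are partitioned by deterministic 2-means
#' and the score is the ratio of between-cluster to within-cluster sum of
#' squares. Assemblies mixing DNA from two organisms produce two composition
#' modes and a high score; the assembly is flagged when
#' `score > score_threshold`.
#'
#' With fewer than 3 windows the screen is inconclusive: the flag is `FALSE`,
#' the score `NaN`, and a warning is issued.
#'
#' @param seqs Character vector of contig sequences (one assembly).
#' @param window,min_tail Windowing as in [tetramer_profile()].
#' @param k_components Number of principal components used (default 2).
#' @param score_threshold Flagging threshold on the dispersion ratio; the
#'   default was calibrated on simulated pure and two-genome assemblies (see
#'   the package vignette).
#' @return A one-row tibble: `contamination_flag`, `contamination_score`,
#'   `n_windows`.
#' @export
contamination_screen <- function(seqs, window = 5000L, min_tail = 1600L,
                                 k_components = 2L, score_threshold = 5) {
  m <- tetramer_profile(seqs, window = window, min_tail = min_tail)
  n <- nrow(m)
  if (n < 3L) {
    warn("fewer than 3 tetramer windows: contamination screen inconclusive")
    return(tibble(contamination_flag = FALSE, contamination_score = NaN,
                  n_windows = n))
  }
  tot_var <- sum(scale(m, scale = FALSE)^2)
  if (tot_var < 1e-12) {
    return(tibble(contamination_flag = FALSE, contamination_score = 0,
                  n_windows = n))
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(k_components, ncol(pc$x))
  x <- pc$x[, seq_len(k), drop = FALSE]
  cl <- two_means(x)
  if (length(unique(cl)) < 2L) {
    score <- 0
  } else {
    tss <- sum(scale(x, scale = FALSE)^2)
    wss <- sum(unlist(purrr::map(split(seq_len(n), cl), function(idx) {
      sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
    })))
    score <- if (wss < 1e-12) Inf else (tss - wss) / wss
  }
  tibble(contamination_flag = score > score_threshold,
         contamination_score = score, n_windows = n)
}

#' Full QC table for a set of assemblies
#'
#' Combines [qc_metrics()] with the per-assembly [contamination_screen()].
#'
#' @inheritParams qc_metrics
#' @inheritParams contamination_screen
#' @return Tibble, one row per assembly, with all QC metric and screen
#'   columns plus `pass_qc` (length filter passed and not flagged).
#' @export
qc_table <- function(contigs, min_assembly_len = 20000L, window = 5000L,
                     score_threshold = 5) {
  metrics <- qc_metrics(contigs, min_assembly_len = min_assembly_len)
  screens <- contigs |>
    group_by(.data$assembly_id) |>
    summarise(
      screen = list(contamination_screen(.data$sequence, window = window,
                                         score_threshold = score_threshold)),
      .groups = "drop"
    ) |>
    tidyr::unnest("screen")
  left_join(metrics, screens, by = "assembly_id") |>
    mutate(pass_qc = .data$pass_length_filter & !.data$contamination_flag)
}

#' Tukey five-number summary
#'
#' Minimum, 25% quantile, median, 75% quantile and maximum, with quantiles by
#' linear interpolation of order statistics.
#'
#' @param values Nonempty numeric vector.
#' @return One-row tibble: `min`, `q25`, `median`, `q75`, `max`.
#' @export
five_number <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    stop_invalid("`values` must be a nonempty numeric vector.")
  }
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, type = 7)
  tibble(min = q[[1]], q25 = q[[2]], median = q[[3]], q75 = q[[4]], max = q[[5]])
}
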