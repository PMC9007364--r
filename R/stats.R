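
#' Two-sided unpaired Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 16 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Nonempty numeric vectors.
#' @return One-row tibble: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `paired` (= FALSE), `n_x`, `n_y`, `exact`.
#' @export
wilcoxon_unpaired <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop_invalid("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         paired = FALSE, n_x = length(x), n_y = length(y), exact = exact)
}

#' Two-sided paired Wilcoxon test (signed-rank on per-pair differences)
#'
#' Pairs are aligned by `pair_ids`, not by position. Zero differences are
#' dropped (Wilcoxon's original rule) or kept with Pratt's rank adjustment
#' via `zero_method = "pratt"` (then the normal approximation is always
#' used). The exact sign-enumeration null is used when there are at most 15
#' nonzero differences and no tied absolute differences; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y Matched numeric vectors.
#' @param x_ids,y_ids Pair identifiers for `x` and `y`; `y` is realigned so
#'   that ids match (`y_ids` defaults to `x_ids`, i.e. positional pairing).
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @return One-row tibble: `statistic` (signed-rank V), `p_value`,
#'   `paired` (= TRUE), `n_x`, `n_y`, `n_effective`, `exact`.
#' @export
wilcoxon_paired <- function(x, y, x_ids = NULL, y_ids = x_ids,
                            zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop_invalid("paired samples must have equal length")
  if (!is.null(x_ids)) {
    if (length(x_ids) != length(x) || length(y_ids) != length(y)) {
      stop_invalid("pair id length mismatch")
    }
    if (anyDuplicated(x_ids) || !setequal(x_ids, y_ids)) {
      stop_invalid("pair ids must be unique and match across groups")
    }
    y <- y[match(x_ids, y_ids)]
  }
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(tibble(statistic = 0, p_value = 1, paired = TRUE,
                  n_x = length(x), n_y = length(y), n_effective = 0L,
                  exact = FALSE))
  }
  if (zero_method == "drop") {
    ties <- anyDuplicated(abs(nz)) > 0L
    exact <- length(nz) <= 15L && !ties
    wt <- suppressWarnings(
      wilcox.test(nz, alternative = "two.sided", exact = exact, correct = TRUE)
    )
    v <- unname(wt$statistic)
    p <- wt$p.value
  } else {
    # Pratt: rank |d| including zeros, then discard zero ranks
    exact <- FALSE
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    nzr <- r[d != 0]
    mu <- sum(nzr) / 2
    sig2 <- sum(nzr^2) / 4
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble(statistic = v, p_value = p, paired = TRUE,
         n_x = length(x), n_y = length(y), n_effective = length(nz),
         exact = exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, monotone and capped at 1, in the input order.
#' @export
bh_adjust <- function(p_values) {
  check_fraction(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Species prevalence from per-sample k-mer hash assignments
#'
#' Counts, per sample, the species assigned strictly more than `min_hashes`
#' k-mer hashes (so a species at exactly `min_hashes` does not count) — a
#' proxy for species prevalence in classifier output.
#'
#' @param assignments Tibble: `sample_id`, `species`, `hashes` (counts
#'   >= 0).
#' @param min_hashes Strict threshold (default 5).
#' @param sample_ids Optional sample universe (samples without any row get
#'   prevalence 0).
#' @return Tibble: `sample_id`, `prevalence`.
#' @export
prevalence_counts <- function(assignments, min_hashes = 5L, sample_ids = NULL) {
  stopifnot(all(c("sample_id", "species", "hashes") %in% names(assignments)))
  if (any(assignments$hashes < 0)) stop_invalid("hash counts must be >= 0")
  counts <- assignments |>
    group_by(.data$sample_id) |>
    summarise(prevalence = sum(.data$hashes > min_hashes), .groups = "drop")
  ids <- if (is.null(sample_ids)) counts$sample_id else as.character(sample_ids)
  tibble(sample_id = ids) |>
    left_join(counts, by = "sample_id") |>
    mutate(prevalence = tidyr::replace_na(.data$prevalence, 0L))
}

#' All pairwise condition comparisons of a metric table
#'
#' Runs a two-sided Wilcoxon test for every metric and every pair of
#' conditions in a long metric table, paired (by `sample_id`) or unpaired,
#' and BH-adjusts the p-values across all comparisons.
#'
#' @param table Long tibble: `sample_id`, `condition`, `metric_name`,
#'   `value` (one value per sample x condition x metric).
#' @param paired Use the paired test (conditions must share sample ids).
#' @param alpha Significance threshold applied to adjusted p-values for the
#'   `significant` column (default 0.1).
#' @return Tibble, one row per (metric, condition pair): test columns plus
#'   `p_adjusted` and `significant`.
#' @export
compare_conditions <- function(table, paired = FALSE, alpha = 0.1) {
  req <- c("sample_id", "condition", "metric_name", "value")
  stopifnot(all(req %in% names(table)))
  if (anyDuplicated(table[, c("sample_id", "condition", "metric_name")])) {
    stop_invalid("one value per (sample, condition, metric) is required")
  }
  out <- list()
  for (m in sort(unique(table$metric_name))) {
    sub <- table[table$metric_name == m, ]
    conds <- sort(unique(sub$condition))
    if (length(conds) < 2L) next
    for (pair in utils::combn(conds, 2L, simplify = FALSE)) {
      a <- sub[sub$condition == pair[1L], ]
      b <- sub[sub$condition == pair[2L], ]
      res <- if (paired) {
        common <- intersect(a$sample_id, b$sample_id)
        if (length(common) != nrow(a) || length(common) != nrow(b)) {
          stop_invalid("paired comparison requires matched sample ids")
        }
        wilcoxon_paired(a$value[match(common, a$sample_id)],
                        b$value[match(common, b$sample_id)],
                        x_ids = common)
      } else {
        wilcoxon_unpaired(a$value, b$value)
      }
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble(metric_name = m, condition_a = pair[1L], condition_b = pair[2L]),
        res
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) > 0L) {
    res$p_adjusted <- bh_adjust(res$p_value)
    res$significant <- res$p_adjusted < alpha
  }
  res
}
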