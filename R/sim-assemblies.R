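
#' Simulate genome composition models
#'
#' Each source genome gets an independent random 3rd-order Markov model of
#' nucleotide composition (a 64 x 4 transition matrix with Dirichlet rows),
#' which guarantees a distinct tetranucleotide signature per genome without
#' hand-tuning.
#'
#' @param n Number of source genomes.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration of each transition row;
#'   smaller values give sharper, more mutually distinct compositions.
#' @return A list of `n` row-stochastic 64 x 4 matrices.
#' @export
sim_genome_models <- function(n, seed = 1L, concentration = 1) {
  with_seed(derive_seed(seed, 4L), {
    purrr::map(seq_len(n), function(i) {
      g <- matrix(rgamma(64L * 4L, shape = concentration), nrow = 64L)
      m <- g / rowSums(g)
      colnames(m) <- BASES
      m
    })
  })
}

# internal: generate many order-3 Markov sequences at once.
# lengths[i] bp from models[[source_idx[i]]]; vectorized across sequences.
markov_sequences <- function(lengths, source_idx, models) {
  n <- length(lengths)
  stopifnot(length(source_idx) == n)
  if (n == 0L) return(character())
  max_len <- max(lengths)
  # stacked cumulative transition probabilities: row (src-1)*64 + state
  cum <- do.call(rbind, purrr::map(models, function(m) t(apply(m, 1L, cumsum))))
  out <- matrix(0L, nrow = max_len, ncol = n)
  # first three bases uniform, then the chain takes over
  out[1:3, ] <- sample.int(4L, 3L * n, replace = TRUE)
  state <- (out[1L, ] - 1L) * 16L + (out[2L, ] - 1L) * 4L + out[3L, ]
  offset <- (source_idx - 1L) * 64L
  for (t in 4:max_len) {
    act <- which(lengths >= t)
    if (length(act) == 0L) break
    rows <- offset[act] + state[act]
    u <- runif(length(act))
    b <- 1L + (u > cum[rows, 1L]) + (u > cum[rows, 2L]) + (u > cum[rows, 3L])
    out[t, act] <- b
    state[act] <- ((state[act] - 1L) %% 16L) * 4L + b
  }
  vapply(seq_len(n), function(i) {
    paste(BASES[out[seq_len(lengths[i]), i]], collapse = "")
  }, character(1))
}

#' Simulate single-cell genome assemblies with optional contamination
#'
#' Every assembly draws its contigs from one source genome's composition
#' model; a `contamination_fraction` of assemblies instead mix contigs from
#' two distinct genomes at a 50:50 (+/- 10%) length share, emulating a
#' two-cell co-sort (doublet) — the canonical contamination mode of
#' fluorescence-activated single-cell sorting.
#'
#' @param config A [sim_config()].
#' @param models Optional list of composition models from
#'   [sim_genome_models()]; defaults to `config$n_genomes` fresh models.
#' @return A list with
#'   \describe{
#'     \item{contigs}{tibble: `assembly_id`, `contig_id`, `sequence`.}
#'     \item{truth}{tibble: `assembly_id`, `contaminated`, `source_1`,
#'       `source_2` (`NA` for pure assemblies).}
#'     \item{models}{the composition models used.}
#'   }
#' @export
sim_assemblies <- function(config, models = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 8000) stop_invalid("`genome_length` must be >= 8000 bp.")
  check_fraction(config$contamination_fraction, "contamination_fraction")
  if (is.null(models)) {
    models <- sim_genome_models(config$n_genomes, seed = config$seed)
  }
  n <- config$n_cells
  with_seed(derive_seed(config$seed, 5L), {
    ids <- sprintf("cell%03d", seq_len(n))
    contaminated <- runif(n) < config$contamination_fraction
    src1 <- sample.int(length(models), n, replace = TRUE)
    src2 <- vapply(src1, function(s) {
      if (length(models) < 2L) return(NA_integer_)
      sample(setdiff(seq_along(models), s), 1L)
    }, integer(1))
    src2[!contaminated] <- NA_integer_

    plan <- purrr::map(seq_len(n), function(i) {
      k <- sample(4:8, 1L)
      props <- runif(k, 0.5, 1.5)
      lens <- pmax(500L, as.integer(round(config$genome_length * props / sum(props))))
      src <- rep(src1[i], k)
      if (contaminated[i]) {
        target <- runif(1, 0.4, 0.6) # contaminant length share
        ord <- sample.int(k)
        cum <- cumsum(lens[ord]) / sum(lens)
        src[ord[cum <= target + 1e-9]] <- src2[i]
        if (all(src == src1[i])) src[ord[1L]] <- src2[i]
      }
      tibble(
        assembly_id = ids[i],
        contig_id = sprintf("%s_c%02d", ids[i], seq_len(k)),
        length = lens, source = src
      )
    })
    plan <- bind_rows(plan)
    plan$sequence <- markov_sequences(plan$length, plan$source, models)
    list(
      contigs = plan[, c("assembly_id", "contig_id", "sequence")],
      truth = tibble(
        assembly_id = ids, contaminated = contaminated,
        source_1 = src1, source_2 = src2
      ),
      models = models
    )
  })
}

#' @importFrom stats rgamma
NULL
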