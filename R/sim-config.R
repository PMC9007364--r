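#' Configuration for the synthetic single-cell genomics study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' the simulated study conditions used throughout the package's tests and
#' vignette: a 100-leaf reference tree, 200 sorted cells, 5% fluorescence
#' noise, a 10% amplification failure rate, 40 kb genomes and a 10% doublet
#' (two-cell co-sort) rate.
#'
#' @param seed Integer seed; the same config always yields byte-identical
#'   outputs.
#' @param n_leaves Number of leaves of the simulated reference tree (>= 2).
#' @param branch_length_mean Mean of the i.i.d. exponential branch lengths
#'   (substitutions/site).
#' @param n_cells Number of sorted cells (one amplification curve and one
#'   assembly each).
#' @param curve_noise_sd Gaussian noise SD added to amplification curves, in
#'   fluorescence units (curve amplitudes are ~1).
#' @param failure_rate Fraction of cells whose amplification fails (flat
#'   curve), in `[0, 1]`.
#' @param genome_length Total assembled length per cell, bp (>= 8000).
#' @param contamination_fraction Fraction of assemblies that mix contigs from
#'   two source genomes, in `[0, 1]`.
#' @param n_genomes Number of distinct source genomes (order-3 Markov
#'   compositions) cells are drawn from.
#' @param catalog_size Number of genes in the simulated reference catalog.
#' @param identity_targets Fractions in (0.5, 1]: each target spawns query
#'   genes mutated to exactly that nucleotide identity versus their catalog
#'   parent.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_leaves = 10, n_cells = 5)
#' tr <- sim_tree(cfg)
sim_config <- function(seed = 1L,
                       n_leaves = 100L,
                       branch_length_mean = 0.1,
                       n_cells = 200L,
                       curve_noise_sd = 0.05,
                       failure_rate = 0.1,
                       genome_length = 40000L,
                       contamination_fraction = 0.1,
                       n_genomes = 5L,
                       catalog_size = 150L,
                       identity_targets = c(0.85, 0.90, 0.96, 0.97, 1.0)) {
  n_leaves <- check_count(n_leaves, "n_leaves", min = 2L)
  n_cells <- check_count(n_cells, "n_cells", min = 0L)
  n_genomes <- check_count(n_genomes, "n_genomes", min = 1L)
  catalog_size <- check_count(catalog_size, "catalog_size", min = 1L)
  check_fraction(failure_rate, "failure_rate")
  check_fraction(contamination_fraction, "contamination_fraction")
  if (branch_length_mean <= 0) stop_invalid("`branch_length_mean` must be > 0.")
  if (curve_noise_sd < 0) stop_invalid("`curve_noise_sd` must be >= 0.")
  if (genome_length < 8000) stop_invalid("`genome_length` must be >= 8000 bp.")
  if (any(identity_targets <= 0.5 | identity_targets > 1)) {
    stop_invalid("`identity_targets` must lie in (0.5, 1].")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_leaves = n_leaves,
      branch_length_mean = branch_length_mean,
      n_cells = n_cells,
      curve_noise_sd = curve_noise_sd,
      failure_rate = failure_rate,
      genome_length = as.integer(genome_length),
      contamination_fraction = contamination_fraction,
      n_genomes = n_genomes,
      catalog_size = catalog_size,
      identity_targets = identity_targets
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
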