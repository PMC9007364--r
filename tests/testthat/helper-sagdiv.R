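# shared fixtures, built in code

star3 <- function() ape::read.tree(text = "(leaf1:1,leaf2:2,leaf3:3);")
caterpillar <- function() ape::read.tree(text = "((A:1,B:2):3,C:4);")

# random small selection instance: tree + random costs/budget/cap
random_instance <- function(seed, n_leaves = NULL, uniform_costs = FALSE) {
  cfg <- sim_config(seed = seed,
                    n_leaves = if (is.null(n_leaves)) 4L + (seed %% 7L) else n_leaves)
  tr <- sim_tree(cfg)
  withr::with_seed(seed + 10000L, {
    n <- length(tr$tip.label)
    costs <- if (uniform_costs) rep(1, n) else runif(n, 0.5, 10)
    names(costs) <- tr$tip.label
    list(
      tree = tr,
      problem = selection_problem(
        tr, costs,
        budget = if (uniform_costs) sample(1:n, 1L) else runif(1, 2, 0.8 * sum(costs)),
        cap = sample(1:n, 1L)
      )
    )
  })
}

# a noiseless 4-parameter logistic on a grid
logistic_curve <- function(times, f0 = 0.1, a = 1, r = 0.2, tinf = 30) {
  f0 + a / (1 + exp(-r * (times - tinf)))
}

# exact identity pair: seq2 differs from seq1 at exactly n_sub positions
make_identity_pair <- function(len, n_sub, seed = 1) {
  withr::with_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    t <- s
    pos <- sample.int(len, n_sub)
    t[pos] <- vapply(t[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    list(a = paste(s, collapse = ""), b = paste(t, collapse = ""))
  })
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small, fast pipeline configuration used by pipeline tests
small_run_config <- function(seed, outdir) {
  run_config(
    seed = seed, outdir = outdir,
    sim = sim_config(seed = seed, n_leaves = 15L, n_cells = 10L,
                     genome_length = 30000L, catalog_size = 20L,
                     identity_targets = c(0.90, 0.97)),
    cap = 5L, n_permutations = 1000L
  )
}
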