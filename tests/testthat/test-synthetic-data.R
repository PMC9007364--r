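test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(n_leaves = 1), class = "sagdiv_invalid_input")
  expect_error(sim_config(failure_rate = 1.2), class = "sagdiv_invalid_input")
  expect_error(sim_config(contamination_fraction = -0.1), class = "sagdiv_invalid_input")
  expect_error(sim_config(genome_length = 4000), class = "sagdiv_invalid_input")
  expect_error(sim_config(identity_targets = c(0.4)), class = "sagdiv_invalid_input")
})

test_that("simulated trees are rooted, binary, positive, and deterministic", {
  cfg <- sim_config(seed = 1, n_leaves = 10)
  t1 <- sim_tree(cfg)
  t2 <- sim_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.binary(t1))
  expect_true(all(t1$edge.length > 0))
  expect_length(t1$tip.label, 10L)

  tiny <- sim_tree(sim_config(seed = 2, n_leaves = 2))
  expect_length(tiny$tip.label, 2L)
  expect_identical(nrow(tiny$edge), 2L)
})

test_that("tree newick serialization round-trips branch lengths", {
  tr <- sim_tree(sim_config(seed = 7, n_leaves = 30))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-10)
})

test_that("total branch length matches the exponential-length expectation", {
  # law of large numbers over replicate trees: E[total] = (2n - 2) * mean
  n <- 50L
  mean_len <- 0.1
  totals <- vapply(1:200, function(s) {
    sum(sim_tree(sim_config(seed = s, n_leaves = n,
                            branch_length_mean = mean_len))$edge.length)
  }, numeric(1))
  expected <- (2 * n - 2) * mean_len
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("noiseless curves peak in slope at the recorded inflection", {
  cfg <- sim_config(seed = 5, n_cells = 5, curve_noise_sd = 0, failure_rate = 0)
  cv <- sim_curves(cfg)
  for (id in cv$truth$cell_id) {
    d <- cv$curves[cv$curves$cell_id == id, ]
    slopes <- diff(d$fluorescence) / diff(d$time_min)
    t_steepest <- d$time_min[which.max(slopes)]
    # steepest finite-difference interval must straddle the true inflection
    expect_lt(abs(t_steepest - cv$truth$true_inflection[cv$truth$cell_id == id]),
              2 * diff(d$time_min)[1])
  }
})

test_that("failure_rate = 1 marks every curve failed in the ground truth", {
  cv <- sim_curves(sim_config(seed = 3, n_cells = 8, failure_rate = 1))
  expect_true(all(cv$truth$failed))
  expect_true(all(is.na(cv$truth$true_inflection)))
})

test_that("assemblies honor contamination fraction and determinism", {
  cfg0 <- sim_config(seed = 4, n_cells = 6, contamination_fraction = 0,
                     genome_length = 20000)
  a0 <- sim_assemblies(cfg0)
  expect_false(any(a0$truth$contaminated))
  expect_true(all(is.na(a0$truth$source_2)))

  a1 <- sim_assemblies(cfg0)
  expect_identical(a0$contigs$sequence, a1$contigs$sequence)

  cfg1 <- sim_config(seed = 4, n_cells = 6, contamination_fraction = 1,
                     genome_length = 20000)
  am <- sim_assemblies(cfg1)
  expect_true(all(am$truth$contaminated))
  expect_true(all(!is.na(am$truth$source_2)))
  expect_true(all(am$truth$source_1 != am$truth$source_2))
})

test_that("every simulated object has exactly one ground-truth record", {
  cfg <- sim_config(seed = 9, n_cells = 7, catalog_size = 10)
  cv <- sim_curves(cfg)
  expect_identical(sort(unique(cv$curves$cell_id)), sort(cv$truth$cell_id))
  asm <- sim_assemblies(cfg)
  expect_identical(sort(unique(asm$contigs$assembly_id)),
                   sort(asm$truth$assembly_id))
  g <- sim_gene_sets(cfg, n_per_target = 3, n_fresh = 2)
  expect_identical(sort(g$queries$gene_id), sort(g$truth$gene_id))
})

test_that("gene mutation hits the identity target exactly by construction", {
  cfg <- sim_config(seed = 11, catalog_size = 20, identity_targets = c(0.9, 1.0))
  g <- sim_gene_sets(cfg, n_per_target = 5, n_fresh = 0)
  derived <- g$truth[!is.na(g$truth$parent_id), ]
  for (i in seq_len(nrow(derived))) {
    q <- g$queries$sequence[g$queries$gene_id == derived$gene_id[i]]
    p <- g$catalog$sequence[g$catalog$gene_id == derived$parent_id[i]]
    expect_identical(nchar(q), nchar(p))
    mism <- sum(strsplit(q, "")[[1]] != strsplit(p, "")[[1]])
    expect_equal(mism, round((1 - derived$true_identity[i]) * nchar(q)))
  }
  # identity target 1 reproduces the parent verbatim
  ones <- derived[derived$true_identity == 1, ]
  expect_gt(nrow(ones), 0)
  for (i in seq_len(nrow(ones))) {
    q <- g$queries$sequence[g$queries$gene_id == ones$gene_id[i]]
    p <- g$catalog$sequence[g$catalog$gene_id == ones$parent_id[i]]
    expect_identical(q, p)
  }
})

test_that("fresh random genes sit near background identity to the catalog", {
  cfg <- sim_config(seed = 13, catalog_size = 30, identity_targets = c(0.9))
  g <- sim_gene_sets(cfg, n_per_target = 0, n_fresh = 5)
  labs <- label_novelty(g$queries, g$catalog)
  expect_true(all(is.na(labs$best_identity) | labs$best_identity < 0.6))
  expect_true(all(labs$novel))
})
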