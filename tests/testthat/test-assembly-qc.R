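test_that("contig end-trimming enforces the strict length rule", {
  s2200 <- strrep("A", 2200)
  s150 <- strrep("A", 150)
  s2301 <- paste0(strrep("G", 100), strrep("A", 2101), strrep("G", 100))
  out <- trim_contigs(c(s2200, s150, s2301))
  expect_length(out, 1L) # 2200 - 200 = 2000 is NOT > 2000; 150 underflows
  expect_identical(nchar(out), 2101L)
  expect_identical(out, strrep("A", 2101)) # both flanks removed
  expect_identical(trim_contigs(character()), character())
})

test_that("low-complexity filter applies the 5% per-base rule", {
  balanced <- strrep("ACGT", 100)
  poly_a <- strrep("A", 400)
  # A at 4.9%: 49 A + 951 others
  edge <- paste0(strrep("A", 49), strrep("C", 317), strrep("G", 317),
                 strrep("T", 317))
  out <- filter_low_complexity(c(balanced, poly_a, edge))
  expect_identical(out, balanced)
})

test_that("assembly metrics match hand-computed values and the 20 kb rule", {
  m <- qc_metrics(tibble::tibble(assembly_id = "a", sequence = "ATGC"))
  expect_identical(m$n_contigs, 1L)
  expect_identical(m$total_length, 4L)
  expect_identical(m$longest_contig, 4L)
  expect_equal(m$gc_fraction, 0.5)

  two <- qc_metrics(tibble::tibble(
    assembly_id = "b", sequence = c(strrep("A", 3000), strrep("A", 5000))
  ))
  expect_identical(two$n_contigs, 2L)
  expect_identical(two$total_length, 8000L)
  expect_identical(two$longest_contig, 5000L)

  near <- qc_metrics(tibble::tibble(assembly_id = c("x", "y"),
                                    sequence = c(strrep("A", 19999),
                                                 strrep("A", 20000))))
  expect_identical(near$pass_length_filter, c(FALSE, TRUE))

  # N positions are excluded from both sides of the GC ratio
  gcn <- qc_metrics(tibble::tibble(assembly_id = "n", sequence = "GCNNNN"))
  expect_equal(gcn$gc_fraction, 1)

  expect_error(qc_metrics(tibble::tibble(assembly_id = character(),
                                         sequence = character())),
               class = "sagdiv_invalid_input")
})

test_that("tetramer profiles are normalized and N-aware", {
  one <- tetramer_profile("AAAAAA")
  expect_identical(nrow(one), 1L)
  expect_equal(unname(one[1, "AAAA"]), 1)
  expect_equal(sum(one), 1)

  # periodic sequence: oracle by direct enumeration of sliding 4-mers
  s <- strrep("ACGT", 1250)
  kmers <- substring(s, 1:(nchar(s) - 3), 4:nchar(s))
  oracle <- table(kmers) / length(kmers)
  prof <- tetramer_profile(s, window = nchar(s))
  nz <- prof[1, prof[1, ] > 0]
  expect_identical(sort(names(nz)), sort(names(oracle)))
  expect_equal(unname(nz[names(oracle)]), unname(as.numeric(oracle)),
               tolerance = 1e-12)
  expect_identical(sum(prof[1, ] > 0), 4L)

  # an N prefix adds only N-containing (uncounted) tetramers
  base <- strrep("ACGGTT", 100)
  with_n <- paste0(strrep("N", 50), base)
  expect_equal(tetramer_profile(base), tetramer_profile(with_n),
               ignore_attr = TRUE)

  # every row is a probability vector
  m <- tetramer_profile(c(strrep("ACGGTTA", 2000)), window = 5000)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("contamination screen handles degenerate inputs", {
  # identical windows: zero variance, score 0, no flag
  rep_seq <- strrep(strrep("ACGGTTCA", 625), 3) # 3 identical 5 kb windows
  out <- contamination_screen(rep_seq)
  expect_false(out$contamination_flag)
  expect_equal(out$contamination_score, 0)

  # fewer than 3 windows: inconclusive with a warning
  expect_warning(short <- contamination_screen(strrep("ACGT", 1500)))
  expect_false(short$contamination_flag)
  expect_true(is.nan(short$contamination_score))
})

test_that("screen separates pure from two-genome assemblies", {
  pure_cfg <- sim_config(seed = 21, n_cells = 12, contamination_fraction = 0)
  mix_cfg <- sim_config(seed = 22, n_cells = 12, contamination_fraction = 1)
  pure <- qc_table(sim_assemblies(pure_cfg)$contigs)
  mixed <- qc_table(sim_assemblies(mix_cfg)$contigs)
  expect_gte(mean(!pure$contamination_flag), 0.9)
  expect_gte(mean(mixed$contamination_flag), 0.8)
})

test_that("five-number summaries use interpolated quantiles", {
  expect_equal(unlist(five_number(1:5)), c(min = 1, q25 = 2, median = 3,
                                           q75 = 4, max = 5))
  expect_equal(unlist(five_number(5)), c(min = 5, q25 = 5, median = 5,
                                         q75 = 5, max = 5))
  expect_equal(five_number(1:4)$median, 2.5)
  f <- five_number(c(2, 7, 1, 9))
  expect_true(f$min <= f$q25 && f$q25 <= f$median &&
                f$median <= f$q75 && f$q75 <= f$max)
  expect_error(five_number(numeric()), class = "sagdiv_invalid_input")
})
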