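
#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end synthetic workflow in
#' one validated object. Defaults are the workflow's standard thresholds:
#' assemblies below 20,000 bp are excluded; contig ends are trimmed by 100
#' bp and only contigs longer than 2,000 bp retained; genes are novel with
#' no catalog match above 95% nucleotide identity; genomes are novel with no
#' reference ANI above 97%; at most 150 cells are selected per run; species
#' prevalence counts hashes above 5; significance is declared below an
#' adjusted p of 0.1.
#'
#' @param seed Integer seed governing every stage.
#' @param outdir Output directory for stage artifacts.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "qc", "cost", "select", "gain", "novelty", "compare")`.
#' @param min_assembly_len,end_trim,min_contig_len Assembly QC thresholds.
#' @param contamination_threshold Tetramer-PCA dispersion-ratio flag cutoff.
#' @param gene_identity_threshold,ani_threshold Novelty cutoffs (strictly
#'   above = known).
#' @param cap,budget Selection cardinality cap and cost budget (minutes).
#' @param solver `"exact"` or `"greedy"`.
#' @param prevalence_min_hashes Strict hash-count threshold for prevalence.
#' @param alpha Adjusted-p significance display threshold.
#' @param n_permutations Enrichment permutations.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       outdir = tempfile("sagdiv_run_"),
                       sim = sim_config(seed = seed),
                       stages = c("simulate", "qc", "cost", "select", "gain",
                                  "novelty", "compare"),
                       min_assembly_len = 20000L,
                       end_trim = 100L,
                       min_contig_len = 2000L,
                       contamination_threshold = 5,
                       gene_identity_threshold = 0.95,
                       ani_threshold = 0.97,
                       cap = 150L,
                       budget = Inf,
                       solver = c("exact", "greedy"),
                       prevalence_min_hashes = 5L,
                       alpha = 0.1,
                       n_permutations = 2000L) {
  all_stages <- c("simulate", "qc", "cost", "select", "gain", "novelty", "compare")
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0L) {
    stop_invalid(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      seed = as.integer(seed), outdir = outdir, sim = sim,
      stages = intersect(all_stages, stages),
      min_assembly_len = min_assembly_len, end_trim = end_trim,
      min_contig_len = min_contig_len,
      contamination_threshold = contamination_threshold,
      gene_identity_threshold = gene_identity_threshold,
      ani_threshold = ani_threshold,
      cap = check_count(cap, "cap", 0L), budget = budget,
      solver = match.arg(solver),
      prevalence_min_hashes = prevalence_min_hashes,
      alpha = alpha, n_permutations = n_permutations
    ),
    class = "run_config"
  )
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_file <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

write_fasta <- function(seqs, names, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
}

#' Run the synthetic single-cell genomics pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate, assembly QC,
#' amplification cost, diversity-maximizing selection, phylogenetic gain,
#' gene-catalog novelty/enrichment, and group comparisons — writing each
#' stage's artifacts (newick / CSV / TSV / FASTA / JSON) to `config$outdir`
#' before the next stage starts. The run is a pure function of the
#' configuration: identical configs produce byte-identical data outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `sag_manifest`: list with `config`, `files`
#'   (tibble of path, md5, rows) and `started`/`finished` timestamps.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  on_stage <- function(s) s %in% config$stages
  path <- function(f) file.path(config$outdir, f)
  need <- function(f, stage, wanted_by) {
    if (!file.exists(path(f))) {
      stop_invalid(sprintf(
        "stage '%s' needs %s but stage '%s' is disabled and the file is absent",
        wanted_by, f, stage
      ), class = "sagdiv_config_error")
    }
  }

  # --- preflight: every enabled stage can be served -------------------------
  if (!on_stage("simulate")) {
    for (s in intersect(config$stages, c("qc", "cost", "select", "gain", "novelty"))) {
      need(switch(s, qc = "contigs.tsv", cost = "curves.csv",
                  select = "placements.tsv", gain = "placements.tsv",
                  novelty = "queries.tsv"), "simulate", s)
    }
  }
  if (on_stage("select")) {
    if (!on_stage("qc")) need("qc.tsv", "qc", "select")
    if (!on_stage("cost")) need("costs.tsv", "cost", "select")
  }
  if (on_stage("gain") && !on_stage("select")) need("selection.tsv", "select", "gain")

  # --- simulate -------------------------------------------------------------
  if (on_stage("simulate")) {
    tree <- sim_tree(config$sim)
    ape::write.tree(tree, path("ref_tree.nwk"))
    cv <- sim_curves(config$sim)
    utils::write.csv(cv$curves, path("curves.csv"), row.names = FALSE, quote = FALSE)
    asm <- sim_assemblies(config$sim)
    write_fasta(asm$contigs$sequence, asm$contigs$contig_id, path("assemblies.fasta"))
    write_tsv_file(asm$contigs[, c("assembly_id", "contig_id", "sequence")],
                   path("contigs.tsv"))
    genes <- sim_gene_sets(config$sim)
    write_fasta(genes$catalog$sequence, genes$catalog$gene_id, path("catalog.fasta"))
    write_fasta(genes$queries$sequence, genes$queries$gene_id, path("queries.fasta"))
    write_tsv_file(genes$catalog, path("catalog.tsv"))
    write_tsv_file(genes$queries, path("queries.tsv"))
    pl <- sim_placements(tree, asm$truth$assembly_id, config$sim)
    write_tsv_file(pl, path("placements.tsv"))
    truth <- list(curves = cv$truth, assemblies = asm$truth, genes = genes$truth)
    jsonlite::write_json(truth, path("ground_truth.json"), digits = NA,
                         na = "null")
  }

  # --- assembly qc ----------------------------------------------------------
  if (on_stage("qc")) {
    contigs <- read_tsv_file(path("contigs.tsv"))
    trimmed <- contigs |>
      group_by(.data$assembly_id) |>
      reframe(sequence = trim_contigs(.data$sequence, config$end_trim,
                                      config$min_contig_len))
    qc <- qc_table(trimmed, min_assembly_len = config$min_assembly_len,
                   score_threshold = config$contamination_threshold)
    write_tsv_file(qc, path("qc.tsv"))
  }

  # --- amplification cost ---------------------------------------------------
  if (on_stage("cost")) {
    curves <- as_tibble(utils::read.csv(path("curves.csv")))
    costs <- amplification_costs(curves)
    write_tsv_file(costs, path("costs.tsv"))
  }

  # --- selection ------------------------------------------------------------
  if (on_stage("select")) {
    qc <- read_tsv_file(path("qc.tsv"))
    costs <- read_tsv_file(path("costs.tsv"))
    pl <- read_tsv_file(path("placements.tsv"))
    tree <- ape::read.tree(path("ref_tree.nwk"))
    keep <- qc$assembly_id[qc$pass_qc]
    cand <- costs |>
      filter(.data$cell_id %in% keep, is.finite(.data$cost))
    grafted <- graft_placements(tree, pl[pl$sag_id %in% cand$cell_id, ])
    prob <- selection_problem(
      grafted$tree, setNames(cand$cost, cand$cell_id),
      budget = config$budget, cap = config$cap, anchored = TRUE
    )
    res <- if (config$solver == "exact") solve_exact(prob) else solve_greedy(prob)
    write_tsv_file(
      tibble(cell_id = cand$cell_id, chosen = cand$cell_id %in% res$chosen),
      path("selection.tsv")
    )
    jsonlite::write_json(
      list(solver = res$solver, pd = res$pd, objective = res$objective,
           total_cost = res$total_cost, n_chosen = length(res$chosen),
           budget = config$budget, cap = config$cap),
      path("selection.json"), auto_unbox = TRUE, digits = NA
    )
  }

  # --- phylogenetic gain ----------------------------------------------------
  if (on_stage("gain")) {
    sel <- read_tsv_file(path("selection.tsv"))
    pl <- read_tsv_file(path("placements.tsv"))
    tree <- ape::read.tree(path("ref_tree.nwk"))
    grafted <- graft_placements(tree, pl[pl$sag_id %in% sel$cell_id[sel$chosen], ])
    write_tsv_file(gain_table(grafted), path("gain.tsv"))
  }

  # --- gene-catalog novelty -------------------------------------------------
  if (on_stage("novelty")) {
    queries <- read_tsv_file(path("queries.tsv"))
    catalog <- read_tsv_file(path("catalog.tsv"))
    labels <- label_novelty(queries, catalog,
                            threshold = config$gene_identity_threshold)
    write_tsv_file(labels, path("labels.tsv"))
    ann <- sim_annotations(queries$gene_id, seed = config$seed)
    write_tsv_file(ann, path("annotations.tsv"))
    if (any(labels$novel) && !all(labels$novel)) {
      enr <- enrichment_test(labels, ann,
                             n_permutations = config$n_permutations,
                             seed = config$seed)
      write_tsv_file(enr, path("enrichment.tsv"))
    }
  }

  # --- group comparisons ----------------------------------------------------
  if (on_stage("compare") && file.exists(path("qc.tsv")) &&
      file.exists(path("selection.tsv"))) {
    qc <- read_tsv_file(path("qc.tsv"))
    sel <- read_tsv_file(path("selection.tsv"))
    long <- qc |>
      filter(.data$assembly_id %in% sel$cell_id) |>
      mutate(condition = ifelse(
        .data$assembly_id %in% sel$cell_id[sel$chosen], "selected", "unselected"
      )) |>
      select("assembly_id", "condition", "n_contigs", "total_length",
             "gc_fraction") |>
      tidyr::pivot_longer(c("n_contigs", "total_length", "gc_fraction"),
                          names_to = "metric_name", values_to = "value") |>
      dplyr::rename(sample_id = "assembly_id")
    if (length(unique(long$condition)) == 2L) {
      tests <- compare_conditions(long, paired = FALSE, alpha = config$alpha)
      write_tsv_file(tests, path("tests.tsv"))
    }
  }

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- structure(
    list(
      config = config,
      files = tibble(
        file = basename(files),
        md5 = unname(tools::md5sum(files)),
        bytes = file.size(files)
      ),
      started = started,
      finished = Sys.time()
    ),
    class = "sag_manifest"
  )
  jsonlite::write_json(
    list(seed = config$seed, stages = config$stages,
         files = manifest$files,
         started = format(started), finished = format(manifest$finished)),
    file.path(config$outdir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' @export
print.sag_manifest <- function(x, ...) {
  cat(sprintf("<sag_manifest> %d files in %s\n", nrow(x$files),
              x$config$outdir))
  invisible(x)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage artifacts of a finished [run_pipeline()] run and bundles
#' the headline numbers: Tukey five-number summaries of every assembly QC
#' metric, selection PD/cost, the root row of the per-clade gain table,
#' novelty fractions, and the comparison test results. The summary is also
#' written to `report.json` in the run directory.
#'
#' @param manifest A `sag_manifest` (or the run directory path).
#' @return A list with elements `qc_summaries`, `selection`, `gain_root`,
#'   `novelty`, `tests`.
#' @export
pipeline_report <- function(manifest) {
  outdir <- if (inherits(manifest, "sag_manifest")) {
    manifest$config$outdir
  } else {
    as.character(manifest)
  }
  path <- function(f) file.path(outdir, f)
  grab <- function(f) if (file.exists(path(f))) read_tsv_file(path(f)) else NULL

  qc <- grab("qc.tsv")
  qc_summaries <- NULL
  if (!is.null(qc)) {
    metrics <- c("n_contigs", "total_length", "longest_contig", "gc_fraction")
    qc_summaries <- bind_rows(purrr::map(metrics, function(m) {
      dplyr::bind_cols(tibble(metric = m), five_number(qc[[m]]))
    }))
  }
  selection <- if (file.exists(path("selection.json"))) {
    jsonlite::read_json(path("selection.json"), simplifyVector = TRUE)
  } else {
    NULL
  }
  gain <- grab("gain.tsv")
  gain_root <- if (!is.null(gain)) gain[which.min(gain$node_id), ] else NULL
  labels <- grab("labels.tsv")
  novelty <- if (!is.null(labels)) {
    list(n_genes = nrow(labels), n_novel = sum(labels$novel),
         frac_novel = mean(labels$novel))
  } else {
    NULL
  }
  report <- list(qc_summaries = qc_summaries, selection = selection,
                 gain_root = gain_root, novelty = novelty,
                 tests = grab("tests.tsv"))
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  report
}

#' @importFrom dplyr reframe
NULL
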