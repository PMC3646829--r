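# End-to-end orchestration: simulate -> filter -> align -> evaluate ->
# report, with deterministic seeding and machine-readable provenance.

#' Configuration for a full pipeline run
#'
#' Collects the stage thresholds in one place. Either supply file paths
#' (`reference_fasta`, `scaffolds_fasta`, `genes_gff3`, `clusters_tsv`,
#' optional `alignments_paf`, `reads_csfasta`/`reads_qual`) or in-memory
#' objects (`reference`, `scaffolds`) from the simulators.
#'
#' @param reference,scaffolds In-memory objects (`synthetic_genome` /
#'   `synthetic_scaffolds` or named sequence vectors), or `NULL` to read
#'   from the path fields.
#' @param reference_fasta,scaffolds_fasta,genes_gff3,clusters_tsv,alignments_paf,reads_csfasta,reads_qual
#'   Input paths (used when the in-memory fields are `NULL`).
#' @param filter A [filter_policy()] applied to reads, when reads are given.
#' @param min_score Alignment score threshold (default 40).
#' @param min_size Misarrangement counting threshold in bp (default 500).
#' @param class_bounds Fragment-length class bounds in bp (default 10/50 kb).
#' @param scaffold_floor Scaffold size floor in bp (default 95).
#' @param evalue_max HSP significance cutoff (default 1e-100).
#' @param seed Integer seed for any stage randomness.
#' @param out_dir Output directory for [run_pipeline()] TSVs (`NULL` for
#'   none).
#' @return A `run_config` list.
#' @export
run_config <- function(reference = NULL, scaffolds = NULL,
                       reference_fasta = NULL, scaffolds_fasta = NULL,
                       genes_gff3 = NULL, clusters_tsv = NULL,
                       alignments_paf = NULL, reads_csfasta = NULL,
                       reads_qual = NULL,
                       filter = filter_policy("nofilter"),
                       min_score = 40, min_size = 500,
                       class_bounds = c(10000, 50000), scaffold_floor = 95,
                       evalue_max = 1e-100, seed = 1L, out_dir = NULL) {
  stopifnot(min_score > 0, min_size > 0, all(class_bounds > 0),
            scaffold_floor > 0, evalue_max > 0)
  structure(list(
    reference = reference, scaffolds = scaffolds,
    reference_fasta = reference_fasta, scaffolds_fasta = scaffolds_fasta,
    genes_gff3 = genes_gff3, clusters_tsv = clusters_tsv,
    alignments_paf = alignments_paf, reads_csfasta = reads_csfasta,
    reads_qual = reads_qual, filter = filter, min_score = min_score,
    min_size = min_size, class_bounds = class_bounds,
    scaffold_floor = scaffold_floor, evalue_max = evalue_max,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' @noRd
.need_path <- function(path, what, stage) {
  if (is.null(path) || !file.exists(path)) {
    stopf("stage '%s' failed: %s path '%s' does not exist",
          stage, what, path %||% "<missing>")
  }
  path
}

# Provenance header lines for TSV outputs.
#' @noRd
.provenance <- function(config, stage) {
  c(sprintf("# stage: %s", stage),
    sprintf("# asmrecon_version: %s",
            as.character(utils::packageVersion("asmrecon"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# min_score: %g", config$min_score),
    sprintf("# min_size: %g", config$min_size),
    sprintf("# class_bounds: %s", paste(config$class_bounds, collapse = ",")),
    sprintf("# scaffold_floor: %g", config$scaffold_floor),
    sprintf("# evalue_max: %g", config$evalue_max))
}

#' @noRd
.write_tsv_prov <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(config, stage), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the assessment pipeline end to end
#'
#' Loads (or takes) the reference, gene annotations, cluster definitions and
#' scaffolds; optionally filters reads and reports their depth; aligns
#' scaffolds to the reference (or ingests a PAF); computes the full
#' [assembly_report()]; scores every gene and every cluster. With an
#' `out_dir`, writes `report.tsv`, `genes.tsv`, `clusters.tsv` and
#' `fragments.tsv`, each with a provenance header; re-running the same
#' configuration reproduces them byte-identically.
#'
#' @param config A [run_config()].
#' @return List with `report` ([assembly_report()]), `genes`
#'   ([evaluate_genes()] output), `gene_summary`, `clusters` (named logical
#'   of [cluster_continuity()] results), and `filter_stats` (when reads were
#'   supplied).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # ---- load stage -------------------------------------------------------
  reference <- config$reference
  if (is.null(reference)) {
    reference <- as_seqset(.need_path(config$reference_fasta, "reference",
                                      "load"))
  }
  genes <- NULL
  clusters <- NULL
  if (inherits(reference, "synthetic_genome")) {
    genes <- reference$genes
    clusters <- reference$clusters
  }
  if (!is.null(config$genes_gff3)) {
    genes <- read_genes_gff3(.need_path(config$genes_gff3, "annotation",
                                        "load"))
  }
  if (!is.null(config$clusters_tsv)) {
    clusters <- read_clusters(.need_path(config$clusters_tsv, "clusters",
                                         "load"))
  }
  scaffolds <- config$scaffolds
  if (is.null(scaffolds)) {
    scaffolds <- as_seqset(.need_path(config$scaffolds_fasta, "scaffolds",
                                      "load"))
  }

  # ---- filter stage (optional; reads inform depth only) -----------------
  filter_stats <- NULL
  if (!is.null(config$reads_csfasta)) {
    reads <- read_csfasta(.need_path(config$reads_csfasta, "reads", "filter"),
                          config$reads_qual)
    mates <- suppressWarnings(pair_mates(reads))
    flt <- filter_pairs(mates$f3, mates$r3, config$filter)
    filter_stats <- flt$stats
    genome_size <- sum(nchar(if (inherits(reference, "synthetic_genome"))
      reference$genome else reference))
    filter_stats$depth <- depth_of_coverage(
      flt$stats$reads_out,
      if (nrow(flt$f3)) nchar(flt$f3$colors[1]) else 0L,
      genome_size)
  }

  # ---- align stage ------------------------------------------------------
  fragments <- NULL
  if (!is.null(config$alignments_paf)) {
    fragments <- load_fragments(.need_path(config$alignments_paf,
                                           "alignments", "align"),
                                min_score = config$min_score)
  }

  # ---- evaluate stage ---------------------------------------------------
  report <- assembly_report(
    scaffolds, reference, fragments = fragments, genes = genes,
    min_score = config$min_score, min_size = config$min_size,
    class_bounds = config$class_bounds,
    scaffold_floor = config$scaffold_floor)

  gene_results <- NULL
  gene_summary <- NULL
  cluster_results <- NULL
  if (!is.null(genes) && nrow(genes)) {
    gene_results <- evaluate_genes(
      if (inherits(reference, "synthetic_genome")) reference
      else gene_sequences(reference, genes),
      scaffolds, evalue_max = config$evalue_max,
      scaffold_floor = config$scaffold_floor)
    gene_summary <- summarize_genes(gene_results)
    if (!is.null(clusters) && length(clusters)) {
      cluster_results <- clusters_continuity(clusters, gene_results)
    }
  }

  # ---- report stage -----------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv_prov(render_report(report, "table2"),
                    file.path(config$out_dir, "report.tsv"), config, "report")
    if (!is.null(gene_results)) {
      .write_tsv_prov(as.data.frame(gene_results),
                      file.path(config$out_dir, "genes.tsv"), config, "genes")
    }
    if (!is.null(cluster_results)) {
      .write_tsv_prov(
        data.frame(cluster_id = names(cluster_results),
                   continuous = unname(cluster_results),
                   stringsAsFactors = FALSE),
        file.path(config$out_dir, "clusters.tsv"), config, "clusters")
    }
    .write_tsv_prov(report$fragments,
                    file.path(config$out_dir, "fragments.tsv"), config,
                    "align")
  }

  list(report = report, genes = gene_results, gene_summary = gene_summary,
       clusters = cluster_results, filter_stats = filter_stats)
}

#' Render an assembly report in a standard table layout
#'
#' Formats an [assembly_report()] as a one-row data frame in one of four
#' conventional layouts: `"table2"` (size/coverage/R50/contig statistics;
#' N50 and Max in kb with 0 decimals, coverage to 2 decimals, R50 in bp),
#' `"table4"` (misarrangement counts and total deletion/insertion kb),
#' `"table5"` (small-indel counts, genome-wide and gene-restricted), or
#' `"table6"` (contig and scaffold counts and their ratio to 2 decimals).
#'
#' @param report An [assembly_report()].
#' @param style One of `"table2"`, `"table4"`, `"table5"`, `"table6"`.
#' @return A data frame with the corresponding columns.
#' @export
render_report <- function(report,
                          style = c("table2", "table4", "table5", "table6")) {
  style <- match.arg(style)
  stopifnot(inherits(report, "assembly_report"))
  switch(style,
    table2 = data.frame(
      `Number (>95 bp)` = report$size$n_scaffolds_95,
      `Number (>500 bp)` = report$size$n_scaffolds_500,
      `N50 (kb)` = round_half_up(report$size$n50 / 1000, 0),
      `Max (kb)` = round_half_up(report$size$max / 1000, 0),
      `Coverage (%)` = round_half_up(report$coverage_pct, 2),
      `R50 (bp)` = report$r50,
      `Contig number (>95 bp)` = report$n_contigs,
      `Contig N50 (kb)` = round_half_up(report$contig_n50 / 1000, 0),
      check.names = FALSE),
    table4 = data.frame(
      Misjoin = unname(report$misarrangement_counts["misjoin"]),
      Inversion = unname(report$misarrangement_counts["inversion"]),
      Deletion = unname(report$misarrangement_counts["deletion"]),
      Insertion = unname(report$misarrangement_counts["insertion"]),
      `Deletion total (kb)` = round_half_up(report$deletion_total_kb, 1),
      `Insertion total (kb)` = round_half_up(report$insertion_total_kb, 1),
      check.names = FALSE),
    table5 = data.frame(
      `Genome insertion` = unname(report$small_indels["n_insertions"]),
      `Genome deletion` = unname(report$small_indels["n_deletions"]),
      `Gene insertion` = unname(report$gene_small_indels["n_insertions"]),
      `Gene deletion` = unname(report$gene_small_indels["n_deletions"]),
      check.names = FALSE),
    table6 = data.frame(
      Contig = report$n_contigs,
      Scaffold = report$size$n_scaffolds_95,
      `Contig/scaffold` = report$scaffolding_ratio,
      check.names = FALSE)
  )
}
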