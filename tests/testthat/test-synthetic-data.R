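small_cfg <- function(seed = 1) {
  genome_config(
    n_chromosomes = 2L, chrom_length = 60000L, centromere_length = 5000L,
    n_genes = 6L,
    cluster_specs = list(list(n_genes = 3L, span = 6000L, repeat_unit = 0L,
                              n_repeats = 0L)),
    seed = seed)
}

test_that("genome generation is deterministic under a fixed seed", {
  g1 <- simulate_genome(small_cfg(5))
  g2 <- simulate_genome(small_cfg(5))
  g3 <- simulate_genome(small_cfg(6))
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$genes, g2$genes)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("generated genome honours structure: lengths, centromeres, genes", {
  cfg <- small_cfg(9)
  g <- simulate_genome(cfg)
  expect_equal(unname(nchar(g$genome)), rep(60000, 2))
  # centromere AT fraction at least the configured floor; background near GC
  for (i in 1:2) {
    cen <- substr(g$genome[[i]], g$centromeres$start[i], g$centromeres$end[i])
    at <- mean(strsplit(cen, "")[[1]] %in% c("A", "T"))
    expect_gte(at, cfg$at_fraction)
    arm <- substr(g$genome[[i]], 1, g$centromeres$start[i] - 1)
    gc <- mean(strsplit(arm, "")[[1]] %in% c("G", "C"))
    # cluster/gene sequences perturb composition only slightly
    expect_lt(abs(gc - cfg$gc_background), 0.03)
  }
  # genes non-overlapping per chromosome
  for (chrom in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == chrom, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  # cluster genes contiguous, ordered, inside the configured span
  cl <- g$genes[!is.na(g$genes$cluster), ]
  expect_equal(nrow(cl), 3)
  expect_identical(cl$gene_id[order(cl$start)], g$clusters$cluster_01)
  expect_lte(max(cl$end) - min(cl$start) + 1, 6000)
})

test_that("infeasible gene packing is rejected", {
  cfg <- genome_config(n_chromosomes = 1L, chrom_length = 20000L,
                       centromere_length = 2000L, n_genes = 50L,
                       gene_length = c(1500L, 2000L), cluster_specs = list(),
                       seed = 1)
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("an empty genome config yields sequence but no annotation", {
  cfg <- genome_config(n_chromosomes = 1L, chrom_length = 10000L,
                       centromere_length = 0L, n_genes = 0L,
                       cluster_specs = list(), seed = 3)
  g <- simulate_genome(cfg)
  expect_equal(nchar(g$genome[[1]]), 10000)
  expect_equal(nrow(g$genes), 0)
})

test_that("genome FASTA/GFF3/cluster files round-trip", {
  g <- simulate_genome(small_cfg(4))
  dir <- tempfile()
  paths <- write_genome(g, dir)
  seqs <- as.character(Biostrings::readDNAStringSet(paths["fasta"]))
  expect_identical(unname(seqs), unname(g$genome))
  genes <- read_genes_gff3(paths["gff3"])
  expect_identical(genes$gene_id, g$genes$gene_id)
  expect_identical(genes$start, g$genes$start)
  expect_identical(genes$end, g$genes$end)
  expect_identical(genes$strand, g$genes$strand)
  clusters <- read_clusters(paths["clusters"])
  expect_identical(clusters$cluster_01, g$clusters$cluster_01)
})

test_that("zero error rates give scaffolds identical to chromosomes", {
  g <- simulate_genome(small_cfg(2))
  sc <- simulate_scaffolds(g, scaffold_error_config(seed = 1))
  expect_identical(unname(sc$scaffolds), unname(g$genome))
  expect_equal(nrow(sc$truth), 0)
})

test_that("induced events are recorded exactly and scaffolds reconstruct", {
  g <- simulate_genome(small_cfg(3))
  ec <- scaffold_error_config(n_misjoin = 2L, n_inversion = 2L,
                              n_deletion = 2L, n_insertion = 2L,
                              size_range = c(600L, 2000L),
                              end_buffer = 4000L, seed = 8)
  sc <- simulate_scaffolds(g, ec)
  expect_equal(sum(sc$truth$kind == "misjoin"), 2)
  expect_equal(sum(sc$truth$kind == "inversion"), 2)
  expect_equal(sum(sc$truth$kind == "deletion"), 2)
  expect_equal(sum(sc$truth$kind == "insertion"), 2)
  expect_true(all(sc$truth$size[sc$truth$kind != "misjoin"] > 500))
  expect_true(all(sc$truth$countable))
  # misjoin junctions join different chromosomes
  mj <- sc$truth[sc$truth$kind == "misjoin", ]
  expect_true(all(mj$chrom != mj$chrom2))
  # segment-plan completeness: rebuilding every scaffold from reference +
  # segments (novel insertions taken from the emitted scaffold) is exact
  rebuilt <- reconstruct_scaffolds(g, sc$segments)
  for (sid in names(sc$scaffolds)) {
    segs <- sc$segments[sc$segments$scaffold_id == sid, ]
    no_ins <- paste(vapply(seq_len(nrow(segs)), function(i) {
      if (segs$kind[i] == "ins") ""
      else substr(sc$scaffolds[[sid]], segs$scaf_start[i], segs$scaf_end[i])
    }, character(1)), collapse = "")
    expect_identical(rebuilt[[sid]], no_ins)
  }
  # determinism
  sc2 <- simulate_scaffolds(g, ec)
  expect_identical(sc$scaffolds, sc2$scaffolds)
  expect_identical(sc$truth, sc2$truth)
})

test_that("deletion events remove exactly the recorded reference span", {
  g <- simulate_genome(small_cfg(12))
  ec <- scaffold_error_config(n_deletion = 1L, size_range = c(600L, 600L),
                              seed = 2)
  sc <- simulate_scaffolds(g, ec)
  tr <- sc$truth
  expect_equal(nrow(tr), 1)
  expect_equal(tr$size, 600L)
  sid <- tr$scaffold_id
  chrom_len <- nchar(g$genome[[tr$chrom]])
  expect_equal(nchar(sc$scaffolds[[sid]]), chrom_len - 600L)
  # sequence on both sides of the cut matches the reference
  expect_identical(substr(sc$scaffolds[[sid]], 1, tr$ref_pos - 1),
                   substr(g$genome[[tr$chrom]], 1, tr$ref_pos - 1))
  expect_identical(substring(sc$scaffolds[[sid]], tr$ref_pos),
                   substring(g$genome[[tr$chrom]], tr$ref_pos + 600))
})

test_that("N-gap runs replace reference sequence without being events", {
  g <- simulate_genome(small_cfg(13))
  sc <- simulate_scaffolds(g, scaffold_error_config(gaps_per_chrom = 2L,
                                                    n_gap_run = 150L,
                                                    seed = 4))
  expect_equal(nrow(sc$truth), 0)
  for (sid in names(sc$scaffolds)) {
    expect_equal(nchar(sc$scaffolds[[sid]]), 60000)
    n_count <- nchar(gsub("[^N]", "", sc$scaffolds[[sid]]))
    expect_equal(n_count, 300)
  }
})

test_that("mate-pair simulation matches its configured library", {
  g <- simulate_genome(small_cfg(21))
  lib <- library_config(insert_mean = 2764, insert_sd = 500, read_len = 50L,
                        n_pairs = 2000L, dot_rate = 0.01, seed = 31)
  mp <- simulate_mate_pairs(g, lib)
  expect_equal(nrow(mp$f3), 2000)
  expect_equal(unique(nchar(mp$f3$colors)), 50)
  # CLT bound on the realized insert mean (3 standard errors)
  expect_lt(abs(mean(mp$truth$insert) - 2764), 3 * 500 / sqrt(2000))
  # dot rate within binomial tolerance
  all_colors <- paste(c(mp$f3$colors, mp$r3$colors), collapse = "")
  p_hat <- mean(strsplit(all_colors, "")[[1]] == ".")
  expect_lt(abs(p_hat - 0.01), 4 * sqrt(0.01 * 0.99 / nchar(all_colors)))
  # a dot-free read decodes to the fragment it was drawn from
  i <- which(!grepl(".", mp$f3$colors, fixed = TRUE))[1]
  dec <- substring(decode_colorspace(mp$f3$primer_base[i], mp$f3$colors[i]), 2)
  tr <- mp$truth[i, ]
  frag <- substr(g$genome[[tr$chrom]], tr$start, tr$start + tr$insert - 1)
  if (tr$strand == "-") frag <- rc(frag)
  expect_identical(dec, substr(frag, 1, 50))
  # R3 is the other fragment end
  j <- which(!grepl(".", mp$r3$colors, fixed = TRUE))[1]
  decr <- substring(decode_colorspace(mp$r3$primer_base[j], mp$r3$colors[j]), 2)
  trj <- mp$truth[j, ]
  fragj <- substr(g$genome[[trj$chrom]], trj$start, trj$start + trj$insert - 1)
  if (trj$strand == "-") fragj <- rc(fragj)
  expect_identical(decr, substring(fragj, trj$insert - 49))
})

test_that("mate-pair edge cases: no pairs, no dots", {
  g <- simulate_genome(small_cfg(22))
  mp0 <- simulate_mate_pairs(g, library_config(n_pairs = 0L, seed = 1))
  expect_equal(nrow(mp0$f3), 0)
  mp <- simulate_mate_pairs(g, library_config(n_pairs = 50L, dot_rate = 0,
                                              seed = 2))
  expect_false(any(grepl(".", c(mp$f3$colors, mp$r3$colors), fixed = TRUE)))
})
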