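test_that("Karlin-Altschul E-values behave as a significance threshold", {
  # exact 500 bp match in a 100 kb search space is overwhelmingly significant
  expect_lt(karlin_evalue(500, 500, 1e5), 1e-100)
  # a 100 bp match is not
  expect_gt(karlin_evalue(100, 500, 1e5), 1e-100)
  # monotone decreasing in score
  e <- karlin_evalue(c(100, 200, 300), 1000, 1e6)
  expect_true(all(diff(e) < 0))
})

test_that("a gene present verbatim scores perfect reconstruction", {
  set.seed(401)
  genes <- c(gA = rand_dna(1200), gB = rand_dna(900))
  scaf <- c(s1 = paste0(rand_dna(500), genes[["gA"]], rand_dna(400),
                        genes[["gB"]], rand_dna(500)))
  res <- evaluate_genes(genes, scaf)
  expect_equal(res$hsp_fraction, c(1, 1))
  expect_equal(res$identity_fraction, c(1, 1))
  expect_false(any(res$lost))
  expect_identical(res$best_scaffold, c("s1", "s1"))
})

test_that("a gene absent from all scaffolds is lost with zero fractions", {
  set.seed(402)
  genes <- c(gA = rand_dna(1000), gGone = rand_dna(1000))
  scaf <- c(s1 = paste0(rand_dna(300), genes[["gA"]], rand_dna(300)))
  res <- evaluate_genes(genes, scaf)
  lost <- res[res$gene_id == "gGone", ]
  expect_true(lost$lost)
  expect_equal(lost$hsp_fraction, 0)
  expect_equal(lost$identity_fraction, 0)
})

test_that("a split gene is scored from the single best scaffold only", {
  set.seed(403)
  gene <- c(gS = rand_dna(2000))
  half1 <- substr(gene[["gS"]], 1, 1200)     # the better half
  half2 <- substr(gene[["gS"]], 1201, 2000)
  scafs <- c(s1 = paste0(rand_dna(200), half1, rand_dna(200)),
             s2 = paste0(rand_dna(200), half2, rand_dna(200)))
  res <- evaluate_genes(gene, scafs)
  expect_false(res$lost)
  expect_identical(res$best_scaffold, "s1")
  expect_equal(res$hsp_fraction, 0.6, tolerance = 0.02)
})

test_that("identity never exceeds HSP fraction", {
  set.seed(404)
  # mutated copy: HSP covers the gene but identity drops
  gene <- c(gM = rand_dna(1500))
  b <- strsplit(gene[["gM"]], "")[[1]]
  idx <- sample(1500, 30)
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  scaf <- c(s1 = paste0(rand_dna(200), paste(b, collapse = ""),
                        rand_dna(200)))
  res <- evaluate_genes(gene, scaf)
  expect_lte(res$identity_fraction, res$hsp_fraction)
  expect_lt(res$identity_fraction, 1)
  expect_gt(res$identity_fraction, 0.95)
})

test_that("gene summaries are base-weighted with exact arithmetic", {
  res <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    gene_len = c(1000L, 1000L, 1000L, 1000L),
    best_scaffold = c("s1", "s1", "s1", NA),
    best_score = c(1000, 1000, 1000, 0),
    n_hsps = c(1L, 1L, 1L, 0L),
    hsp_fraction = c(1, 1, 1, 0),
    identity_fraction = c(1, 1, 1, 0),
    lost = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  class(res) <- c("gene_recon", "data.frame")
  s <- summarize_genes(res)
  expect_equal(unname(s["hsp_pct"]), 75)
  expect_equal(unname(s["n_lost"]), 1)
  sub <- summarize_genes(res, subset = c("g1", "g2"))
  expect_equal(unname(sub["hsp_pct"]), 100)
  expect_lte(unname(sub["hsp_pct"]), 100)
  expect_error(summarize_genes(res, subset = "nope"), "unknown gene id")
})

test_that("cluster continuity requires one scaffold, order, and no interleaving", {
  set.seed(405)
  g1 <- rand_dna(1000); g2 <- rand_dna(1000); g3 <- rand_dna(1000)
  gx <- rand_dna(1000)  # a foreign gene
  genes <- c(g1 = g1, g2 = g2, g3 = g3, gx = gx)
  spacer <- function() rand_dna(300)

  # contiguous in order: continuous
  sc <- c(s1 = paste0(spacer(), g1, spacer(), g2, spacer(), g3, spacer(),
                      gx, spacer()))
  res <- evaluate_genes(genes, sc)
  expect_true(isTRUE(cluster_continuity(c("g1", "g2", "g3"), res)))

  # whole-cluster reversal is still continuous
  sc_rev <- c(s1 = paste0(spacer(), rc(paste0(g1, spacer(), g2, spacer(),
                                              g3)), spacer(), gx))
  res_rev <- evaluate_genes(genes, sc_rev)
  expect_true(isTRUE(cluster_continuity(c("g1", "g2", "g3"), res_rev)))

  # split across two scaffolds: broken
  sc_split <- c(s1 = paste0(spacer(), g1, spacer(), g2, spacer()),
                s2 = paste0(spacer(), g3, spacer(), gx))
  res_split <- evaluate_genes(genes, sc_split)
  expect_false(isTRUE(cluster_continuity(c("g1", "g2", "g3"), res_split)))

  # permuted order: broken
  sc_perm <- c(s1 = paste0(spacer(), g2, spacer(), g1, spacer(), g3))
  res_perm <- evaluate_genes(genes, sc_perm)
  expect_false(isTRUE(cluster_continuity(c("g1", "g2", "g3"), res_perm)))

  # a foreign gene interleaved between cluster genes: broken
  sc_inter <- c(s1 = paste0(spacer(), g1, spacer(), gx, spacer(), g2,
                            spacer(), g3))
  res_inter <- evaluate_genes(genes, sc_inter)
  expect_false(isTRUE(cluster_continuity(c("g1", "g2", "g3"), res_inter)))

  expect_error(cluster_continuity(c("g1", "missing"), res), "unknown gene id")
})

test_that("deleting a cluster-internal segment flips only that cluster", {
  g <- simulate_genome(genome_config(
    n_chromosomes = 2L, chrom_length = 60000L, centromere_length = 5000L,
    n_genes = 4L,
    cluster_specs = list(
      list(n_genes = 3L, span = 6000L, repeat_unit = 0L, n_repeats = 0L),
      list(n_genes = 3L, span = 6000L, repeat_unit = 0L, n_repeats = 0L)),
    seed = 77))
  scafs <- g$genome
  names(scafs) <- paste0("s_", names(scafs))
  res <- evaluate_genes(g, scafs)
  expect_true(all(clusters_continuity(g$clusters, res)))

  # excise cluster_01's middle gene span (plus margins) from its scaffold
  cl1 <- g$genes[!is.na(g$genes$cluster) & g$genes$cluster == "cluster_01", ]
  cl1 <- cl1[order(cl1$start), ]
  chrom <- cl1$chrom[1]
  cut_lo <- cl1$start[2] - 50
  cut_hi <- cl1$end[2] + 50
  broken <- scafs
  sid <- paste0("s_", chrom)
  broken[[sid]] <- paste0(substr(scafs[[sid]], 1, cut_lo - 1),
                          substring(scafs[[sid]], cut_hi + 1))
  res2 <- evaluate_genes(g, broken)
  cont <- clusters_continuity(g$clusters, res2)
  expect_false(unname(cont["cluster_01"]))
  expect_true(unname(cont["cluster_02"]))
})
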