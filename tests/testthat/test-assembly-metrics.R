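# Fragment rows are built directly (no aligner) so the metric definitions
# are tested in isolation.
frag_row <- function(sid, qs, qe, chrom, rs, re, strand = "+", score = 1000,
                     n_ins = 0L, n_del = 0L) {
  data.frame(scaffold_id = sid, scaffold_start = qs, scaffold_end = qe,
             ref_chrom = chrom, ref_start = rs, ref_end = re,
             strand = strand, score = score, n_match = re - rs + 1,
             n_mismatch = 0L, n_ins = n_ins, n_del = n_del,
             stringsAsFactors = FALSE)
}

test_that("n50 follows the cumulative-sum definition", {
  expect_equal(n50(100), 100)
  expect_equal(n50(c(50, 40, 30, 20, 10)), 40)
  expect_equal(n50(c(10, 10, 10, 10)), 10)
  expect_error(n50(numeric()))
})

test_that("n50 and ng50 agree with the brute-force oracle on random multisets", {
  set.seed(303)
  for (i in 1:200) {
    lens <- sample(1:500, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(lens), n50_oracle(lens))
    gsize <- sample(1:20000, 1)
    expect_equal(ng50(lens, gsize), n50_oracle(lens, gsize))
  }
})

test_that("ng50 handles threshold edge cases", {
  expect_equal(ng50(c(60, 30), 100), 60)
  expect_equal(ng50(10, 1000), 0)                      # unreachable sentinel
  lens <- c(40, 30, 20, 10)
  expect_equal(ng50(lens, sum(lens)), n50(lens))       # same threshold
  # once the total reaches the genome size, NG50 >= N50
  set.seed(304)
  for (i in 1:50) {
    lens <- sample(1:300, 20, replace = TRUE)
    gsize <- sample(seq_len(sum(lens)), 1)
    expect_gte(ng50(lens, gsize), n50(lens))
  }
})

test_that("r50 is NG50 over fragment reference spans", {
  fr <- rbind(frag_row("s1", 1, 60000, "c1", 1, 60000),
              frag_row("s2", 1, 30000, "c1", 65001, 95000))
  expect_equal(r50(fr, 100000), 60000)
  expect_equal(r50(empty_frags <- fr[0, ], 100000), 0)
  # full coverage of the reference in one fragment
  fr1 <- frag_row("s1", 1, 1e5, "c1", 1, 1e5)
  expect_equal(r50(fr1, 1e5), 1e5)
  # merge variant unions overlapping spans
  fr2 <- rbind(frag_row("s1", 1, 60000, "c1", 1, 60000),
               frag_row("s2", 1, 60000, "c1", 1, 60000))
  expect_equal(r50(fr2, 300000), 0)        # 120k of spans never reaches 150k
  expect_equal(r50(fr2, 100000, merge = TRUE), 60000)
})

test_that("genome coverage uses interval union semantics", {
  ref <- c(c1 = strrep("A", 100000))
  fr <- rbind(frag_row("s1", 1, 50000, "c1", 1, 50000),
              frag_row("s2", 1, 50000, "c1", 1, 50000))
  expect_equal(genome_coverage(fr, ref), 50)
  expect_equal(genome_coverage(fr[0, ], ref), 0)
  full <- rbind(frag_row("s1", 1, 60000, "c1", 1, 60000),
                frag_row("s2", 1, 50000, "c1", 50001, 100000))
  expect_equal(genome_coverage(full, ref), 100)
  # invariant under duplication
  expect_equal(genome_coverage(rbind(full, full), ref), 100)
})

test_that("length-class coverage attributes each base to the longest fragment", {
  ref <- c(c1 = strrep("A", 100000))
  fr <- frag_row("s1", 1, 60000, "c1", 1, 60000)
  cc <- coverage_by_class(fr, ref)
  expect_equal(unname(cc[">50kb"]), 0.6)
  expect_equal(unname(cc["uncovered"]), 0.4)
  expect_equal(sum(cc), 1)
  # 9 kb fragment sits in the <=10 kb class (boundary inclusive)
  fr9 <- frag_row("s1", 1, 9000, "c1", 1, 9000)
  cc9 <- coverage_by_class(fr9, ref)
  expect_equal(unname(cc9["<=10kb"]), 0.09)
  # exactly 10 kb still <=10 kb
  cc10 <- coverage_by_class(frag_row("s1", 1, 10000, "c1", 1, 10000), ref)
  expect_equal(unname(cc10["<=10kb"]), 0.1)
  # a base covered by both a short and a long fragment goes to the long one
  both <- rbind(frag_row("s1", 1, 9000, "c1", 1, 9000),
                frag_row("s2", 1, 60000, "c1", 1, 60000))
  ccb <- coverage_by_class(both, ref)
  expect_equal(unname(ccb["<=10kb"]), 0)
  expect_equal(unname(ccb[">50kb"]), 0.6)
  expect_equal(sum(ccb), 1)
})

test_that("misarrangement classification implements the adjacency rules", {
  # misjoin: consecutive fragments on different chromosomes
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 10000, "c2", 1, 5000))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "misjoin")

  # deletion: 600 bp reference gap, no scaffold gap
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 10000, "c1", 5601, 10600))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$size, 600)

  # 400 bp gap is below the counting threshold
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 10000, "c1", 5401, 10400))
  expect_equal(nrow(classify_misarrangements(fr)), 0)

  # insertion: 700 bp scaffold gap, no reference gap
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5701, 10700, "c1", 5001, 10000))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$size, 700)

  # inversion: interior flipped fragment counts once, not as two misjoins
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 6000, "c1", 5001, 6000, strand = "-"),
              frag_row("s1", 6001, 11000, "c1", 6001, 11000))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "inversion")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$size, 1000)

  # flipped run of 400 bp stays below the threshold
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 5400, "c1", 5001, 5400, strand = "-"),
              frag_row("s1", 5401, 10400, "c1", 5401, 10400))
  expect_equal(nrow(classify_misarrangements(fr)), 0)

  # same chromosome but displaced beyond the misjoin bound
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5001, 10000, "c1", 150001, 155000))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "misjoin")

  # same-locus N-bridged gap (equal gaps on both axes) is clean
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000),
              frag_row("s1", 5701, 10700, "c1", 5701, 10700))
  expect_equal(nrow(classify_misarrangements(fr)), 0)

  # minus-strand pair with a reference gap is still a deletion
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 5601, 10600, strand = "-"),
              frag_row("s1", 5001, 10000, "c1", 1, 5000, strand = "-"))
  ev <- classify_misarrangements(fr)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$size, 600)
})

test_that("small-indel counting sums fragments and respects a gene mask", {
  fr <- rbind(frag_row("s1", 1, 5000, "c1", 1, 5000, n_ins = 3L, n_del = 1L),
              frag_row("s2", 1, 5000, "c2", 1, 5000))
  expect_equal(unname(count_small_indels(fr)), c(3, 1))
  attr(fr, "indels") <- data.frame(
    scaffold_id = "s1", ref_chrom = "c1",
    ref_pos = c(100L, 2000L, 4000L),
    kind = c("insertion", "insertion", "deletion"),
    len = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  mask <- data.frame(chrom = "c1", start = 1500, end = 4500)
  expect_equal(unname(count_small_indels(fr, mask)), c(1, 1))
  # gene-restricted counts never exceed genome-wide counts
  g <- count_small_indels(fr)
  m <- count_small_indels(fr, mask)
  expect_true(all(m <= g))
})

test_that("contig splitting and the scaffolding ratio follow their definitions", {
  contigs <- split_to_contigs(c(s1 = "ACGTNNNNACGT"))
  expect_equal(unname(contigs), c("ACGT", "ACGT"))
  expect_equal(names(contigs), c("s1_ctg1", "s1_ctg2"))
  expect_equal(unname(split_to_contigs(c(s = "ACGTACGT"))), "ACGTACGT")
  expect_equal(length(split_to_contigs(c(s = "NNNN"))), 0)

  expect_equal(scaffolding_ratio(5332, 1184), 4.50)
  expect_equal(scaffolding_ratio(7153, 2456), 2.91)
  expect_equal(scaffolding_ratio(7, 7), 1.00)
  expect_error(scaffolding_ratio(5, 0))
})

test_that("size statistics apply the 95/500 bp floors", {
  scafs <- c(a = strrep("A", 2000), b = strrep("C", 400),
             c = strrep("G", 96), d = strrep("T", 95), e = strrep("A", 50))
  st <- size_stats(scafs)
  expect_equal(st$n_scaffolds_95, 3)
  expect_equal(st$n_scaffolds_500, 1)
  expect_equal(st$max, 2000)
  expect_equal(st$total, 2641)
  expect_gte(st$max, st$n50)
  expect_lte(st$n_scaffolds_500, st$n_scaffolds_95)
})
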