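test_that("an exact copy yields one full-length forward fragment", {
  set.seed(11)
  ref <- c(chr_a = rand_dna(5000))
  scafs <- c(s1 = ref[["chr_a"]])
  fr <- align_scaffolds(scafs, ref)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$scaffold_start, 1)
  expect_equal(fr$scaffold_end, 5000)
  expect_equal(fr$ref_start, 1)
  expect_equal(fr$ref_end, 5000)
  expect_identical(fr$strand, "+")
  expect_equal(fr$n_ins + fr$n_del + fr$n_mismatch, 0)
  expect_equal(fr$score, 5000)
})

test_that("a reverse-complemented copy aligns on the minus strand", {
  set.seed(12)
  ref <- c(chr_a = rand_dna(4000))
  scafs <- c(s1 = rc(substr(ref[["chr_a"]], 1001, 3000)))
  fr <- align_scaffolds(scafs, ref)
  expect_equal(nrow(fr), 1)
  expect_identical(fr$strand, "-")
  expect_equal(fr$ref_start, 1001)
  expect_equal(fr$ref_end, 3000)
  expect_equal(fr$scaffold_start, 1)
  expect_equal(fr$scaffold_end, 2000)
})

test_that("strand symmetry: reverse-complementing a scaffold flips strand only", {
  set.seed(13)
  ref <- c(chr_a = rand_dna(6000))
  piece <- substr(ref[["chr_a"]], 2001, 4500)
  fwd <- align_scaffolds(c(s = piece), ref)
  rev <- align_scaffolds(c(s = rc(piece)), ref)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "-")
  expect_equal(rev$ref_start, fwd$ref_start)
  expect_equal(rev$ref_end, fwd$ref_end)
  expect_equal(rev$score, fwd$score)
})

test_that("short random sequences never reach the significance threshold", {
  set.seed(14)
  ref <- c(chr_a = rand_dna(3000))
  for (i in 1:5) {
    fr <- align_scaffolds(setNames(list(rand_dna(30))[[1]], "s"), ref)
    expect_equal(nrow(fr), 0)
    # brute-force confirmation: the optimal local score itself is < 40
    expect_lt(sw_oracle_score(rand_dna(30), substr(ref[["chr_a"]], 1, 500)),
              40)
  }
})

test_that("N runs never match and break fragments cleanly", {
  set.seed(15)
  ref <- c(chr_a = rand_dna(4000))
  scaf <- paste0(substr(ref[["chr_a"]], 1, 1500), strrep("N", 700),
                 substr(ref[["chr_a"]], 2201, 4000))
  fr <- align_scaffolds(c(s = scaf), ref)
  expect_equal(nrow(fr), 2)
  expect_true(all(fr$n_mismatch == 0))
  # scaffold gap equals reference gap: no misarrangement
  ev <- classify_misarrangements(fr)
  expect_equal(nrow(ev), 0)
})

test_that("small indels inside a fragment are counted without splitting it", {
  set.seed(16)
  ref <- c(chr_a = rand_dna(5000))
  r <- ref[["chr_a"]]
  # 3 bp deleted at 1500, 2 bp inserted at 3000
  scaf <- paste0(substr(r, 1, 1500), substr(r, 1504, 3000), "GG",
                 substring(r, 3001))
  fr <- align_scaffolds(c(s = scaf), ref)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$n_del, 3)
  expect_equal(fr$n_ins, 2)
  ind <- attr(fr, "indels")
  expect_equal(sort(ind$kind), c("deletion", "insertion"))
  expect_equal(ind$len[ind$kind == "deletion"], 3)
})

test_that("the chained aligner matches the Smith-Waterman oracle on short pairs", {
  set.seed(17)
  for (i in 1:20) {
    q <- rand_dna(sample(50:200, 1))
    s <- if (i %% 2 == 0) rand_dna(sample(50:200, 1)) else {
      # related pair: mutated copy embedded in background
      paste0(rand_dna(30), mut <- q, rand_dna(30))
    }
    expect_equal(local_align(q, s)$score, sw_oracle_score(q, s))
  }
})

test_that("PAF fragments load with converted coordinates and tags", {
  paf <- tempfile(fileext = ".paf")
  writeLines(c(
    paste("s1", 1000, 0, 500, "+", "chr_a", 5000, 100, 600, 480, 500, 60,
          "AS:i:450", "cg:Z:200M5I200M5D95M", sep = "\t"),
    paste("s1", 1000, 500, 900, "-", "chr_b", 4000, 1000, 1400, 395, 400, 60,
          "AS:i:390", sep = "\t"),
    paste("s2", 800, 0, 60, "+", "chr_a", 5000, 0, 60, 35, 60, 60,
          "AS:i:20", sep = "\t")), paf)
  expect_message(fr <- load_fragments(paf), "dropped 1")
  expect_equal(nrow(fr), 2)
  expect_equal(fr$scaffold_start[1], 1)     # 0-based -> 1-based
  expect_equal(fr$scaffold_end[1], 500)
  expect_equal(fr$ref_start[1], 101)
  expect_equal(fr$ref_end[1], 600)
  expect_identical(fr$strand[2], "-")
  expect_equal(fr$score[1], 450)
  expect_equal(fr$n_ins[1], 5)
  expect_equal(fr$n_del[1], 5)
  ind <- attr(fr, "indels")
  expect_equal(nrow(ind), 2)
  expect_equal(ind$ref_pos[ind$kind == "insertion"], 301)

  # malformed lines are rejected with their line number
  writeLines("q\t100\t0\t50\t+\tt\t100\t0\t50\t40\t50", paf)  # 11 columns
  expect_error(load_fragments(paf), "line 1")
})

test_that("fragments round-trip through PAF output", {
  set.seed(18)
  ref <- c(chr_a = rand_dna(3000))
  scafs <- c(s1 = substr(ref[["chr_a"]], 501, 2500))
  fr <- align_scaffolds(scafs, ref)
  paf <- tempfile(fileext = ".paf")
  write_fragments(fr, paf, format = "paf",
                  scaffold_lengths = nchar(scafs),
                  ref_lengths = nchar(ref))
  back <- load_fragments(paf)
  expect_equal(back$scaffold_start, fr$scaffold_start)
  expect_equal(back$scaffold_end, fr$scaffold_end)
  expect_equal(back$ref_start, fr$ref_start)
  expect_equal(back$ref_end, fr$ref_end)
  expect_equal(back$score, fr$score)
})

test_that("an empty reference is rejected", {
  expect_error(align_scaffolds(c(s = "ACGTACGT"), character(0)))
})
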