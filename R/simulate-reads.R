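# Mate-paired color-space read simulator.
#
# Follows the SOLiD long mate-pair convention: both mates of a pair are
# emitted from the same strand of a size-selected fragment, the F3 tag from
# its 5' end and the R3 tag from its 3' end, separated by the insert. Insert
# sizes are Gaussian, truncated at twice the read length. Quality values
# follow a per-position Gaussian with a linearly declining mean (clipped to
# [0, 40]), which produces realistic minimum-QV filter rejection without
# modelling the instrument; undetermined-color dropout replaces a color with
# '.' (QV 0) at a fixed per-color rate.

#' Configuration for the mate-pair read simulator
#'
#' Defaults mirror a SOLiD long mate-paired library with a 2.8 kb insert
#' (mean 2764 bp, SD 500 bp) and 50 bp reads; the companion 1.9 kb library
#' uses `insert_mean = 1875`, `insert_sd = 400`.
#'
#' @param insert_mean,insert_sd Gaussian insert size parameters (bp).
#' @param read_len Read length in bp (number of colors per read).
#' @param n_pairs Number of mate pairs to generate.
#' @param dot_rate Per-color probability of an undetermined ('.') call.
#' @param qv_start,qv_end Mean QV at the first/last color (linear decline).
#' @param qv_sd Per-position QV standard deviation.
#' @param seed Integer seed.
#' @return A `library_config` list.
#' @export
library_config <- function(insert_mean = 2764, insert_sd = 500,
                           read_len = 50L, n_pairs = 1000L,
                           dot_rate = 0.01,
                           qv_start = 33, qv_end = 20, qv_sd = 6,
                           seed = 1L) {
  stopifnot(insert_mean > 0, insert_sd >= 0, read_len >= 2, n_pairs >= 0,
            dot_rate >= 0, dot_rate < 1, qv_sd >= 0)
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len = as.integer(read_len), n_pairs = as.integer(n_pairs),
                 dot_rate = dot_rate, qv_start = qv_start, qv_end = qv_end,
                 qv_sd = qv_sd, seed = as.integer(seed)),
            class = "library_config")
}

#' Simulate mate-paired color-space reads
#'
#' Draws fragments uniformly from the reference (chromosome chosen
#' proportional to length, strand at random), truncating insert sizes at
#' `2 * read_len` and at the chromosome length, and encodes both mates in
#' color space (F3 primer base T, R3 primer base G).
#'
#' @param reference A `synthetic_genome`, named character vector,
#'   `DNAStringSet`, or FASTA path. Chromosomes shorter than the maximum
#'   insert are excluded.
#' @param config A [library_config()].
#' @return List with `f3`, `r3` ([color_reads()] in pair order) and `truth`,
#'   a data frame of fragment positions and realized insert sizes.
#' @export
simulate_mate_pairs <- function(reference, config = library_config()) {
  stopifnot(inherits(config, "library_config"))
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  rl <- config$read_len
  with_seed(config$seed, {
    n <- config$n_pairs
    if (n == 0) {
      empty <- color_reads(character(), character(), character(),
                           character(), list())
      return(list(f3 = empty, r3 = empty,
                  truth = data.frame(pair_id = character(), chrom = character(),
                                     start = integer(), insert = integer(),
                                     strand = character(),
                                     stringsAsFactors = FALSE)))
    }
    lens <- nchar(genome)
    usable <- which(lens >= config$insert_mean + 4 * config$insert_sd)
    if (!length(usable)) stopf("no chromosome is longer than the max insert")
    chrom_idx <- usable[sample.int(length(usable), n, replace = TRUE,
                                   prob = lens[usable])]
    insert <- as.integer(round(rnorm(n, config$insert_mean, config$insert_sd)))
    insert <- pmax(insert, 2L * rl)
    insert <- pmin(insert, lens[chrom_idx])
    start <- vapply(seq_len(n), function(i) {
      sample.int(lens[chrom_idx[i]] - insert[i] + 1L, 1)
    }, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    frag_f3 <- character(n)
    frag_r3 <- character(n)
    for (i in seq_len(n)) {
      frag <- substr(genome[[chrom_idx[i]]], start[i],
                     start[i] + insert[i] - 1L)
      if (strand[i] == "-") frag <- revcomp(frag)
      frag_f3[i] <- substr(frag, 1L, rl)
      frag_r3[i] <- substr(frag, insert[i] - rl + 1L, insert[i])
    }

    mean_qv <- seq(config$qv_start, config$qv_end, length.out = rl)
    make_reads <- function(frags, tag, primer) {
      colors <- vapply(frags, function(s) {
        encode_colorspace(paste0(primer, s))$colors
      }, character(1), USE.NAMES = FALSE)
      qvs <- lapply(seq_len(n), function(i) {
        q <- as.integer(round(rnorm(rl, mean_qv, config$qv_sd)))
        pmin(pmax(q, 0L), 40L)
      })
      if (config$dot_rate > 0) {
        for (i in seq_len(n)) {
          dots <- which(runif(rl) < config$dot_rate)
          if (length(dots)) {
            cc <- strsplit(colors[i], "")[[1]]
            cc[dots] <- "."
            colors[i] <- paste(cc, collapse = "")
            qvs[[i]][dots] <- 0L
          }
        }
      }
      color_reads(sprintf("synth_%07d_%s", seq_len(n), tag),
                  rep(tag, n), rep(primer, n), colors, qvs)
    }
    f3 <- make_reads(frag_f3, "F3", "T")
    r3 <- make_reads(frag_r3, "R3", "G")
    truth <- data.frame(
      pair_id = sprintf("synth_%07d", seq_len(n)),
      chrom = names(genome)[chrom_idx], start = start, insert = insert,
      strand = strand, stringsAsFactors = FALSE)
    list(f3 = f3, r3 = r3, truth = truth)
  })
}
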