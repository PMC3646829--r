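# Synthetic reference genome generator.
#
# Emulates the statistical structure the assessment pipeline assumes of a
# small fungal genome: several chromosomes with an AT-rich centromere placed
# mid-chromosome, non-overlapping annotated genes, and physically contiguous
# secondary-metabolite-like gene clusters whose genes are built from similar
# repeating units (the feature that makes PKS/NRPS genes hard to assemble
# from short reads). Everything is deterministic under the configured seed.

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Point-mutate a DNA string at a given per-base substitution rate.
#' @noRd
mutate_dna <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  b <- strsplit(s, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a desk-scale stand-in for a small fungal genome: 8
#' chromosomes of 125 kb (1 Mb total), GC background 0.48, an 8 kb AT-rich
#' (>= 85% AT) centromere in the middle of each chromosome, 40 ordinary genes
#' of 1-2 kb, and three gene clusters — two PKS/NRPS-like clusters whose genes
#' are built from ~1.5 kb repeating units diverged ~10% from each other, and
#' one small 3-gene cluster.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param gc_background GC fraction of non-centromeric background sequence.
#' @param centromere_length Centromere length in bp (one per chromosome,
#'   mid-chromosome).
#' @param at_fraction Minimum AT fraction inside centromeres (enforced by
#'   composition, so the realized fraction is always >= this).
#' @param n_genes Number of ordinary (non-cluster) genes, placed
#'   non-overlapping outside centromeres and clusters.
#' @param gene_length Length range (bp) for ordinary genes.
#' @param cluster_specs List of cluster specifications, each a list with
#'   `n_genes`, `span` (bp), `repeat_unit` (bp; 0 for no repeat structure),
#'   `n_repeats` (repeat units per gene), and optionally `divergence`
#'   (per-base substitution rate between repeat units, default 0.10).
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A `genome_config` list.
#' @export
genome_config <- function(n_chromosomes = 8L,
                          chrom_length = 125000L,
                          gc_background = 0.48,
                          centromere_length = 8000L,
                          at_fraction = 0.85,
                          n_genes = 40L,
                          gene_length = c(1000L, 2000L),
                          cluster_specs = list(
                            list(n_genes = 5L, span = 28000L,
                                 repeat_unit = 1500L, n_repeats = 3L),
                            list(n_genes = 4L, span = 23000L,
                                 repeat_unit = 1500L, n_repeats = 3L),
                            list(n_genes = 3L, span = 6000L,
                                 repeat_unit = 0L, n_repeats = 0L)
                          ),
                          seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0,
            gc_background > 0, gc_background < 1,
            centromere_length >= 0, centromere_length < chrom_length,
            at_fraction >= 0, at_fraction <= 1, n_genes >= 0,
            length(gene_length) == 2, gene_length[1] <= gene_length[2])
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    gc_background = gc_background,
    centromere_length = as.integer(centromere_length),
    at_fraction = at_fraction,
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    cluster_specs = cluster_specs,
    seed = as.integer(seed)
  ), class = "genome_config")
}

# AT-rich sequence with AT fraction >= at_frac by construction.
#' @noRd
.at_rich_dna <- function(n, at_frac) {
  n_at <- ceiling(at_frac * n)
  b <- c(sample(c("A", "T"), n_at, replace = TRUE),
         sample(c("C", "G"), n - n_at, replace = TRUE))
  paste(sample(b), collapse = "")
}

# Build one cluster gene from diverged repeat units (PKS/NRPS-like).
#' @noRd
.repeat_gene_seq <- function(repeat_unit, n_repeats, divergence, gc) {
  base_unit <- random_dna(repeat_unit, gc)
  units <- vapply(seq_len(n_repeats),
                  function(i) mutate_dna(base_unit, divergence), character(1))
  paste0(random_dna(150, gc), paste(units, collapse = ""), random_dna(150, gc))
}

#' Simulate an annotated reference genome
#'
#' Generates chromosome sequences, a gene table and gene-cluster definitions
#' according to a [genome_config()]. Centromeres sit mid-chromosome; cluster
#' genes are contiguous, ordered and non-overlapping within their span;
#' ordinary genes are placed non-overlapping outside centromeres and clusters.
#'
#' @param config A [genome_config()].
#' @return A `synthetic_genome` list with elements:
#'   * `genome`: named character vector of chromosome sequences;
#'   * `genes`: data frame (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'     `cluster`) with 1-based closed coordinates;
#'   * `clusters`: named list of gene-id vectors in reference order;
#'   * `config`: the input configuration.
#' @export
simulate_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(config$seed, {
    nch <- config$n_chromosomes
    L <- config$chrom_length
    chrom_names <- paste0("chr_", tolower(as.roman(seq_len(nch))))
    genome <- setNames(vapply(seq_len(nch), function(i) {
      random_dna(L, config$gc_background)
    }, character(1)), chrom_names)

    # centromere mid-chromosome
    cen <- data.frame(chrom = chrom_names,
                      start = rep(0L, nch), end = rep(0L, nch))
    if (config$centromere_length > 0) {
      cs <- as.integer(floor((L - config$centromere_length) / 2)) + 1L
      ce <- cs + config$centromere_length - 1L
      for (i in seq_len(nch)) {
        substr(genome[i], cs, ce) <-
          .at_rich_dna(config$centromere_length, config$at_fraction)
      }
      cen$start <- cs
      cen$end <- ce
    }

    # free intervals per chromosome (1-based closed), excluding centromere
    # and a small margin at chromosome ends
    margin <- 2000L
    free <- lapply(seq_len(nch), function(i) {
      if (config$centromere_length > 0) {
        list(c(margin + 1L, cen$start[i] - margin),
             c(cen$end[i] + margin, L - margin))
      } else {
        list(c(margin + 1L, L - margin))
      }
    })

    claim <- function(chrom_idx, len, gap = 200L) {
      # pick a random free sub-interval on chrom_idx that fits `len`,
      # remove it (plus gap) from the free list; NULL if impossible
      ivs <- free[[chrom_idx]]
      fits <- which(vapply(ivs, function(iv) iv[2] - iv[1] + 1 >= len,
                           logical(1)))
      if (!length(fits)) return(NULL)
      w <- vapply(ivs[fits], function(iv) iv[2] - iv[1] + 1, numeric(1))
      k <- fits[sample.int(length(fits), 1, prob = w)]
      iv <- ivs[[k]]
      start <- iv[1] + sample.int(iv[2] - iv[1] + 1 - len + 1, 1) - 1L
      end <- start + len - 1L
      rest <- list()
      if (start - gap - 1L >= iv[1]) rest <- c(rest, list(c(iv[1], start - gap - 1L)))
      if (end + gap + 1L <= iv[2]) rest <- c(rest, list(c(end + gap + 1L, iv[2])))
      free[[chrom_idx]] <<- c(ivs[-k], rest)
      c(start, end)
    }

    genes <- list()
    clusters <- list()
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("g%04d", gid)
    }

    # clusters first (they need long contiguous spans)
    for (ci in seq_along(config$cluster_specs)) {
      sp <- config$cluster_specs[[ci]]
      div <- sp$divergence %||% 0.10
      chrom_idx <- ((ci - 1L) %% nch) + 1L
      span <- claim(chrom_idx, as.integer(sp$span), gap = 1000L)
      if (is.null(span)) {
        stopf("infeasible packing: cluster %d (span %d bp) does not fit on %s",
              ci, sp$span, chrom_names[chrom_idx])
      }
      cluster_id <- sprintf("cluster_%02d", ci)
      gene_seqs <- vapply(seq_len(sp$n_genes), function(g) {
        if (sp$repeat_unit > 0) {
          .repeat_gene_seq(sp$repeat_unit, sp$n_repeats, div,
                           config$gc_background)
        } else {
          random_dna(round(0.7 * sp$span / sp$n_genes), config$gc_background)
        }
      }, character(1))
      total_gene <- sum(nchar(gene_seqs))
      if (total_gene > span[2] - span[1] + 1) {
        stopf("infeasible packing: cluster %d genes (%d bp) exceed span %d bp",
              ci, total_gene, sp$span)
      }
      slack <- (span[2] - span[1] + 1) - total_gene
      gaps <- floor(slack * seq_len(sp$n_genes) / (sp$n_genes + 1))
      pos <- span[1]
      ids <- character(sp$n_genes)
      for (g in seq_len(sp$n_genes)) {
        glen <- nchar(gene_seqs[g])
        gstart <- pos + if (g == 1) gaps[1] else gaps[g] - gaps[g - 1]
        gend <- gstart + glen - 1L
        substr(genome[chrom_idx], gstart, gend) <- gene_seqs[g]
        ids[g] <- next_id()
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = ids[g], chrom = chrom_names[chrom_idx],
          start = as.integer(gstart), end = as.integer(gend),
          strand = sample(c("+", "-"), 1), cluster = cluster_id,
          stringsAsFactors = FALSE
        )
        pos <- gend + 1L
      }
      clusters[[cluster_id]] <- ids
    }

    # ordinary genes
    if (config$n_genes > 0) {
      chrom_of <- sort(rep_len(seq_len(nch), config$n_genes))
      for (i in seq_len(config$n_genes)) {
        glen <- sample(seq(config$gene_length[1], config$gene_length[2]), 1)
        span <- claim(chrom_of[i], glen)
        if (is.null(span)) {
          stopf("infeasible packing: gene %d of %d (length %d bp) does not fit",
                i, config$n_genes, glen)
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = next_id(), chrom = chrom_names[chrom_of[i]],
          start = span[1], end = span[2],
          strand = sample(c("+", "-"), 1), cluster = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }

    genes <- if (length(genes)) do.call(rbind, genes) else data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), cluster = character(),
      stringsAsFactors = FALSE
    )
    if (nrow(genes)) {
      genes <- genes[order(match(genes$chrom, chrom_names), genes$start), ]
      rownames(genes) <- NULL
    }

    structure(list(genome = genome, genes = genes, clusters = clusters,
                   centromeres = cen, config = config),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic_genome: %d chromosomes, %s bp total, %d genes, %d clusters\n",
    length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
    nrow(x$genes), length(x$clusters)))
  invisible(x)
}

#' Extract gene sequences from a reference
#'
#' Returns the genomic sequence of each gene (introns included): the
#' reference substring over the gene interval, reverse-complemented for
#' minus-strand genes.
#'
#' @param reference A `synthetic_genome`, named character vector,
#'   `DNAStringSet`, or FASTA path.
#' @param genes Gene data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`); taken from `reference` if it is a `synthetic_genome`.
#' @return Named character vector of gene sequences.
#' @export
gene_sequences <- function(reference, genes = NULL) {
  if (inherits(reference, "synthetic_genome")) {
    genes <- genes %||% reference$genes
    genome <- reference$genome
  } else {
    genome <- as_seqset(reference)
  }
  if (is.null(genes)) stopf("gene table required")
  out <- vapply(seq_len(nrow(genes)), function(i) {
    s <- substr(genome[[genes$chrom[i]]], genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, genes$gene_id)
}

#' Write a synthetic genome to FASTA + GFF3 + cluster list
#'
#' @param x A `synthetic_genome`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default "reference").
#' @return Invisibly, a named character vector of the paths written
#'   (`fasta`, `gff3`, `clusters`).
#' @export
write_genome <- function(x, dir, prefix = "reference") {
  stopifnot(inherits(x, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  cl <- file.path(dir, paste0(prefix, "_clusters.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$genome), fa)
  gr <- GenomicRanges::GRanges(
    seqnames = x$genes$chrom,
    ranges = IRanges::IRanges(x$genes$start, x$genes$end),
    strand = x$genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- x$genes$gene_id
  S4Vectors::mcols(gr)$cluster <- x$genes$cluster
  rtracklayer::export(gr, gff, format = "gff3")
  write_clusters(x$clusters, cl)
  invisible(c(fasta = fa, gff3 = gff, clusters = cl))
}

#' Read gene annotations from GFF3
#'
#' @param path GFF3 path (type "gene" records; 1-based closed coordinates).
#' @return Gene data frame as in [simulate_genome()].
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  mc <- S4Vectors::mcols(gr)
  data.frame(
    gene_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    cluster = if ("cluster" %in% names(mc)) as.character(mc$cluster)
              else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write / read gene-cluster definitions
#'
#' Plain TSV with columns `cluster_id`, `order`, `gene_id`; one row per gene,
#' ordered along the reference.
#'
#' @param clusters Named list of ordered gene-id vectors.
#' @param path Output path.
#' @return `write_clusters`: invisibly, `path`. `read_clusters`: named list of
#'   ordered gene-id vectors.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(names(clusters), function(cid) {
    data.frame(cluster_id = cid, order = seq_along(clusters[[cid]]),
               gene_id = clusters[[cid]], stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = character(), order = integer(),
                       gene_id = character(), stringsAsFactors = FALSE)
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, df$order), ]
  split(df$gene_id, df$cluster_id)
}
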