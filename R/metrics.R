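# Assembly-level statistics: size statistics (N50/NG50/R50), reference
# coverage, fragment-length-class coverage, misarrangement classification,
# small-indel accounting, contig derivation and the scaffolding ratio.

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together contain
#' at least half of all bases (the standard cumulative-sum convention).
#'
#' @param lengths Positive numeric vector of sequence lengths.
#' @return N50 in bp.
#' @examples
#' n50(c(50, 40, 30, 20, 10))  # 40
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stopf("n50 of an empty length set is undefined")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' NG50 of a set of sequence lengths against a genome size
#'
#' As [n50()] but the half-threshold is taken against `genome_size` rather
#' than the assembly size. Returns 0 when the cumulative length never reaches
#' half the genome (undefined sentinel).
#'
#' @param lengths Positive numeric vector of sequence lengths.
#' @param genome_size Reference genome size in bp (> 0).
#' @return NG50 in bp, or 0 if unreachable.
#' @examples
#' ng50(c(60, 30), 100)  # 60
#' @export
ng50 <- function(lengths, genome_size) {
  if (genome_size <= 0) stopf("genome_size must be > 0")
  if (!length(lengths)) return(0)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= genome_size / 2)[1]
  if (is.na(i)) 0 else unname(s[i])
}

#' R50: NG50 of reference fragments covered by significant alignments
#'
#' The N50-style statistic for genome reconstruction: the NG50 of the
#' reference spans of scaffold alignment fragments (pre-filtered to
#' significant score), with the reference genome size as the total. Unlike
#' N50 it penalises misarranged scaffolds, whose alignments break into short
#' fragments.
#'
#' @param fragments AlignmentFragment data frame (see [align_scaffolds()]);
#'   reference spans are `ref_end - ref_start + 1`.
#' @param genome_size Reference genome size in bp.
#' @param merge If `TRUE`, overlapping reference intervals are union-merged
#'   per chromosome before taking spans (sensitivity variant); the default
#'   counts each fragment's span as-is.
#' @return R50 in bp (0 for no fragments).
#' @export
r50 <- function(fragments, genome_size, merge = FALSE) {
  if (!nrow(fragments)) return(0)
  if (merge) {
    spans <- unlist(lapply(split(fragments, fragments$ref_chrom), function(f) {
      IRanges::width(IRanges::reduce(IRanges::IRanges(f$ref_start, f$ref_end)))
    }), use.names = FALSE)
  } else {
    spans <- fragments$ref_end - fragments$ref_start + 1
  }
  ng50(spans, genome_size)
}

#' Reference genome coverage by alignment fragments
#'
#' 100 x |union of reference intervals| / reference length: overlapping or
#' duplicated fragments are counted once.
#'
#' @param fragments AlignmentFragment data frame.
#' @param reference Reference sequences (any form accepted by
#'   [align_scaffolds()]), used for the total length.
#' @return Coverage percentage in \[0, 100\].
#' @export
genome_coverage <- function(fragments, reference) {
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  total <- sum(nchar(genome))
  if (!nrow(fragments)) return(0)
  covered <- sum(unlist(lapply(split(fragments, fragments$ref_chrom),
    function(f) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(f$ref_start, f$ref_end))))
    }), use.names = FALSE))
  100 * covered / total
}

#' Reference coverage by fragment length class
#'
#' Attributes each reference base to the longest fragment covering it, then
#' reports the fraction of the genome in each length class (by default
#' <= 10 kb, 10-50 kb, > 50 kb) plus the uncovered fraction. Fractions sum
#' to 1.
#'
#' @param fragments AlignmentFragment data frame.
#' @param reference Reference sequences.
#' @param bounds Ascending class bounds in bp (default `c(10000, 50000)`).
#' @return Named numeric vector of fractions: one per class (e.g. `"<=10kb"`,
#'   `">10kb"`, `">50kb"`) and `"uncovered"`.
#' @export
coverage_by_class <- function(fragments, reference, bounds = c(10000, 50000)) {
  stopifnot(!is.unsorted(bounds), all(bounds > 0))
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  lens <- nchar(genome)
  class_names <- c(paste0("<=", bounds[1] / 1000, "kb"),
                   paste0(">", bounds / 1000, "kb"))
  counts <- setNames(numeric(length(class_names)), class_names)
  if (nrow(fragments)) {
    fragments$span <- fragments$ref_end - fragments$ref_start + 1
    # paint in ascending span order so the longest fragment wins each base
    fragments <- fragments[order(fragments$span), , drop = FALSE]
    fragments$class <- findInterval(fragments$span, bounds,
                                    left.open = TRUE) + 1L
    for (chrom in unique(fragments$ref_chrom)) {
      f <- fragments[fragments$ref_chrom == chrom, , drop = FALSE]
      v <- integer(lens[[chrom]])
      for (i in seq_len(nrow(f))) {
        v[f$ref_start[i]:f$ref_end[i]] <- f$class[i]
      }
      tab <- tabulate(v, nbins = length(class_names))
      counts <- counts + tab
    }
  }
  frac <- counts / sum(lens)
  c(frac, uncovered = 1 - sum(frac))
}

#' Classify misarrangements from ordered alignment fragments
#'
#' Walks consecutive fragment pairs of each scaffold (fragments whose
#' scaffold interval lies inside another fragment's are ignored) and
#' classifies discordances, counting only events larger than `min_size` in
#' the reference:
#'
#' * **misjoin** — the pair maps to different chromosomes, or to loci whose
#'   separation on the reference disagrees with the scaffold by more than
#'   `misjoin_bound`;
#' * **inversion** — a maximal run of fragments whose strand opposes its
#'   same-locus neighbours (counted once per flipped run, not once per
#'   junction), provided the run spans more than `min_size`;
#' * **deletion** — the reference gap between the pair exceeds the scaffold
#'   gap by more than `min_size` (size = the difference);
#' * **insertion** — the scaffold gap exceeds the reference gap by more than
#'   `min_size`.
#'
#' @param fragments AlignmentFragment data frame (sorted output of
#'   [align_scaffolds()] or [load_fragments()]).
#' @param min_size Counting threshold in bp (default 500; events of size
#'   <= `min_size` are never reported).
#' @param misjoin_bound Reference-vs-scaffold displacement beyond which a
#'   same-chromosome pair is a misjoin rather than an indel (default 100 kb).
#' @return MisarrangementEvent data frame: `kind`, `scaffold_id`, `size`
#'   (NA for misjoins and measured on the reference for inversions),
#'   `ref_chrom`, `ref_pos`, `ref_chrom2`, `ref_pos2` (misjoins only).
#' @export
classify_misarrangements <- function(fragments, min_size = 500,
                                     misjoin_bound = 1e5) {
  events <- list()
  add <- function(kind, sid, size, chrom, pos, chrom2 = NA_character_,
                  pos2 = NA_integer_) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, scaffold_id = sid, size = size, ref_chrom = chrom,
      ref_pos = as.integer(pos), ref_chrom2 = chrom2,
      ref_pos2 = as.integer(pos2), stringsAsFactors = FALSE)
  }
  for (sid in unique(fragments$scaffold_id)) {
    fr <- fragments[fragments$scaffold_id == sid, , drop = FALSE]
    fr <- fr[order(fr$scaffold_start, fr$scaffold_end), , drop = FALSE]
    if (is.unsorted(fr$scaffold_start)) stopf("fragments must be sorted")
    # drop fragments scaffold-contained in another (repeat-induced copies)
    if (nrow(fr) > 1) {
      contained <- vapply(seq_len(nrow(fr)), function(i) {
        any(fr$scaffold_start <= fr$scaffold_start[i] &
            fr$scaffold_end >= fr$scaffold_end[i] &
            seq_len(nrow(fr)) != i &
            (fr$scaffold_end - fr$scaffold_start >
               fr$scaffold_end[i] - fr$scaffold_start[i]))
      }, logical(1))
      fr <- fr[!contained, , drop = FALSE]
    }
    n <- nrow(fr)
    if (n < 2) next

    # pass 1: segment into same-locus blocks; block breaks are misjoins
    block <- integer(n)
    block[1] <- 1L
    for (i in seq_len(n - 1L)) {
      f1 <- fr[i, ]
      f2 <- fr[i + 1L, ]
      same_locus <- f1$ref_chrom == f2$ref_chrom
      if (same_locus) {
        # unsigned distance between the two reference intervals
        dist <- max(0L, max(f1$ref_start, f2$ref_start) -
                        min(f1$ref_end, f2$ref_end))
        scaf_gap <- f2$scaffold_start - f1$scaffold_end - 1L
        same_locus <- dist - max(scaf_gap, 0L) <= misjoin_bound
      }
      if (!same_locus) {
        add("misjoin", sid, NA_integer_, f1$ref_chrom,
            if (f1$strand == "+") f1$ref_end else f1$ref_start,
            f2$ref_chrom,
            if (f2$strand == "+") f2$ref_start else f2$ref_end)
        block[i + 1L] <- block[i] + 1L
      } else {
        block[i + 1L] <- block[i]
      }
    }

    for (b in unique(block)) {
      bf <- fr[block == b, , drop = FALSE]
      m <- nrow(bf)
      if (m < 2) next
      # inversions: maximal runs opposing the majority strand of the block,
      # provided the run is larger than min_size on the reference
      span_by_strand <- tapply(bf$ref_end - bf$ref_start + 1, bf$strand, sum)
      majority <- names(span_by_strand)[which.max(span_by_strand)]
      run <- rle(bf$strand)
      run_end <- cumsum(run$lengths)
      run_start <- run_end - run$lengths + 1L
      for (ri in seq_along(run$values)) {
        if (run$values[ri] == majority) next
        rs <- run_start[ri]
        re <- run_end[ri]
        inv_span <- max(bf$ref_end[rs:re]) - min(bf$ref_start[rs:re]) + 1L
        if (inv_span > min_size) {
          add("inversion", sid, inv_span, bf$ref_chrom[1],
              min(bf$ref_start[rs:re]))
        }
      }
      # indels: same-strand consecutive pairs only
      for (i in seq_len(m - 1L)) {
        f1 <- bf[i, ]
        f2 <- bf[i + 1L, ]
        if (f1$strand != f2$strand) next
        ref_gap <- if (f1$strand == "+") f2$ref_start - f1$ref_end - 1L
                   else f1$ref_start - f2$ref_end - 1L
        scaf_gap <- f2$scaffold_start - f1$scaffold_end - 1L
        d <- ref_gap - scaf_gap
        if (d > min_size) {
          add("deletion", sid, d, f1$ref_chrom,
              if (f1$strand == "+") f1$ref_end + 1L else f2$ref_end + 1L)
        } else if (-d > min_size) {
          add("insertion", sid, -d, f1$ref_chrom,
              if (f1$strand == "+") f1$ref_end + 1L else f1$ref_start - 1L)
        }
      }
    }
  }
  if (length(events)) {
    out <- do.call(rbind, events)
    rownames(out) <- NULL
    out
  } else {
    data.frame(kind = character(), scaffold_id = character(),
               size = integer(), ref_chrom = character(), ref_pos = integer(),
               ref_chrom2 = character(), ref_pos2 = integer(),
               stringsAsFactors = FALSE)
  }
}

#' Count small indels in alignment fragments
#'
#' Sums per-alignment insertion and deletion base counts over fragments.
#' With a gene mask, only indels whose reference position falls inside a
#' gene are counted (requires per-indel detail in `attr(fragments,
#' "indels")`, as produced by [align_scaffolds()]).
#'
#' @param fragments AlignmentFragment data frame.
#' @param gene_mask Optional gene data frame (`chrom`, `start`, `end`) or
#'   `GRanges` restricting the count to gene regions.
#' @return Named integer vector `c(n_insertions, n_deletions)`.
#' @export
count_small_indels <- function(fragments, gene_mask = NULL) {
  if (is.null(gene_mask)) {
    return(c(n_insertions = sum(fragments$n_ins),
             n_deletions = sum(fragments$n_del)))
  }
  ind <- attr(fragments, "indels")
  if (is.null(ind)) {
    stopf("gene-restricted counts need per-indel detail (attr 'indels')")
  }
  if (methods::is(gene_mask, "GRanges")) {
    gene_mask <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gene_mask)),
      start = GenomicRanges::start(gene_mask),
      end = GenomicRanges::end(gene_mask), stringsAsFactors = FALSE)
  }
  if (!nrow(ind)) return(c(n_insertions = 0L, n_deletions = 0L))
  in_mask <- vapply(seq_len(nrow(ind)), function(i) {
    any(gene_mask$chrom == ind$ref_chrom[i] &
        gene_mask$start <= ind$ref_pos[i] &
        gene_mask$end >= ind$ref_pos[i])
  }, logical(1))
  c(n_insertions = sum(ind$len[in_mask & ind$kind == "insertion"]),
    n_deletions = sum(ind$len[in_mask & ind$kind == "deletion"]))
}

#' Split scaffolds into contigs at N runs
#'
#' Contigs are the maximal N-free runs of each scaffold; empty pieces are
#' dropped (a scaffold of only N yields no contigs).
#'
#' @param scaffolds Named character vector, `DNAStringSet`, FASTA path, or
#'   `synthetic_scaffolds`.
#' @return Named character vector of contigs (`<scaffold>_ctg<i>`).
#' @export
split_to_contigs <- function(scaffolds) {
  scafs <- if (inherits(scaffolds, "synthetic_scaffolds")) scaffolds$scaffolds
           else as_seqset(scaffolds)
  out <- character()
  for (sid in names(scafs)) {
    pieces <- strsplit(scafs[[sid]], "N+")[[1]]
    pieces <- pieces[nzchar(pieces)]
    if (length(pieces)) {
      names(pieces) <- sprintf("%s_ctg%d", sid, seq_along(pieces))
      out <- c(out, pieces)
    }
  }
  out
}

#' Scaffolding ratio
#'
#' Contig count divided by scaffold count, reported half-up to 2 decimals
#' (table convention). Higher means more contigs joined per scaffold.
#'
#' @param n_contigs,n_scaffolds Counts; `n_scaffolds` must be > 0.
#' @return Numeric ratio rounded to 2 decimals.
#' @examples
#' scaffolding_ratio(5332, 1184)  # 4.50
#' @export
scaffolding_ratio <- function(n_contigs, n_scaffolds) {
  if (any(n_scaffolds <= 0)) stopf("n_scaffolds must be > 0")
  round_half_up(n_contigs / n_scaffolds, 2)
}

#' Scaffold size statistics
#'
#' @param scaffolds Named character vector (or any form accepted by
#'   [split_to_contigs()]).
#' @param floor_95,floor_500 Size floors for the two count columns.
#' @return One-row data frame: `n_scaffolds_95`, `n_scaffolds_500`, `n50`,
#'   `max`, `total` (all sizes in bp; N50 over scaffolds > `floor_95`).
#' @export
size_stats <- function(scaffolds, floor_95 = 95, floor_500 = 500) {
  scafs <- if (inherits(scaffolds, "synthetic_scaffolds")) scaffolds$scaffolds
           else as_seqset(scaffolds)
  lens <- nchar(scafs)
  kept <- lens[lens > floor_95]
  data.frame(
    n_scaffolds_95 = sum(lens > floor_95),
    n_scaffolds_500 = sum(lens > floor_500),
    n50 = if (length(kept)) n50(kept) else 0,
    max = if (length(lens)) max(lens) else 0,
    total = sum(lens)
  )
}

#' Full assembly report
#'
#' Computes the complete metrics table for one assembly: size statistics,
#' reference coverage, R50, length-class coverage, misarrangement counts and
#' total deletion/insertion sizes, small-indel counts (genome-wide and
#' gene-restricted), contig statistics and the scaffolding ratio.
#'
#' @param scaffolds Scaffold sequences.
#' @param reference Reference sequences (any accepted form).
#' @param fragments Optional precomputed AlignmentFragment data frame; when
#'   `NULL`, [align_scaffolds()] is run.
#' @param genes Optional gene table for gene-restricted indel counts.
#' @param min_score Alignment score threshold (used when aligning here).
#' @param min_size Misarrangement counting threshold (bp).
#' @param class_bounds Length-class bounds for [coverage_by_class()].
#' @param scaffold_floor Scaffolds at or below this length are excluded from
#'   alignment-based metrics (default 95 bp).
#' @return An `assembly_report` list; see fields in the description.
#' @export
assembly_report <- function(scaffolds, reference, fragments = NULL,
                            genes = NULL, min_score = 40, min_size = 500,
                            class_bounds = c(10000, 50000),
                            scaffold_floor = 95) {
  scafs <- if (inherits(scaffolds, "synthetic_scaffolds")) scaffolds$scaffolds
           else as_seqset(scaffolds)
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  genome_size <- sum(nchar(genome))
  used <- scafs[nchar(scafs) > scaffold_floor]
  if (is.null(fragments)) {
    fragments <- align_scaffolds(used, genome, min_score = min_score)
  }
  stats <- size_stats(scafs, floor_95 = scaffold_floor)
  contigs <- split_to_contigs(scafs)
  contig_lens <- nchar(contigs)
  contig_kept <- contig_lens[contig_lens > scaffold_floor]
  events <- classify_misarrangements(fragments, min_size = min_size)
  indels <- count_small_indels(fragments)
  gene_indels <- if (!is.null(genes)) count_small_indels(fragments, genes)
                 else c(n_insertions = NA_integer_, n_deletions = NA_integer_)
  cls <- coverage_by_class(fragments, genome, bounds = class_bounds)
  structure(list(
    size = stats,
    coverage_pct = genome_coverage(fragments, genome),
    r50 = r50(fragments, genome_size),
    ng50 = ng50(nchar(scafs), genome_size),
    class_coverage = cls,
    misarrangements = events,
    misarrangement_counts = c(
      misjoin = sum(events$kind == "misjoin"),
      inversion = sum(events$kind == "inversion"),
      deletion = sum(events$kind == "deletion"),
      insertion = sum(events$kind == "insertion")),
    deletion_total_kb = sum(events$size[events$kind == "deletion"]) / 1000,
    insertion_total_kb = sum(events$size[events$kind == "insertion"]) / 1000,
    small_indels = indels,
    gene_small_indels = gene_indels,
    n_contigs = sum(contig_lens > scaffold_floor),
    contig_n50 = if (length(contig_kept)) n50(contig_kept) else 0,
    scaffolding_ratio = scaffolding_ratio(
      max(1L, sum(contig_lens > scaffold_floor)),
      max(1L, sum(nchar(scafs) > scaffold_floor))),
    fragments = fragments,
    genome_size = genome_size
  ), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembly_report\n")
  cat(sprintf("  scaffolds >95 bp: %d (N50 %s bp, max %s bp)\n",
              x$size$n_scaffolds_95, format(x$size$n50, big.mark = ","),
              format(x$size$max, big.mark = ",")))
  cat(sprintf("  coverage: %.2f%%   R50: %s bp\n", x$coverage_pct,
              format(x$r50, big.mark = ",")))
  cat(sprintf("  misarrangements: %s\n",
              paste(names(x$misarrangement_counts),
                    x$misarrangement_counts, sep = "=", collapse = " ")))
  cat(sprintf("  contigs: %d (N50 %s bp), scaffolding ratio %.2f\n",
              x$n_contigs, format(x$contig_n50, big.mark = ","),
              x$scaffolding_ratio))
  invisible(x)
}
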