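# Per-gene reconstruction scoring and gene-cluster continuity.
#
# Each gene's genomic sequence (introns included) is locally aligned against
# the assembled scaffolds; segment pairs are deemed high-scoring (HSPs) when
# their Karlin-Altschul E-value is below a cutoff (default 1e-100). For each
# gene only the scaffold carrying the highest-scoring HSP is used: the
# fraction of gene bases inside qualifying HSPs on that scaffold, and the
# fraction of identical bases within them, are the reconstruction scores.
# A gene with no qualifying HSP on any scaffold is lost.

#' Karlin-Altschul E-value for an ungapped-scoring local alignment
#'
#' `E = K * m * n * exp(-lambda * S)`. Defaults are the ungapped values for
#' unit match/mismatch scoring on uniform-composition DNA: `lambda = ln 3`
#' (the solution of `0.25 e^lambda + 0.75 e^-lambda = 1`) and `K = 0.33`.
#' Downstream logic depends on threshold behaviour, not on absolute
#' E-values, so these constants are configurable but rarely worth changing.
#'
#' @param score Alignment score(s).
#' @param m Query (gene) length in bp.
#' @param n Search-space (total scaffold) length in bp.
#' @param lambda,K Karlin-Altschul constants.
#' @return E-value(s).
#' @export
karlin_evalue <- function(score, m, n, lambda = log(3), K = 0.33) {
  K * m * n * exp(-lambda * score)
}

#' Score gene reconstruction in assembled scaffolds
#'
#' @param reference A `synthetic_genome` (gene table and sequences taken from
#'   it), or a named character vector of gene sequences.
#' @param scaffolds Scaffold sequences (any form accepted by
#'   [align_scaffolds()]); scaffolds at or below `scaffold_floor` bp are
#'   excluded before searching.
#' @param genes Optional gene table when `reference` is raw sequences.
#' @param evalue_max HSP significance cutoff (default 1e-100).
#' @param lambda,K Karlin-Altschul constants (see [karlin_evalue()]).
#' @param scaffold_floor Minimum scaffold length searched (default 95 bp).
#' @return A `gene_recon` data frame with one row per gene: `gene_id`,
#'   `gene_len`, `best_scaffold`, `best_score`, `n_hsps` (qualifying HSPs on
#'   the best scaffold), `hsp_fraction`, `identity_fraction`, `lost`.
#'   All qualifying HSP placements (any scaffold) are attached as
#'   `attr(, "placements")`.
#' @export
evaluate_genes <- function(reference, scaffolds, genes = NULL,
                           evalue_max = 1e-100, lambda = log(3), K = 0.33,
                           scaffold_floor = 95) {
  gene_seqs <- if (inherits(reference, "synthetic_genome")) {
    gene_sequences(reference, genes)
  } else {
    as_seqset(reference)
  }
  scafs <- if (inherits(scaffolds, "synthetic_scaffolds")) scaffolds$scaffolds
           else as_seqset(scaffolds)
  scafs <- scafs[nchar(scafs) > scaffold_floor]
  if (!length(gene_seqs)) stopf("no genes to evaluate")
  if (any(nchar(gene_seqs) == 0)) stopf("empty gene sequence")
  n_space <- sum(nchar(scafs))

  res <- .anchor_align(gene_seqs, scafs, min_score = 20, stride = 10L)
  hits <- res$fragments
  if (nrow(hits)) {
    hits$evalue <- karlin_evalue(hits$score, nchar(gene_seqs)[
      match(hits$query_id, names(gene_seqs))], n_space, lambda, K)
    hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  } else {
    hits$evalue <- numeric()
  }

  rows <- lapply(names(gene_seqs), function(gid) {
    glen <- nchar(gene_seqs[[gid]])
    h <- hits[hits$query_id == gid, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(gene_id = gid, gene_len = glen,
                        best_scaffold = NA_character_, best_score = 0,
                        n_hsps = 0L, hsp_fraction = 0, identity_fraction = 0,
                        lost = TRUE, stringsAsFactors = FALSE))
    }
    best <- h$subject_id[which.max(h$score)]
    hb <- h[h$subject_id == best, , drop = FALSE]
    cov <- IRanges::reduce(IRanges::IRanges(hb$q_start, hb$q_end))
    hsp_frac <- min(1, sum(IRanges::width(cov)) / glen)
    # identity: matches within HSPs, overlaps resolved in favour of the
    # higher-scoring HSP (its matches are kept; lower-scoring overlap
    # contributions are scaled out by the trimmed width)
    hb <- hb[order(-hb$score), , drop = FALSE]
    claimed <- IRanges::IRanges()
    ident_bases <- 0
    for (i in seq_len(nrow(hb))) {
      iv <- IRanges::IRanges(hb$q_start[i], hb$q_end[i])
      new <- IRanges::setdiff(iv, claimed)
      kept <- sum(IRanges::width(new))
      w <- IRanges::width(iv)
      ident_bases <- ident_bases + hb$n_match[i] * kept / w
      claimed <- IRanges::reduce(IRanges::union(claimed, iv))
    }
    data.frame(gene_id = gid, gene_len = glen, best_scaffold = best,
               best_score = max(hb$score), n_hsps = nrow(hb),
               hsp_fraction = hsp_frac,
               identity_fraction = min(hsp_frac, ident_bases / glen),
               lost = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_recon", "data.frame")
  placements <- hits
  names(placements)[names(placements) == "query_id"] <- "gene_id"
  names(placements)[names(placements) == "subject_id"] <- "scaffold_id"
  attr(out, "placements") <- placements
  out
}

#' Aggregate gene reconstruction results
#'
#' Base-weighted mean HSP and identity percentages (genes weighted by their
#' length, matching a "percentage of gene bases" reading) plus the lost-gene
#' count, over all genes or a named subset.
#'
#' @param results A `gene_recon` data frame from [evaluate_genes()].
#' @param subset Optional character vector of gene ids (e.g. the PKS/NRPS
#'   list) to aggregate over.
#' @return Named numeric vector: `hsp_pct`, `identity_pct`, `n_lost`,
#'   `n_genes`.
#' @export
summarize_genes <- function(results, subset = NULL) {
  if (!is.null(subset)) {
    missing <- setdiff(subset, results$gene_id)
    if (length(missing)) stopf("unknown gene id '%s'", missing[1])
    results <- results[results$gene_id %in% subset, , drop = FALSE]
  }
  w <- results$gene_len
  c(hsp_pct = 100 * sum(results$hsp_fraction * w) / sum(w),
    identity_pct = 100 * sum(results$identity_fraction * w) / sum(w),
    n_lost = sum(results$lost),
    n_genes = nrow(results))
}

#' Test gene-cluster continuity in assembled scaffolds
#'
#' A cluster is continuous when every member gene has a qualifying HSP on
#' one and the same scaffold, the genes appear there in reference order
#' (a whole-cluster reversal is allowed, since scaffold strandedness is
#' arbitrary), and no gene from outside the cluster is placed between them
#' on that scaffold.
#'
#' @param cluster_genes Character vector of gene ids in reference order.
#' @param results A `gene_recon` data frame from [evaluate_genes()] covering
#'   at least the cluster genes (interleaving is checked against every gene
#'   present in `results`).
#' @return `TRUE` or `FALSE`, with the failure reason in `attr(, "reason")`.
#' @export
cluster_continuity <- function(cluster_genes, results) {
  stopifnot(length(cluster_genes) >= 1)
  missing <- setdiff(cluster_genes, results$gene_id)
  if (length(missing)) stopf("unknown gene id '%s'", missing[1])
  pl <- attr(results, "placements")
  if (is.null(pl)) stopf("results carry no HSP placements")
  fail <- function(reason) structure(FALSE, reason = reason)

  sub <- results[match(cluster_genes, results$gene_id), , drop = FALSE]
  if (any(sub$lost)) return(fail("lost gene(s) in cluster"))
  # scaffolds carrying qualifying HSPs for every cluster gene
  by_gene <- lapply(cluster_genes, function(g) {
    unique(pl$scaffold_id[pl$gene_id == g])
  })
  common <- Reduce(intersect, by_gene)
  if (!length(common)) return(fail("cluster split across scaffolds"))

  for (scaf in common) {
    # top-scoring HSP midpoint of each cluster gene on this scaffold
    mid <- vapply(cluster_genes, function(g) {
      h <- pl[pl$gene_id == g & pl$scaffold_id == scaf, , drop = FALSE]
      h <- h[which.max(h$score), ]
      (h$s_start + h$s_end) / 2
    }, numeric(1))
    increasing <- all(diff(mid) > 0)
    decreasing <- all(diff(mid) < 0)
    if (!increasing && !decreasing) next
    # interleaved foreign placement between consecutive cluster genes?
    others <- setdiff(unique(results$gene_id[!results$lost]), cluster_genes)
    lo <- min(mid)
    hi <- max(mid)
    interleaved <- FALSE
    for (g in others) {
      h <- pl[pl$gene_id == g & pl$scaffold_id == scaf, , drop = FALSE]
      if (!nrow(h)) next
      h <- h[which.max(h$score), ]
      # only the gene's best placement overall counts as its location
      if (!identical(results$best_scaffold[results$gene_id == g], scaf)) next
      m <- (h$s_start + h$s_end) / 2
      if (m > lo && m < hi) {
        interleaved <- TRUE
        break
      }
    }
    if (!interleaved) return(TRUE)
  }
  fail("gene order not preserved on any shared scaffold")
}

#' Continuity of every cluster
#'
#' @param clusters Named list of ordered gene-id vectors.
#' @param results A `gene_recon` data frame from [evaluate_genes()].
#' @return Named logical vector, one element per cluster.
#' @export
clusters_continuity <- function(clusters, results) {
  vapply(clusters, function(g) isTRUE(cluster_continuity(g, results)),
         logical(1))
}
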