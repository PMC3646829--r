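# Scaffold-to-reference fragment alignment.
#
# The aligner follows the seed-and-extend design of reference aligners used
# for assembly assessment: exact k-mer anchors are collected on both strands,
# grouped into co-diagonal chains (tolerating small diagonal drift from
# indels), chains are extended to maximal boundaries, and the inter-anchor
# pieces are resolved exactly — by direct comparison when lengths agree and
# by an affine-gap dynamic-programming alignment (Biostrings) when they do
# not. Each maximal chain becomes one AlignmentFragment; alignments are not
# chained across events, so a scaffold crossing a misjoin, inversion or large
# indel yields several fragments, which is exactly what the misarrangement
# classifier consumes.
#
# Scoring: match +1, mismatch -1, gap of length L costs 2 + L (open 2,
# extend 1). Fragments are kept when score > min_score (default 40, the
# conventional cutoff for significant homology in unit-score local
# alignment).

# match +1, mismatch -1; N matches nothing (not even N)
#' @noRd
.aln_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      b <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(b, b))
      mm["A", "A"] <- mm["C", "C"] <- mm["G", "G"] <- mm["T", "T"] <- 1
      m <<- mm
    }
    m
  }
})

#' Optimal local alignment of two short sequences
#'
#' Smith-Waterman local alignment under the package scoring scheme (match
#' +1, mismatch -1, gap open 2, gap extend 1 per base; a length-L gap costs
#' 2 + L). Intended for short sequences (the dynamic programme is quadratic);
#' [align_scaffolds()] is the scalable entry point.
#'
#' @param query,subject Character scalars over A/C/G/T.
#' @return List with `score` and the aligned `query_range`/`subject_range`
#'   (1-based closed), plus `n_match`, `n_mismatch`, `n_ins` (bases in query
#'   absent from subject), `n_del`.
#' @export
local_align <- function(query, subject) {
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = .aln_matrix(),
    gapOpening = 2, gapExtension = 1)
  list(
    score = Biostrings::score(pa),
    query_range = c(Biostrings::start(Biostrings::pattern(pa)),
                    Biostrings::end(Biostrings::pattern(pa))),
    subject_range = c(Biostrings::start(Biostrings::subject(pa)),
                      Biostrings::end(Biostrings::subject(pa))),
    n_match = Biostrings::nmatch(pa),
    n_mismatch = Biostrings::nmismatch(pa),
    n_ins = sum(Biostrings::width(Biostrings::insertion(pa))[[1]]),
    n_del = sum(Biostrings::width(Biostrings::deletion(pa))[[1]])
  )
}

# Global (end-to-end) alignment stats of two short pieces. Returns counts of
# matches, mismatches, and per-gap details. One side may be empty.
#' @noRd
.piece_stats <- function(q, s) {
  lq <- nchar(q)
  ls <- nchar(s)
  if (lq == 0 && ls == 0) {
    return(list(n_match = 0L, n_mismatch = 0L,
                ins = integer(), del = integer()))
  }
  if (ls == 0) return(list(n_match = 0L, n_mismatch = 0L,
                           ins = lq, del = integer()))
  if (lq == 0) return(list(n_match = 0L, n_mismatch = 0L,
                           ins = integer(), del = ls))
  if (q == s) {
    return(list(n_match = lq, n_mismatch = 0L, ins = integer(),
                del = integer()))
  }
  if (lq == ls) {
    qb <- strsplit(q, "")[[1]]
    sb <- strsplit(s, "")[[1]]
    mm <- sum(qb != sb)
    # substitution-only interpretation unless wildly divergent (which hints
    # at compensating indels); then fall through to the DP
    if (mm / lq <= 0.3 || lq < 8) {
      return(list(n_match = lq - mm, n_mismatch = as.integer(mm),
                  ins = integer(), del = integer()))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    q, s, type = "global", substitutionMatrix = .aln_matrix(),
    gapOpening = 2, gapExtension = 1)
  # derive counts from the gapped alignment strings: indel() drops terminal
  # gaps, which end-to-end piece alignment must keep
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap_p <- ap == "-"
  gap_s <- as_ == "-"
  ins_runs <- rle(gap_s)
  del_runs <- rle(gap_p)
  list(
    n_match = sum(!gap_p & !gap_s & ap == as_),
    n_mismatch = sum(!gap_p & !gap_s & ap != as_),
    ins = ins_runs$lengths[ins_runs$values],
    del = del_runs$lengths[del_runs$values]
  )
}

# Anchor collection: exact k-mer matches of query k-mers (taken every
# `stride` bp, plus the terminal k-mer) against one subject strand.
# Returns data.frame(qpos, spos), 1-based.
#' @noRd
.collect_anchors <- function(pd, qpos, subject, max_hits = 20L) {
  m <- Biostrings::matchPDict(pd, subject)
  st <- Biostrings::startIndex(m)
  counts <- lengths(st)
  keep <- counts > 0L & counts <= max_hits
  if (!any(keep)) return(data.frame(qpos = integer(), spos = integer()))
  data.frame(
    qpos = rep(qpos[keep], counts[keep]),
    spos = unlist(st[keep], use.names = FALSE)
  )
}

# Group anchors of one (subject, strand) into chains: split on consecutive
# diagonal jumps > band, then on query gaps > max_gap. Returns a list of
# data.frames (qpos, spos), each sorted by qpos with monotone non-overlapping
# anchors.
#' @noRd
.chain_anchors <- function(anchors, k, band, max_gap) {
  if (!nrow(anchors)) return(list())
  anchors$diag <- anchors$spos - anchors$qpos
  anchors <- anchors[order(anchors$diag, anchors$qpos), ]
  grp <- cumsum(c(1L, diff(anchors$diag) > band))
  chains <- list()
  for (g in split(anchors, grp)) {
    g <- g[order(g$qpos, g$spos), ]
    sub <- cumsum(c(1L, diff(g$qpos) > max_gap))
    for (h in split(g, sub)) {
      # enforce strictly increasing, non-overlapping anchor set
      keep <- integer()
      last_q <- -Inf
      last_s <- -Inf
      for (i in seq_len(nrow(h))) {
        if (h$qpos[i] >= last_q + k && h$spos[i] >= last_s + k) {
          keep <- c(keep, i)
          last_q <- h$qpos[i]
          last_s <- h$spos[i]
        }
      }
      if (length(keep)) chains[[length(chains) + 1L]] <- h[keep, , drop = FALSE]
    }
  }
  chains
}

# Greedy exact-match extension of [qs,qe]/[ss,se] against sequence ends.
#' @noRd
.extend_ends <- function(qseq, sseq, qs, qe, ss, se) {
  while (qs > 1L && ss > 1L &&
         substr(qseq, qs - 1L, qs - 1L) == substr(sseq, ss - 1L, ss - 1L) &&
         substr(qseq, qs - 1L, qs - 1L) != "N") {
    qs <- qs - 1L
    ss <- ss - 1L
  }
  lq <- nchar(qseq)
  ls <- nchar(sseq)
  while (qe < lq && se < ls &&
         substr(qseq, qe + 1L, qe + 1L) == substr(sseq, se + 1L, se + 1L) &&
         substr(qseq, qe + 1L, qe + 1L) != "N") {
    qe <- qe + 1L
    se <- se + 1L
  }
  c(qs, qe, ss, se)
}

# Core engine: align each query against each subject on both strands.
# Returns list(fragments, indels) in *query/subject* naming; subject
# coordinates are on the forward strand.
#' @noRd
.anchor_align <- function(queries, subjects, min_score = 40, k = 21L,
                          stride = 25L, band = 200L, max_gap = 500L) {
  queries <- as_seqset(queries)
  subjects <- as_seqset(subjects)
  if (!length(subjects) || sum(nchar(subjects)) == 0) {
    stopf("empty subject sequence set")
  }
  sub_fwd <- lapply(subjects, Biostrings::DNAString)
  sub_rev <- lapply(subjects, function(s) {
    Biostrings::reverseComplement(Biostrings::DNAString(s))
  })
  frags <- list()
  indels <- list()

  for (qname in names(queries)) {
    qseq <- queries[[qname]]
    L <- nchar(qseq)
    if (L < k) next
    qpos <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    kmers <- substring(qseq, qpos, qpos + k - 1L)
    ok <- grepl("^[ACGT]+$", kmers)
    if (!any(ok)) next
    qpos <- qpos[ok]
    kmers <- kmers[ok]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))

    for (sname in names(subjects)) {
      slen <- nchar(subjects[[sname]])
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") sub_fwd[[sname]] else sub_rev[[sname]]
        sseq <- if (strand == "+") subjects[[sname]]
                else as.character(subj)
        anchors <- .collect_anchors(pd, qpos, subj)
        chains <- .chain_anchors(anchors, k, band, max_gap)
        for (ch in chains) {
          res <- .score_chain(ch, qseq, sseq, k)
          if (res$score <= min_score) next
          # convert subject coords to forward strand
          if (strand == "+") {
            rs <- res$ss
            re <- res$se
          } else {
            rs <- slen - res$se + 1L
            re <- slen - res$ss + 1L
          }
          frags[[length(frags) + 1L]] <- data.frame(
            query_id = qname, q_start = res$qs, q_end = res$qe,
            subject_id = sname, s_start = rs, s_end = re, strand = strand,
            score = res$score, n_match = res$n_match,
            n_mismatch = res$n_mismatch, n_ins = res$n_ins,
            n_del = res$n_del, stringsAsFactors = FALSE)
          if (nrow(res$indels)) {
            tab <- res$indels
            tab$s_pos <- if (strand == "+") tab$s_pos
                         else slen - tab$s_pos + 1L
            tab$query_id <- qname
            tab$subject_id <- sname
            indels[[length(indels) + 1L]] <- tab
          }
        }
      }
    }
  }
  frags <- if (length(frags)) do.call(rbind, frags) else data.frame(
    query_id = character(), q_start = integer(), q_end = integer(),
    subject_id = character(), s_start = integer(), s_end = integer(),
    strand = character(), score = numeric(), n_match = integer(),
    n_mismatch = integer(), n_ins = integer(), n_del = integer(),
    stringsAsFactors = FALSE)
  indels <- if (length(indels)) do.call(rbind, indels) else data.frame(
    s_pos = integer(), kind = character(), len = integer(),
    query_id = character(), subject_id = character(), stringsAsFactors = FALSE)
  # drop exact duplicates (multi-hit k-mers can seed the same chain twice)
  if (nrow(frags)) {
    key <- with(frags, paste(query_id, q_start, q_end, subject_id, s_start,
                             s_end, strand))
    dup <- duplicated(key)
    frags <- frags[!dup, , drop = FALSE]
    frags <- frags[order(frags$query_id, frags$q_start, frags$s_start), ,
                   drop = FALSE]
    rownames(frags) <- NULL
  }
  list(fragments = frags, indels = indels)
}

# Score one chain: extend ends, resolve inter-anchor pieces, accumulate
# match/mismatch/indel counts and the affine score.
#' @noRd
.score_chain <- function(ch, qseq, sseq, k) {
  n <- nrow(ch)
  ext <- .extend_ends(qseq, sseq, ch$qpos[1], ch$qpos[n] + k - 1L,
                      ch$spos[1], ch$spos[n] + k - 1L)
  qs <- ext[1]; qe <- ext[2]; ss <- ext[3]; se <- ext[4]
  n_match <- (ch$qpos[1] - qs) + (qe - (ch$qpos[n] + k - 1L)) + n * k
  # overlap correction: consecutive anchors are non-overlapping by
  # construction, so each contributes k matched bases
  n_mismatch <- 0L
  ins <- integer()
  del <- integer()
  ind_pos <- integer()
  ind_kind <- character()
  ind_len <- integer()
  if (n > 1) {
    pq_start <- ch$qpos[-n] + k
    pq_end <- ch$qpos[-1] - 1L
    ps_start <- ch$spos[-n] + k
    ps_end <- ch$spos[-1] - 1L
    qpieces <- substring(qseq, pq_start, pq_end)
    spieces <- substring(sseq, ps_start, ps_end)
    qpieces[pq_end < pq_start] <- ""
    spieces[ps_end < ps_start] <- ""
    for (i in seq_len(n - 1L)) {
      st <- .piece_stats(qpieces[i], spieces[i])
      n_match <- n_match + st$n_match
      n_mismatch <- n_mismatch + st$n_mismatch
      ins <- c(ins, st$ins)
      del <- c(del, st$del)
      if (length(st$ins)) {
        ind_pos <- c(ind_pos, rep(ps_start[i], length(st$ins)))
        ind_kind <- c(ind_kind, rep("insertion", length(st$ins)))
        ind_len <- c(ind_len, st$ins)
      }
      if (length(st$del)) {
        ind_pos <- c(ind_pos, rep(ps_start[i], length(st$del)))
        ind_kind <- c(ind_kind, rep("deletion", length(st$del)))
        ind_len <- c(ind_len, st$del)
      }
    }
  }
  score <- n_match - n_mismatch - sum(2L + ins) - sum(2L + del)
  list(qs = qs, qe = qe, ss = ss, se = se, score = score,
       n_match = as.integer(n_match), n_mismatch = as.integer(n_mismatch),
       n_ins = sum(ins), n_del = sum(del),
       indels = data.frame(s_pos = ind_pos, kind = ind_kind, len = ind_len,
                           stringsAsFactors = FALSE))
}

#' Align scaffolds to a reference genome
#'
#' Produces scored local alignment fragments of each scaffold against the
#' reference, searching both strands. Runs of N in scaffolds never match.
#' Only fragments with `score > min_score` are returned, sorted by scaffold
#' and scaffold coordinate.
#'
#' @param scaffolds,reference Named character vectors, `DNAStringSet`s, FASTA
#'   paths, or (for `reference`) a `synthetic_genome`.
#' @param min_score Score threshold; fragments must exceed it (default 40).
#' @param k Anchor k-mer length.
#' @param stride Distance between sampled anchor k-mers on the scaffold.
#' @param band Maximum diagonal drift within one fragment (accommodates small
#'   indels).
#' @param max_gap Maximum unanchored scaffold stretch within one fragment.
#' @return An AlignmentFragment data frame with columns `scaffold_id`,
#'   `scaffold_start`, `scaffold_end`, `ref_chrom`, `ref_start`, `ref_end`
#'   (1-based closed, forward-strand reference coordinates), `strand`,
#'   `score`, `n_match`, `n_mismatch`, `n_ins` (bases present in the scaffold
#'   but not the reference), `n_del`. Per-indel detail (reference position,
#'   kind, length) is attached as `attr(, "indels")`.
#' @export
align_scaffolds <- function(scaffolds, reference, min_score = 40, k = 21L,
                            stride = 25L, band = 200L, max_gap = 500L) {
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  scafs <- if (inherits(scaffolds, "synthetic_scaffolds")) scaffolds$scaffolds
           else as_seqset(scaffolds)
  res <- .anchor_align(scafs, genome, min_score = min_score, k = k,
                       stride = stride, band = band, max_gap = max_gap)
  fr <- res$fragments
  names(fr)[names(fr) == "query_id"] <- "scaffold_id"
  names(fr)[names(fr) == "q_start"] <- "scaffold_start"
  names(fr)[names(fr) == "q_end"] <- "scaffold_end"
  names(fr)[names(fr) == "subject_id"] <- "ref_chrom"
  names(fr)[names(fr) == "s_start"] <- "ref_start"
  names(fr)[names(fr) == "s_end"] <- "ref_end"
  ind <- res$indels
  ind <- data.frame(scaffold_id = ind$query_id, ref_chrom = ind$subject_id,
                    ref_pos = ind$s_pos, kind = ind$kind, len = ind$len,
                    stringsAsFactors = FALSE)
  attr(fr, "indels") <- ind
  fr
}

#' Load alignment fragments from a PAF file
#'
#' Accepts minimap2/LAST-style PAF (12 mandatory columns plus optional typed
#' tags). The query is taken as the scaffold. PAF's 0-based half-open
#' coordinates are converted to the package's 1-based closed convention.
#' Scores come from the `AS:i` tag when present, otherwise the number of
#' matching bases (column 10). Indel counts (and per-indel detail) are
#' derived from the `cg:Z` CIGAR tag when present.
#'
#' @param path PAF path.
#' @param min_score Records with score <= `min_score` are dropped (a message
#'   reports how many).
#' @return AlignmentFragment data frame as from [align_scaffolds()].
#' @export
load_fragments <- function(path, min_score = 40) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  frags <- list()
  indels <- list()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      stopf("malformed PAF line %d: %d columns (12 required)", ln, length(f))
    }
    if (!f[5] %in% c("+", "-")) stopf("malformed PAF line %d: bad strand", ln)
    qs <- as.integer(f[3]) + 1L
    qe <- as.integer(f[4])
    ts <- as.integer(f[8]) + 1L
    te <- as.integer(f[9])
    nmatch <- as.integer(f[10])
    if (any(is.na(c(qs, qe, ts, te, nmatch))) || qe < qs || te < ts) {
      stopf("malformed PAF line %d: bad coordinates", ln)
    }
    tags <- if (length(f) > 12) f[13:length(f)] else character()
    as_tag <- grep("^AS:i:", tags, value = TRUE)
    score <- if (length(as_tag)) as.numeric(sub("^AS:i:", "", as_tag[1]))
             else nmatch
    cg <- grep("^cg:Z:", tags, value = TRUE)
    n_ins <- 0L
    n_del <- 0L
    if (length(cg)) {
      ops <- gregexpr("\\d+[MIDNSHP=X]", sub("^cg:Z:", "", cg[1]))[[1]]
      cig <- regmatches(sub("^cg:Z:", "", cg[1]), list(ops))[[1]]
      lens_ <- as.integer(sub("[MIDNSHP=X]$", "", cig))
      ops_ <- sub("^\\d+", "", cig)
      rpos <- ts
      for (i in seq_along(ops_)) {
        if (ops_[i] %in% c("M", "=", "X")) {
          rpos <- rpos + lens_[i]
        } else if (ops_[i] == "I") {
          n_ins <- n_ins + lens_[i]
          indels[[length(indels) + 1L]] <- data.frame(
            scaffold_id = f[1], ref_chrom = f[6], ref_pos = rpos,
            kind = "insertion", len = lens_[i], stringsAsFactors = FALSE)
        } else if (ops_[i] %in% c("D", "N")) {
          n_del <- n_del + lens_[i]
          indels[[length(indels) + 1L]] <- data.frame(
            scaffold_id = f[1], ref_chrom = f[6], ref_pos = rpos,
            kind = "deletion", len = lens_[i], stringsAsFactors = FALSE)
          rpos <- rpos + lens_[i]
        }
      }
    }
    aln_len <- as.integer(f[11])
    frags[[ln]] <- data.frame(
      scaffold_id = f[1], scaffold_start = qs, scaffold_end = qe,
      ref_chrom = f[6], ref_start = ts, ref_end = te, strand = f[5],
      score = score, n_match = nmatch,
      n_mismatch = max(0L, aln_len - nmatch - n_ins - n_del),
      n_ins = n_ins, n_del = n_del, stringsAsFactors = FALSE)
  }
  fr <- if (length(frags)) do.call(rbind, frags) else empty_fragments()
  dropped <- sum(fr$score <= min_score)
  if (dropped) message(sprintf("dropped %d fragment(s) with score <= %g",
                               dropped, min_score))
  fr <- fr[fr$score > min_score, , drop = FALSE]
  fr <- fr[order(fr$scaffold_id, fr$scaffold_start), , drop = FALSE]
  rownames(fr) <- NULL
  attr(fr, "indels") <- if (length(indels)) do.call(rbind, indels)
                        else empty_indels()
  fr
}

#' Write alignment fragments as TSV or PAF
#'
#' @param fragments AlignmentFragment data frame.
#' @param path Output path.
#' @param format "tsv" (all columns) or "paf" (coordinates converted to
#'   0-based half-open; score in the `AS:i` tag).
#' @param scaffold_lengths,ref_lengths Named lengths, required for PAF.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path, format = c("tsv", "paf"),
                            scaffold_lengths = NULL, ref_lengths = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(scaffold_lengths) || is.null(ref_lengths)) {
      stopf("PAF output needs scaffold_lengths and ref_lengths")
    }
    aln_len <- fragments$n_match + fragments$n_mismatch + fragments$n_ins +
      fragments$n_del
    lines <- sprintf(
      "%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255\tAS:i:%d",
      fragments$scaffold_id,
      as.integer(scaffold_lengths[fragments$scaffold_id]),
      fragments$scaffold_start - 1L, fragments$scaffold_end,
      fragments$strand, fragments$ref_chrom,
      as.integer(ref_lengths[fragments$ref_chrom]),
      fragments$ref_start - 1L, fragments$ref_end,
      fragments$n_match, aln_len, as.integer(round(fragments$score)))
    writeLines(lines, path)
  }
  invisible(path)
}
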