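# Error-bearing scaffold generator with an exact truth table.
#
# Scaffolds are concatenations of reference segments transformed by induced
# events. Event kinds follow the misarrangement taxonomy used downstream:
#   misjoin   - a junction joining segments from two different chromosomes;
#   inversion - a segment reverse-complemented in place;
#   deletion  - a run of reference sequence missing from the scaffold;
#   insertion - novel (random) sequence present only in the scaffold.
# N-gap runs (replacing an equal span of reference, as an assembler gap
# would) can be sprinkled in; they are *not* events and must not be reported
# by the classifier. Small indels (1-5 bp) model base-level assembly errors.
# Every induced event is recorded in the truth table with exact reference
# coordinates, including a below-threshold class used to exercise the 500 bp
# counting rule.

#' Configuration for the scaffold error generator
#'
#' Event numbers are explicit counts (not rates) so that the truth table is
#' fully determined by the seed. Countable events draw sizes from
#' `size_range` (all > 500 bp by default); `n_subthreshold` additional events
#' (cycling through inversion/deletion/insertion) draw from
#' `sub_size_range` (<= 500 bp) to test the counting threshold. Event sites
#' are separated by at least `min_separation` bp of clean sequence plus the
#' maximum event size.
#'
#' @param n_misjoin,n_inversion,n_deletion,n_insertion Event counts.
#' @param size_range Size range (bp) for countable events (min > 500).
#' @param n_subthreshold Number of below-threshold events.
#' @param sub_size_range Size range (bp) for below-threshold events (max <=
#'   500).
#' @param small_indel_rate Per-bp probability of a 1-5 bp indel in scaffold
#'   sequence.
#' @param n_gap_run Length (bp) of each N-gap run.
#' @param gaps_per_chrom Number of N-gap runs per chromosome (replacing an
#'   equal reference span; not events).
#' @param min_separation Minimum clean separation between event sites (bp).
#' @param end_buffer Event-free buffer at chromosome ends (bp).
#' @param seed Integer seed.
#' @return A `scaffold_error_config` list.
#' @export
scaffold_error_config <- function(n_misjoin = 0L, n_inversion = 0L,
                                  n_deletion = 0L, n_insertion = 0L,
                                  size_range = c(600L, 5000L),
                                  n_subthreshold = 0L,
                                  sub_size_range = c(50L, 400L),
                                  small_indel_rate = 0,
                                  n_gap_run = 100L,
                                  gaps_per_chrom = 0L,
                                  min_separation = 2000L,
                                  end_buffer = 10000L,
                                  seed = 1L) {
  stopifnot(n_misjoin >= 0, n_inversion >= 0, n_deletion >= 0,
            n_insertion >= 0, n_subthreshold >= 0,
            size_range[1] > 500, size_range[1] <= size_range[2],
            sub_size_range[2] <= 500, sub_size_range[1] >= 1,
            small_indel_rate >= 0, small_indel_rate < 1,
            n_gap_run >= 0, gaps_per_chrom >= 0,
            min_separation > 0, end_buffer > 0)
  structure(list(
    n_misjoin = as.integer(n_misjoin), n_inversion = as.integer(n_inversion),
    n_deletion = as.integer(n_deletion), n_insertion = as.integer(n_insertion),
    size_range = as.integer(size_range),
    n_subthreshold = as.integer(n_subthreshold),
    sub_size_range = as.integer(sub_size_range),
    small_indel_rate = small_indel_rate,
    n_gap_run = as.integer(n_gap_run),
    gaps_per_chrom = as.integer(gaps_per_chrom),
    min_separation = as.integer(min_separation),
    end_buffer = as.integer(end_buffer),
    seed = as.integer(seed)
  ), class = "scaffold_error_config")
}

# Sample n positions in [lo, hi] pairwise separated by >= min_dist, uniform
# given the separation constraint: draw order statistics on the slack and
# add fixed offsets (always succeeds when the interval is long enough).
#' @noRd
sample_separated <- function(n, lo, hi, min_dist) {
  if (n == 0) return(integer())
  slack <- (hi - lo) - (n - 1) * min_dist
  if (slack < 0) {
    stopf("cannot place %d sites separated by %d bp in [%d, %d]",
          n, min_dist, lo, hi)
  }
  u <- sort(runif(n, 0, slack))
  as.integer(floor(lo + u + (seq_len(n) - 1) * min_dist))
}

#' Simulate error-bearing scaffolds from a reference
#'
#' Induces the configured events into per-chromosome scaffold plans, performs
#' misjoin cut-and-cross-join operations between chromosomes, then assembles
#' sequences (applying small indels and N-gap runs). Zero event counts give
#' scaffolds identical to the chromosomes and an empty truth table.
#'
#' @param reference A `synthetic_genome`, named character vector,
#'   `DNAStringSet`, or FASTA path.
#' @param config A [scaffold_error_config()].
#' @return A `synthetic_scaffolds` list with elements:
#'   * `scaffolds`: named character vector of scaffold sequences;
#'   * `truth`: data frame of induced events (`kind`, `scaffold_id`, `chrom`,
#'     `ref_pos`, `chrom2`, `ref_pos2`, `size`, `countable`); for misjoins
#'     `chrom`/`ref_pos` and `chrom2`/`ref_pos2` are the two joined loci and
#'     `size` is `NA`;
#'   * `segments`: data frame mapping scaffold intervals back to reference
#'     intervals (`scaffold_id`, `scaf_start`, `scaf_end`, `kind`, `chrom`,
#'     `ref_start`, `ref_end`, `strand`);
#'   * `small_indels`: data frame of induced small indels.
#' @export
simulate_scaffolds <- function(reference, config = scaffold_error_config()) {
  stopifnot(inherits(config, "scaffold_error_config"))
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  nch <- length(genome)
  chrom_names <- names(genome)
  lens <- nchar(genome)

  with_seed(config$seed, {
    # ---- plan events -----------------------------------------------------
    sub_kinds <- rep_len(c("inversion", "deletion", "insertion"),
                         config$n_subthreshold)
    events <- data.frame(
      kind = c(rep("inversion", config$n_inversion),
               rep("deletion", config$n_deletion),
               rep("insertion", config$n_insertion),
               sub_kinds,
               rep("gap", config$gaps_per_chrom * nch),
               rep("cut", 2L * config$n_misjoin)),
      stringsAsFactors = FALSE
    )
    n_ev <- nrow(events)
    if (n_ev > 0) {
      events$size <- 0L
      countable <- events$kind %in% c("inversion", "deletion", "insertion") &
        !seq_len(n_ev) %in% seq(config$n_inversion + config$n_deletion +
                                config$n_insertion + 1L,
                                length.out = config$n_subthreshold)
      big <- which(countable)
      sub <- which(events$kind %in% c("inversion", "deletion", "insertion") &
                   !countable)
      events$size[big] <- as.integer(floor(runif(
        length(big), config$size_range[1], config$size_range[2] + 1)))
      events$size[sub] <- as.integer(floor(runif(
        length(sub), config$sub_size_range[1], config$sub_size_range[2] + 1)))
      events$size[events$kind == "gap"] <- config$n_gap_run
      events$countable <- countable

      # misjoin chromosome pairs: source chrom index < target chrom index so
      # the part-successor graph is acyclic
      if (config$n_misjoin > 0 && nch < 2) {
        stopf("misjoins require at least 2 chromosomes")
      }
      mj_pairs <- lapply(seq_len(config$n_misjoin), function(j) {
        sort(sample.int(nch, 2))
      })
      cut_rows <- which(events$kind == "cut")
      events$misjoin_id <- NA_integer_
      events$chrom_idx <- NA_integer_
      for (j in seq_len(config$n_misjoin)) {
        r <- cut_rows[c(2L * j - 1L, 2L * j)]
        events$misjoin_id[r] <- j
        events$chrom_idx[r] <- mj_pairs[[j]]
      }
      # gaps assigned round-robin; other events proportional to length
      gap_rows <- which(events$kind == "gap")
      events$chrom_idx[gap_rows] <- rep(seq_len(nch),
                                        each = config$gaps_per_chrom)
      todo <- which(is.na(events$chrom_idx))
      events$chrom_idx[todo] <- sample.int(nch, length(todo), replace = TRUE,
                                           prob = lens)

      # positions: separated within each chromosome
      sep <- config$min_separation + max(events$size, config$n_gap_run, 1L)
      events$pos <- NA_integer_
      for (i in seq_len(nch)) {
        rows <- which(events$chrom_idx == i)
        if (!length(rows)) next
        p <- sample_separated(length(rows), config$end_buffer,
                              lens[i] - config$end_buffer, sep)
        events$pos[rows] <- p[sample.int(length(p))]
      }
    } else {
      events <- data.frame(kind = character(), size = integer(),
                           countable = logical(), misjoin_id = integer(),
                           chrom_idx = integer(), pos = integer(),
                           stringsAsFactors = FALSE)
    }

    # ---- build per-chromosome piece plans --------------------------------
    # piece: list(kind = ref|ins|gap, chrom, start, end, strand, len)
    plans <- list()      # list of part plans; part = list of pieces
    part_meta <- list()  # (chrom_idx, part_index, begins_at_cut misjoin id,
                         #  ends_at_cut misjoin id)
    truth <- list()
    for (i in seq_len(nch)) {
      ev <- events[events$chrom_idx %in% i, , drop = FALSE]
      ev <- ev[order(ev$pos), , drop = FALSE]
      cur <- 1L
      part <- list()
      part_index <- 1L
      begins_cut <- NA_integer_
      flush_ref <- function(upto) {
        if (upto >= cur) {
          part[[length(part) + 1L]] <<- list(
            kind = "ref", chrom = chrom_names[i], start = cur, end = upto,
            strand = "+", len = upto - cur + 1L)
        }
      }
      for (r in seq_len(nrow(ev))) {
        kind <- ev$kind[r]
        pos <- ev$pos[r]
        size <- ev$size[r]
        if (kind == "cut") {
          flush_ref(pos - 1L)
          plans[[length(plans) + 1L]] <- part
          part_meta[[length(part_meta) + 1L]] <- list(
            chrom_idx = i, part_index = part_index,
            begins_cut = begins_cut, ends_cut = ev$misjoin_id[r])
          part <- list()
          part_index <- part_index + 1L
          begins_cut <- ev$misjoin_id[r]
          cur <- pos
        } else if (kind == "deletion") {
          flush_ref(pos - 1L)
          cur <- pos + size
        } else if (kind == "insertion") {
          flush_ref(pos - 1L)
          part[[length(part) + 1L]] <- list(
            kind = "ins", chrom = NA_character_, start = NA_integer_,
            end = NA_integer_, strand = "+", len = size)
          cur <- pos
        } else if (kind == "inversion") {
          flush_ref(pos - 1L)
          part[[length(part) + 1L]] <- list(
            kind = "ref", chrom = chrom_names[i], start = pos,
            end = pos + size - 1L, strand = "-", len = size)
          cur <- pos + size
        } else if (kind == "gap") {
          flush_ref(pos - 1L)
          part[[length(part) + 1L]] <- list(
            kind = "gap", chrom = chrom_names[i], start = pos,
            end = pos + size - 1L, strand = "+", len = size)
          cur <- pos + size
        }
        if (kind %in% c("inversion", "deletion", "insertion")) {
          truth[[length(truth) + 1L]] <- data.frame(
            kind = kind, scaffold_id = NA_character_,
            chrom = chrom_names[i], ref_pos = pos,
            chrom2 = NA_character_, ref_pos2 = NA_integer_,
            size = size, countable = ev$countable[r],
            stringsAsFactors = FALSE)
        }
      }
      flush_ref(lens[i])
      plans[[length(plans) + 1L]] <- part
      part_meta[[length(part_meta) + 1L]] <- list(
        chrom_idx = i, part_index = part_index,
        begins_cut = begins_cut, ends_cut = NA_integer_)
    }

    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      kind = character(), scaffold_id = character(), chrom = character(),
      ref_pos = integer(), chrom2 = character(), ref_pos2 = integer(),
      size = integer(), countable = logical(), stringsAsFactors = FALSE)

    # ---- wire parts into scaffolds via misjoin successor links -----------
    ends_cut <- vapply(part_meta, function(m) m$ends_cut %||% NA_integer_,
                       integer(1))
    begins_cut <- vapply(part_meta, function(m) m$begins_cut %||% NA_integer_,
                         integer(1))
    chrom_idx_of <- vapply(part_meta, function(m) m$chrom_idx, integer(1))
    successor <- rep(NA_integer_, length(plans))
    mj_junction <- rep(NA_integer_, length(plans))  # misjoin id at part end
    for (j in seq_len(config$n_misjoin)) {
      # source: the part on the lower-index chromosome ending at this cut;
      # target: the part on the higher-index chromosome beginning at it
      src_cands <- which(ends_cut == j)
      tgt_cands <- which(begins_cut == j)
      src <- src_cands[which.min(chrom_idx_of[src_cands])]
      tgt <- tgt_cands[which.max(chrom_idx_of[tgt_cands])]
      successor[src] <- tgt
      mj_junction[src] <- j
    }

    has_pred <- rep(FALSE, length(plans))
    has_pred[successor[!is.na(successor)]] <- TRUE
    starts <- which(!has_pred)
    # deterministic scaffold order: by chromosome then part index
    ord <- order(chrom_idx_of[starts],
                 vapply(part_meta[starts], function(m) m$part_index,
                        integer(1)))
    starts <- starts[ord]

    # ---- assemble sequences ---------------------------------------------
    scaffolds <- character()
    segments <- list()
    small_indels <- list()
    mj_truth_scaffold <- function(j, sid) {
      cut_rows <- which(events$kind == "cut" & events$misjoin_id == j)
      e <- events[cut_rows, ]
      e <- e[order(e$chrom_idx), ]
      truth[nrow(truth) + 1L, ] <<- list(
        "misjoin", sid, chrom_names[e$chrom_idx[1]], e$pos[1],
        chrom_names[e$chrom_idx[2]], e$pos[2], NA_integer_, TRUE)
    }

    sid_n <- 0L
    for (s in starts) {
      sid_n <- sid_n + 1L
      sid <- sprintf("scaf_%03d", sid_n)
      seq_parts <- character()
      offset <- 0L
      p <- s
      while (!is.na(p)) {
        for (piece in plans[[p]]) {
          if (piece$kind == "ref") {
            seqs <- substr(genome[[piece$chrom]], piece$start, piece$end)
            if (piece$strand == "-") seqs <- revcomp(seqs)
            if (config$small_indel_rate > 0 && nchar(seqs) > 0) {
              res <- .apply_small_indels(seqs, config$small_indel_rate,
                                         piece, sid)
              seqs <- res$seq
              if (nrow(res$indels)) {
                small_indels[[length(small_indels) + 1L]] <- res$indels
              }
            }
          } else if (piece$kind == "ins") {
            seqs <- random_dna(piece$len, 0.5)
          } else {  # gap
            seqs <- strrep("N", piece$len)
          }
          plen <- nchar(seqs)
          if (plen > 0) {
            segments[[length(segments) + 1L]] <- data.frame(
              scaffold_id = sid, scaf_start = offset + 1L,
              scaf_end = offset + plen, kind = piece$kind,
              chrom = piece$chrom, ref_start = piece$start,
              ref_end = piece$end, strand = piece$strand,
              stringsAsFactors = FALSE)
            seq_parts <- c(seq_parts, seqs)
            offset <- offset + plen
          }
        }
        if (!is.na(mj_junction[p])) mj_truth_scaffold(mj_junction[p], sid)
        p <- successor[p]
      }
      scaffolds[sid] <- paste(seq_parts, collapse = "")
    }

    # fill scaffold ids for in-place events from segments
    segs <- do.call(rbind, segments)
    na_sid <- which(is.na(truth$scaffold_id))
    for (r in na_sid) {
      hit <- segs[segs$kind == "ref" & segs$chrom %in% truth$chrom[r] &
                  segs$ref_start <= truth$ref_pos[r] + 1L &
                  segs$ref_end >= truth$ref_pos[r] - 1L, , drop = FALSE]
      if (nrow(hit)) truth$scaffold_id[r] <- hit$scaffold_id[1]
    }

    small_indels <- if (length(small_indels)) do.call(rbind, small_indels)
                    else empty_indels()
    rownames(truth) <- NULL
    structure(list(scaffolds = scaffolds, truth = truth, segments = segs,
                   small_indels = small_indels, config = config),
              class = "synthetic_scaffolds")
  })
}

# Sprinkle 1-5 bp indels into a ref piece's sequence; returns the mutated
# sequence and a table of induced indels with approximate ref coordinates.
#' @noRd
.apply_small_indels <- function(seqs, rate, piece, sid) {
  n <- nchar(seqs)
  k <- if (n > 30L) stats::rbinom(1, n, rate) else 0L
  k <- min(k, (n - 10L) %/% 21L + 1L)
  if (k == 0) {
    return(list(seq = seqs, indels = empty_indels()))
  }
  pos <- sort(sample.int(n - 10L, k))
  # keep indels apart so they never merge
  pos <- pos[c(TRUE, diff(pos) > 20L)]
  kinds <- sample(c("insertion", "deletion"), length(pos), replace = TRUE)
  lens <- sample(1:5, length(pos), replace = TRUE)
  out <- character()
  cur <- 1L
  for (i in seq_along(pos)) {
    out <- c(out, substr(seqs, cur, pos[i] - 1L))
    if (kinds[i] == "insertion") {
      out <- c(out, random_dna(lens[i], 0.5))
      cur <- pos[i]
    } else {
      cur <- pos[i] + lens[i]
    }
  }
  out <- c(out, substr(seqs, cur, n))
  ref_pos <- if (piece$strand == "+") piece$start + pos - 1L
             else piece$end - pos + 1L
  indels <- data.frame(
    scaffold_id = sid, ref_chrom = piece$chrom, ref_pos = as.integer(ref_pos),
    kind = kinds, len = as.integer(lens), stringsAsFactors = FALSE)
  list(seq = paste(out, collapse = ""), indels = indels)
}

#' @export
print.synthetic_scaffolds <- function(x, ...) {
  cat(sprintf(
    "synthetic_scaffolds: %d scaffolds, %s bp; %d truth events (%d countable)\n",
    length(x$scaffolds), format(sum(nchar(x$scaffolds)), big.mark = ","),
    nrow(x$truth), sum(x$truth$countable)))
  invisible(x)
}

#' Write scaffolds and their truth table
#'
#' @param x A `synthetic_scaffolds` object.
#' @param dir Output directory.
#' @param prefix File name prefix (default "scaffolds").
#' @return Invisibly, named paths (`fasta`, `truth`, `segments`).
#' @export
write_scaffolds <- function(x, dir, prefix = "scaffolds") {
  stopifnot(inherits(x, "synthetic_scaffolds"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  sg <- file.path(dir, paste0(prefix, "_segments.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$scaffolds), fa)
  write.table(x$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$segments, sg, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, truth = tr, segments = sg))
}

#' Rebuild scaffold sequences from a segment table
#'
#' Reconstructs each scaffold from the reference and a `segments` table
#' (ignoring small indels, which are not part of the segment plan). Used to
#' verify truth-table/segment completeness: with no small indels the
#' reconstruction is exact.
#'
#' @param reference Reference sequences (any form accepted by
#'   [simulate_scaffolds()]).
#' @param segments A `segments` data frame from [simulate_scaffolds()].
#' @return Named character vector of reconstructed scaffold sequences.
#' @export
reconstruct_scaffolds <- function(reference, segments) {
  genome <- if (inherits(reference, "synthetic_genome")) reference$genome
            else as_seqset(reference)
  out <- character()
  for (sid in unique(segments$scaffold_id)) {
    segs <- segments[segments$scaffold_id == sid, , drop = FALSE]
    segs <- segs[order(segs$scaf_start), , drop = FALSE]
    parts <- vapply(seq_len(nrow(segs)), function(i) {
      if (segs$kind[i] == "ref") {
        s <- substr(genome[[segs$chrom[i]]], segs$ref_start[i], segs$ref_end[i])
        if (segs$strand[i] == "-") revcomp(s) else s
      } else if (segs$kind[i] == "gap") {
        strrep("N", segs$scaf_end[i] - segs$scaf_start[i] + 1L)
      } else {
        NA_character_  # novel insertion: not reconstructible from reference
      }
    }, character(1))
    out[sid] <- paste(parts[!is.na(parts)], collapse = "")
  }
  out
}
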