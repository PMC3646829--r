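# Independent oracles used to check the package's implementations.

# Brute-force affine-gap Smith-Waterman score: match +1, mismatch -1, a gap
# of length L costs 2 + L (open 2, extend 1). Row-vectorised dynamic
# programme, written independently of the package's alignment code.
#   best[i,j] = max(0, best[i-1,j-1] + s_ij, E[i,j], D[i,j])
#   E[i,j]    = max_{g>=1} best[i,  j-g] - (2 + g)   (gap in subject axis)
#   D[i,j]    = max_{g>=1} best[i-g,  j] - (2 + g)   (gap in query axis)
# Opening a new gap from a state that itself ended in a same-direction gap is
# dominated by extending, so E can be taken over the gap-free row maximum;
# the within-row maximisation reduces to a cumulative maximum.
sw_oracle_score <- function(query, subject, open = 2, ext = 1) {
  qb <- strsplit(query, "")[[1]]
  sb <- strsplit(subject, "")[[1]]
  n <- length(qb)
  m <- length(sb)
  best_prev <- numeric(m + 1)
  d_prev <- rep(-Inf, m + 1)
  top <- 0
  js <- seq_len(m)
  for (i in seq_len(n)) {
    sub_score <- ifelse(sb == qb[i], 1, -1)
    d_row <- pmax(d_prev - ext, best_prev - open - ext)
    mdiag <- best_prev[js] + sub_score        # best_prev[j-1] + s(i,j)
    h0 <- pmax(0, mdiag, d_row[js + 1])
    a <- h0 + js * ext
    e <- c(-Inf, cummax(a)[-m]) - open - js * ext
    best_row <- c(0, pmax(h0, e))
    top <- max(top, best_row)
    best_prev <- best_row
    d_prev <- d_row
  }
  top
}

# Cumulative-sum N50 oracle straight from the definition: the largest length
# L such that sequences of length >= L hold at least half of `threshold`
# (assembly total for N50, genome size for NG50); 0 when unreachable.
n50_oracle <- function(lengths, threshold = sum(lengths)) {
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= threshold / 2) return(L)
  }
  0
}

# Random DNA helper for fixtures.
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

# Match recovered misarrangement events against a truth table (kind equal,
# location within `pos_tol` bp, size within `size_tol` bp; misjoins match on
# either orientation of the junction). Returns c(precision, recall).
event_precision_recall <- function(events, truth, pos_tol = 1000,
                                   size_tol = 20) {
  match_one <- function(kind, chrom, pos, chrom2, pos2, size) {
    if (kind == "misjoin") {
      any(truth$kind == "misjoin" &
          ((truth$chrom == chrom & abs(truth$ref_pos - pos) < pos_tol &
            truth$chrom2 == chrom2 & abs(truth$ref_pos2 - pos2) < pos_tol) |
           (truth$chrom2 == chrom & abs(truth$ref_pos2 - pos) < pos_tol &
            truth$chrom == chrom2 & abs(truth$ref_pos - pos2) < pos_tol)))
    } else {
      any(truth$kind == kind & truth$chrom == chrom &
          abs(truth$ref_pos - pos) < pos_tol &
          abs(truth$size - size) <= size_tol)
    }
  }
  matched <- vapply(seq_len(nrow(events)), function(i) {
    match_one(events$kind[i], events$ref_chrom[i], events$ref_pos[i],
              events$ref_chrom2[i], events$ref_pos2[i], events$size[i])
  }, logical(1))
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    t1 <- truth[i, ]
    if (t1$kind == "misjoin") {
      any(events$kind == "misjoin" &
          ((events$ref_chrom == t1$chrom &
            abs(events$ref_pos - t1$ref_pos) < pos_tol) |
           (events$ref_chrom2 == t1$chrom &
            abs(events$ref_pos2 - t1$ref_pos) < pos_tol)))
    } else {
      any(events$kind == t1$kind & events$ref_chrom == t1$chrom &
          abs(events$ref_pos - t1$ref_pos) < pos_tol &
          abs(events$size - t1$size) <= size_tol)
    }
  }, logical(1))
  c(precision = if (nrow(events)) mean(matched) else 1,
    recall = if (nrow(truth)) mean(recalled) else 1)
}
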