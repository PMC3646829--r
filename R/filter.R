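# Read filtering regimes for mate-paired color reads.
#
# Three regimes are supported, mirroring common practice for SOLiD data:
#   nofilter - keep everything;
#   nodot    - drop reads with any undetermined ('.') color call;
#   qv       - drop reads unless every color has QV strictly above a threshold
#              (threshold 10 corresponds to 90% per-base accuracy).
# With the convention that '.' positions carry QV 0, the qv regime is strictly
# stricter than nodot, giving the nesting
#   survivors(qv, T >= 0) subseteq survivors(nodot) subseteq survivors(nofilter).

#' Construct a read filtering policy
#'
#' @param mode One of "nofilter", "nodot", "qv".
#' @param qv_threshold Integer >= 0; used only in "qv" mode. A read passes iff
#'   every quality value is strictly greater than this (default 10).
#' @param pair_rule "both_pass" (a pair survives only if both mates pass; a
#'   mate-pair with one bad mate gives no linkage signal to an assembler) or
#'   "independent" (mates filtered individually).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(mode = c("nofilter", "nodot", "qv"),
                          qv_threshold = 10L,
                          pair_rule = c("both_pass", "independent")) {
  mode <- match.arg(mode)
  pair_rule <- match.arg(pair_rule)
  qv_threshold <- as.integer(qv_threshold)
  if (is.na(qv_threshold) || qv_threshold < 0) {
    stopf("qv_threshold must be a non-negative integer")
  }
  structure(list(mode = mode, qv_threshold = qv_threshold,
                 pair_rule = pair_rule),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf("filter_policy: mode=%s%s, pair_rule=%s\n", x$mode,
              if (x$mode == "qv") sprintf(" (QV > %d)", x$qv_threshold) else "",
              x$pair_rule))
  invisible(x)
}

#' Does each read pass a filtering policy?
#'
#' @param reads A [color_reads()] data frame.
#' @param policy A [filter_policy()].
#' @return Logical vector, one element per read.
#' @export
passes_filter <- function(reads, policy) {
  stopifnot(inherits(reads, "color_reads"), inherits(policy, "filter_policy"))
  switch(policy$mode,
    nofilter = rep(TRUE, nrow(reads)),
    nodot = !grepl(".", reads$colors, fixed = TRUE),
    qv = vapply(reads$qvs, function(q) {
      length(q) == 0 || min(q) > policy$qv_threshold
    }, logical(1))
  )
}

#' Filter mate pairs under a policy
#'
#' Applies `policy` to paired F3/R3 reads. Under `pair_rule = "both_pass"` a
#' pair survives only if both mates pass; under `"independent"` each mate is
#' kept or dropped on its own (surviving mates of broken pairs are returned as
#' singletons).
#'
#' @param f3,r3 [color_reads()] data frames in matching pair order (see
#'   [pair_mates()]).
#' @param policy A [filter_policy()].
#' @return List with `f3`, `r3` (surviving pairs), `singletons` (only under
#'   `"independent"`), and `stats`, a one-row data frame with input/output
#'   pair, read and base (color) counts.
#' @export
filter_pairs <- function(f3, r3, policy) {
  stopifnot(inherits(f3, "color_reads"), inherits(r3, "color_reads"))
  if (nrow(f3) != nrow(r3)) {
    stopf("f3 and r3 must have the same number of reads (paired order)")
  }
  pf <- passes_filter(f3, policy)
  pr <- passes_filter(r3, policy)
  bases_in <- sum(nchar(f3$colors)) + sum(nchar(r3$colors))
  if (policy$pair_rule == "both_pass") {
    keep <- pf & pr
    out_f3 <- f3[keep, , drop = FALSE]
    out_r3 <- r3[keep, , drop = FALSE]
    singles <- f3[0, , drop = FALSE]
  } else {
    keep <- pf & pr
    out_f3 <- f3[keep, , drop = FALSE]
    out_r3 <- r3[keep, , drop = FALSE]
    singles <- rbind(f3[pf & !pr, , drop = FALSE], r3[pr & !pf, , drop = FALSE])
  }
  class(out_f3) <- class(out_r3) <- class(singles) <-
    c("color_reads", "data.frame")
  bases_out <- sum(nchar(out_f3$colors)) + sum(nchar(out_r3$colors)) +
    sum(nchar(singles$colors))
  stats <- data.frame(
    mode = policy$mode, pair_rule = policy$pair_rule,
    pairs_in = nrow(f3), pairs_out = sum(keep),
    reads_in = 2L * nrow(f3),
    reads_out = 2L * sum(keep) + nrow(singles),
    bases_in = bases_in, bases_out = bases_out,
    stringsAsFactors = FALSE
  )
  list(f3 = out_f3, r3 = out_r3, singletons = singles, stats = stats)
}

#' Phred quality value to base-level accuracy
#'
#' `accuracy = 1 - 10^(-qv/10)`: QV 10 is 90% accuracy, QV 20 is 99%.
#'
#' @param qv Numeric vector of quality values (>= 0).
#' @return Numeric vector of accuracies in \[0, 1).
#' @examples
#' qv_to_accuracy(10)  # 0.9
#' @export
qv_to_accuracy <- function(qv) {
  stopifnot(all(qv >= 0))
  1 - 10^(-qv / 10)
}

#' Expected depth of coverage
#'
#' Fold coverage of a genome by a read set: `n_reads * read_len /
#' genome_size`.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param genome_size Genome size in bp (> 0).
#' @param subsample Optional fraction in (0, 1\] applied to `n_reads` first
#'   (e.g. to mirror a subsampling step upstream of assembly).
#' @return Fold coverage (numeric).
#' @export
depth_of_coverage <- function(n_reads, read_len, genome_size, subsample = 1) {
  if (genome_size <= 0) stopf("genome_size must be > 0")
  stopifnot(subsample > 0, subsample <= 1)
  n_reads * subsample * read_len / genome_size
}
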