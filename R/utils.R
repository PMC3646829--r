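# Shared internal helpers.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero to `digits` decimals (table-style rounding;
# base round() is banker's rounding which disagrees at .5 ties).
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Random DNA of length n with a given GC fraction (iid model).
#' @noRd
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' @noRd
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Coerce a reference to a named character vector of sequences.
# Accepts DNAStringSet, named character vector, or a FASTA path.
#' @noRd
as_seqset <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) stopf("sequences must be named")
    return(x)
  }
  stopf("cannot interpret object of class '%s' as sequences", class(x)[1])
}

# Empty AlignmentFragment table with the canonical column set.
#' @noRd
empty_fragments <- function() {
  data.frame(
    scaffold_id = character(), scaffold_start = integer(),
    scaffold_end = integer(), ref_chrom = character(),
    ref_start = integer(), ref_end = integer(), strand = character(),
    score = numeric(), n_match = integer(), n_mismatch = integer(),
    n_ins = integer(), n_del = integer(), stringsAsFactors = FALSE
  )
}

#' @noRd
empty_indels <- function() {
  data.frame(
    scaffold_id = character(), ref_chrom = character(), ref_pos = integer(),
    kind = character(), len = integer(), stringsAsFactors = FALSE
  )
}
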