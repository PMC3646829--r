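# SOLiD di-base color-space codec and csfasta/.qual I/O.
#
# The di-base code is the XOR of 2-bit base codes (A=0, C=1, G=2, T=3), which
# reproduces the standard SOLiD encoding matrix: color 0 for equal adjacent
# bases, 3 for complementary transversions, etc. '.' marks an undetermined
# color call.

.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Encode a nucleotide sequence in SOLiD color space
#'
#' Converts a base-space sequence into the di-base color representation used
#' by the SOLiD platform: each color is the XOR of the 2-bit codes (A=0, C=1,
#' G=2, T=3) of two adjacent bases, so a sequence of n bases yields n-1
#' colors, with the first base reported separately as the primer base.
#'
#' @param sequence Character scalar over the alphabet A/C/G/T, length >= 2.
#' @return A list with elements `primer_base` (single character) and `colors`
#'   (character scalar over "0123", one symbol per adjacent base pair).
#' @examples
#' encode_colorspace("AACGT")   # primer "A", colors "0131"
#' @seealso [decode_colorspace()]
#' @export
encode_colorspace <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 2) stopf("sequence must have length >= 2")
  bases <- strsplit(toupper(sequence), "")[[1]]
  codes <- .BASE_CODE[bases]
  bad <- which(is.na(codes))
  if (length(bad)) {
    stopf("non-ACGT character '%s' at position %d", bases[bad[1]], bad[1])
  }
  cols <- bitwXor(codes[-length(codes)], codes[-1])
  list(primer_base = bases[1], colors = paste(cols, collapse = ""))
}

#' Decode a color-space read back to nucleotides
#'
#' Exact inverse of [encode_colorspace()]: starting from the primer base, each
#' color XORed with the running base code yields the next base. Undetermined
#' colors ('.') cannot be decoded and raise an error naming the first bad
#' position.
#'
#' @param primer_base Single character, one of A/C/G/T.
#' @param colors Character scalar over "0123" (may be empty).
#' @return Character scalar: the nucleotide sequence, of length
#'   `nchar(colors) + 1`.
#' @examples
#' decode_colorspace("A", "0131")  # "AACGT"
#' @export
decode_colorspace <- function(primer_base, colors) {
  stopifnot(is.character(primer_base), nchar(primer_base) == 1)
  primer_base <- toupper(primer_base)
  if (!primer_base %in% names(.BASE_CODE)) {
    stopf("invalid primer base '%s'", primer_base)
  }
  if (nchar(colors) == 0) return(primer_base)
  syms <- strsplit(colors, "")[[1]]
  dot <- which(syms == ".")
  if (length(dot)) {
    stopf("undetermined color '.' at position %d cannot be decoded", dot[1])
  }
  if (!all(syms %in% c("0", "1", "2", "3"))) {
    stopf("invalid color symbol at position %d",
          which(!syms %in% c("0", "1", "2", "3"))[1])
  }
  code <- .BASE_CODE[[primer_base]]
  out <- character(length(syms) + 1)
  out[1] <- primer_base
  for (i in seq_along(syms)) {
    code <- bitwXor(code, as.integer(syms[i]))
    out[i + 1] <- names(.BASE_CODE)[code + 1L]
  }
  paste(out, collapse = "")
}

#' Construct a set of color-space reads
#'
#' Container for SOLiD color-space reads: a data frame of class `color_reads`
#' with one row per read. `colors` holds the color string (alphabet 0/1/2/3
#' and '.' for undetermined calls) and `qvs` a list column of Phred-scaled
#' integer quality values, one per color. Positions with color '.' are
#' conventionally assigned QV 0, which makes quality filters strictly stricter
#' than undetermined-call removal.
#'
#' @param read_id Character vector of read identifiers.
#' @param tag Character vector, "F3" or "R3" (mate tag).
#' @param primer_base Character vector of primer bases (A/C/G/T).
#' @param colors Character vector of color strings.
#' @param qvs List of integer vectors, `qvs[[i]]` of length
#'   `nchar(colors[i])`.
#' @return A `color_reads` data frame.
#' @export
color_reads <- function(read_id, tag, primer_base, colors, qvs) {
  stopifnot(length(read_id) == length(colors), length(qvs) == length(colors))
  tag <- as.character(tag)
  if (!all(tag %in% c("F3", "R3"))) stopf("tag must be 'F3' or 'R3'")
  if (!all(toupper(primer_base) %in% names(.BASE_CODE))) {
    stopf("invalid primer base")
  }
  nl <- nchar(colors)
  ql <- lengths(qvs)
  if (any(nl != ql)) {
    i <- which(nl != ql)[1]
    stopf("read '%s': %d colors but %d quality values", read_id[i], nl[i], ql[i])
  }
  qvs <- unname(lapply(qvs, as.integer))
  if (any(vapply(qvs, function(q) any(q < 0), logical(1)))) {
    stopf("quality values must be >= 0")
  }
  out <- data.frame(
    read_id = as.character(read_id), tag = tag,
    primer_base = toupper(primer_base), colors = as.character(colors),
    stringsAsFactors = FALSE
  )
  out$qvs <- qvs
  class(out) <- c("color_reads", "data.frame")
  out
}

#' @export
print.color_reads <- function(x, ...) {
  cat(sprintf("color_reads: %d reads (%d F3, %d R3), lengths %s\n",
              nrow(x), sum(x$tag == "F3"), sum(x$tag == "R3"),
              paste(unique(nchar(x$colors)), collapse = "/")))
  invisible(x)
}

#' Read a csfasta color read file
#'
#' Parses the csfasta dialect of FASTA emitted by SOLiD conversion tools:
#' '#' comment lines are skipped, each '>' header is followed by one sequence
#' line whose first character is the primer base and the rest are colors.
#' The mate tag is taken from a trailing `_F3`/`_R3` in the id when present.
#'
#' @param path Path to a csfasta file.
#' @param qual_path Optional path to the matching .qual file; if supplied the
#'   reads are paired with their quality values record by record (mismatched
#'   ids or lengths are an error). Without it, all QVs are set to 0.
#' @return A [color_reads()] data frame.
#' @export
read_csfasta <- function(path, qual_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) {
    return(color_reads(character(), character(), character(), character(), list()))
  }
  if (!hdr[1] || any(diff(which(hdr)) != 2) || sum(hdr) * 2 != length(lines)) {
    stopf("malformed csfasta: expected alternating header/sequence lines")
  }
  ids <- sub("^>", "", lines[hdr])
  seqs <- lines[!hdr]
  primer <- substr(seqs, 1, 1)
  colors <- substr(seqs, 2, nchar(seqs))
  tag <- ifelse(grepl("_R3$", ids), "R3", "F3")
  if (is.null(qual_path)) {
    qvs <- lapply(nchar(colors), function(n) integer(n))
  } else {
    q <- read_qual(qual_path)
    if (length(q) != length(ids)) {
      stopf("csfasta has %d records but .qual has %d", length(ids), length(q))
    }
    if (!identical(names(q), ids)) {
      i <- which(names(q) != ids)[1]
      stopf("record %d: csfasta id '%s' does not match .qual id '%s'",
            i, ids[i], names(q)[i])
    }
    bad <- which(lengths(q) != nchar(colors))
    if (length(bad)) {
      stopf("read '%s': %d colors but %d quality values",
            ids[bad[1]], nchar(colors)[bad[1]], lengths(q)[bad[1]])
    }
    qvs <- q
    # undetermined colors get QV 0 regardless of what the .qual file says
    has_dot <- grepl(".", colors, fixed = TRUE)
    for (i in which(has_dot)) {
      dots <- which(strsplit(colors[i], "")[[1]] == ".")
      qvs[[i]][dots] <- 0L
    }
  }
  color_reads(ids, tag, primer, colors, qvs)
}

#' Read a SOLiD .qual quality file
#'
#' @param path Path to a .qual file ('>' headers, whitespace-separated
#'   integers on the following line(s)).
#' @return Named list of integer vectors, in file order.
#' @export
read_qual <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines)) return(setNames(list(), character()))
  if (!hdr[1]) stopf("malformed .qual: does not start with a '>' header")
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  vals <- split(lines[!hdr], idx[!hdr])
  out <- lapply(vals, function(v) {
    as.integer(strsplit(paste(v, collapse = " "), "\\s+")[[1]])
  })
  # records with no value line at all become empty integer vectors
  full <- setNames(vector("list", length(ids)), as.character(seq_along(ids)))
  full[names(out)] <- out
  full <- lapply(full, function(v) if (is.null(v)) integer() else v)
  setNames(full, ids)
}

#' Write color reads to csfasta (and optionally .qual)
#'
#' Round-trips with [read_csfasta()]: ids, colors, and quality values are
#' preserved bit-exactly.
#'
#' @param reads A [color_reads()] data frame.
#' @param path Output csfasta path.
#' @param qual_path Optional output .qual path.
#' @return Invisibly, `path`.
#' @export
write_csfasta <- function(reads, path, qual_path = NULL) {
  stopifnot(inherits(reads, "color_reads"))
  lines <- as.vector(rbind(paste0(">", reads$read_id),
                           paste0(reads$primer_base, reads$colors)))
  writeLines(lines, path)
  if (!is.null(qual_path)) {
    qlines <- as.vector(rbind(
      paste0(">", reads$read_id),
      vapply(reads$qvs, paste, character(1), collapse = " ")
    ))
    writeLines(qlines, qual_path)
  }
  invisible(path)
}

#' Pair F3/R3 mates by shared read id prefix
#'
#' SOLiD mate naming puts the tag as a suffix (`<prefix>_F3` / `<prefix>_R3`).
#' Reads are paired on the shared prefix; orphans (prefixes with only one
#' mate) are returned separately and reported with a warning.
#'
#' @param reads A [color_reads()] data frame containing both tags.
#' @return List with `f3` and `r3` ([color_reads()] in matching pair order)
#'   and `orphans` (a `color_reads` of unpaired reads).
#' @export
pair_mates <- function(reads) {
  stopifnot(inherits(reads, "color_reads"))
  prefix <- sub("_(F3|R3)$", "", reads$read_id)
  f3 <- reads[reads$tag == "F3", , drop = FALSE]
  r3 <- reads[reads$tag == "R3", , drop = FALSE]
  pf <- prefix[reads$tag == "F3"]
  pr <- prefix[reads$tag == "R3"]
  common <- intersect(pf, pr)
  f3p <- f3[match(common, pf), , drop = FALSE]
  r3p <- r3[match(common, pr), , drop = FALSE]
  orphans <- rbind(f3[!pf %in% common, , drop = FALSE],
                   r3[!pr %in% common, , drop = FALSE])
  class(f3p) <- class(r3p) <- class(orphans) <- c("color_reads", "data.frame")
  if (nrow(orphans)) {
    warning(sprintf("%d orphan mate(s) without a partner", nrow(orphans)),
            call. = FALSE)
  }
  list(f3 = f3p, r3 = r3p, orphans = orphans)
}
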