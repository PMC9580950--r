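#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Uppercase/lowercase input over `{A,C,G,T,U}` is accepted; `U` is treated as
#' `T` and the result is returned lower-case, the case convention used for all
#' sequence output in this package.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length over `{a,c,g,t}`.
#' @export
normalize_seq <- function(seq) {
  if (!is.character(seq)) {
    stop("`seq` must be a character vector", call. = FALSE)
  }
  out <- chartr("Uu", "Tt", seq)
  bad <- grepl("[^ACGTacgt]", out)
  if (any(bad)) {
    stop(
      "non-nucleotide character in sequence(s): ",
      paste(utils::head(seq[bad], 3L), collapse = ", "),
      call. = FALSE
    )
  }
  tolower(out)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reverse complement, e.g. the mature sequences of
#' hsa-mir-3529-5p and hsa-mir-7-2 map onto each other. Input may use `U`
#' (normalized to `T`); output is lower-case DNA.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,U}` (any case).
#' @return Character vector of reverse complements, lower-case.
#' @examples
#' reverse_complement("aggtagactgggatttgttgtt")
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))
  tolower(as.character(rc))
}

#' Split a mature sequence into seed and xseed regions
#'
#' The seed region of a mature miRNA (conventionally positions 2-8, 1-based)
#' dominates target recognition; the xseed region is everything else, kept in
#' original order. The two parts always partition the sequence.
#'
#' @param seq A single nucleotide sequence.
#' @param seed_range Integer vector `c(first, last)` of 1-based inclusive seed
#'   positions. Default `c(2, 8)`.
#' @return A list with components `seed`, `xseed`, and `seed_range`.
#' @examples
#' seed_decompose("tgacccccatgtcgcctctgtag")
#' @export
seed_decompose <- function(seq, seed_range = c(2L, 8L)) {
  stopifnot(length(seq) == 1L)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  first <- as.integer(seed_range[1L])
  last <- as.integer(seed_range[2L])
  if (first < 1L || last < first) {
    stop("invalid seed_range", call. = FALSE)
  }
  if (last > n) {
    stop(
      "seed_range [", first, ", ", last, "] exceeds sequence length ", n,
      call. = FALSE
    )
  }
  seed <- substr(seq, first, last)
  xseed <- paste0(substr(seq, 1L, first - 1L), substring(seq, last + 1L))
  list(seed = seed, xseed = xseed, seed_range = c(first, last))
}

#' Reassemble a sequence from its seed/xseed decomposition
#'
#' Inverse of [seed_decompose()]; used mainly to check the partition property.
#'
#' @param decomp A list as returned by [seed_decompose()].
#' @return The reconstructed sequence.
#' @export
seed_reassemble <- function(decomp) {
  first <- decomp$seed_range[1L]
  prefix <- substr(decomp$xseed, 1L, first - 1L)
  suffix <- substring(decomp$xseed, first)
  paste0(prefix, decomp$seed, suffix)
}

#' Vectorised seed extraction
#'
#' @param seq Character vector of sequences.
#' @inheritParams seed_decompose
#' @return Character vector of seed substrings.
#' @export
seed_of <- function(seq, seed_range = c(2L, 8L)) {
  substr(normalize_seq(seq), seed_range[1L], seed_range[2L])
}

#' Vectorised xseed extraction
#'
#' @inheritParams seed_of
#' @return Character vector of xseed strings (sequence minus the seed region).
#' @export
xseed_of <- function(seq, seed_range = c(2L, 8L)) {
  seq <- normalize_seq(seq)
  paste0(
    substr(seq, 1L, seed_range[1L] - 1L),
    substring(seq, seed_range[2L] + 1L)
  )
}

#' Hamming distance between two equal-length strings
#'
#' Returns `Inf` for strings of unequal length (no alignment is attempted);
#' this is the comparison used when deciding whether two xseed regions are
#' within the clustering tolerance.
#'
#' @param a,b Single character strings.
#' @return Non-negative integer, or `Inf` when lengths differ.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    return(Inf)
  }
  if (nchar(a) == 0L) {
    return(0L)
  }
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}
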