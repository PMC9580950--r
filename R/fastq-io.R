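#' Write reads to a FASTQ file
#'
#' Writes four-line FASTQ records with Phred+33 quality strings, preserving
#' sequence case byte-for-byte (mature portions are emitted lower-case by the
#' simulator). Paths ending in `.gz` are gzip-compressed.
#'
#' @param reads A tibble/data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output path (`.fastq` or `.fastq.gz`).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(
    paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality),
    con
  )
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file, optionally gzip-compressed.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", path, " has ", length(lines), " lines", call. = FALSE)
  }
  i <- seq(1L, length(lines), by = 4L)
  if (length(i) > 0L && any(substr(lines[i], 1L, 1L) != "@")) {
    stop("malformed FASTQ header in ", path, call. = FALSE)
  }
  tibble::tibble(
    id = sub("^@", "", lines[i]),
    sequence = lines[i + 1L],
    quality = lines[i + 3L]
  )
}

#' Decode a Phred+33 quality string to numeric scores
#'
#' @param quality A single quality string.
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(quality) {
  if (!is.character(quality) || length(quality) != 1L || !nzchar(quality)) {
    stop("`quality` must be one non-empty string", call. = FALSE)
  }
  utf8ToInt(quality) - 33L
}

#' Write / read a simulation ground-truth table
#'
#' The ground truth is a plain CSV with one row per simulated molecule and the
#' fixed column order `molecule_name, rna_class, sequence, chrom, start, end,
#' strand, expression_count, cigar, source_id, alteration_mode`.
#'
#' @param truth Ground-truth tibble as produced by [simulate_reads()].
#' @param path Output CSV path.
#' @return Invisibly (`write_truth`) or visibly (`read_truth`) the tibble.
#' @export
write_truth <- function(truth, path) {
  cols <- c(
    "molecule_name", "rna_class", "sequence", "chrom", "start", "end",
    "strand", "expression_count", "cigar", "source_id", "alteration_mode"
  )
  stopifnot(all(cols %in% names(truth)))
  utils::write.csv(truth[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    stop("truth file not found: ", path, call. = FALSE)
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$source_id[is.na(out$source_id)] <- ""
  tibble::as_tibble(out)
}
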