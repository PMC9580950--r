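#' Load a mature small-RNA reference set from FASTA + GFF3
#'
#' Reads mature sequences from `fasta_path` and their genomic coordinates from
#' `gff3_path` (miRBase-style GFF3: 1-based inclusive, stranded). Features are
#' matched to FASTA records by the `Name` attribute, falling back to `ID`; the
#' FASTA header is taken up to the first whitespace. `U` bases are normalized
#' to `T` internally.
#'
#' The RNA class of each record is read from an `rna_class` GFF3 attribute
#' when present (one of `known_miRNA`, `novel_miRNA`, `known_piRNA`);
#' otherwise it is inferred from the feature type (`miRNA` -> `known_miRNA`,
#' `piRNA` -> `known_piRNA`), defaulting to `known_miRNA`.
#'
#' @param fasta_path Path to a FASTA file of mature sequences.
#' @param gff3_path Path to the matching GFF3 file.
#' @return A tibble with one row per mature sequence and columns `id`,
#'   `mature_seq`, `rna_class`, `chrom`, `start`, `end`, `strand`.
#' @export
load_reference <- function(fasta_path, gff3_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  if (!file.exists(gff3_path)) {
    stop("GFF3 file not found: ", gff3_path, call. = FALSE)
  }
  validate_gff3_lines(gff3_path)

  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate FASTA id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  mature <- normalize_seq(as.character(seqs))

  gff <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gff))
  feat_name <- if ("Name" %in% names(meta)) as.character(meta$Name) else rep(NA_character_, length(gff))
  feat_id <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gff))
  key <- ifelse(is.na(feat_name) | feat_name == "", feat_id, feat_name)

  idx <- match(ids, key)
  if (anyNA(idx)) {
    stop(
      "no GFF3 coordinate feature for FASTA id(s): ",
      paste(ids[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  n_unused <- length(gff) - length(unique(idx))
  if (n_unused > 0L) {
    message(n_unused, " GFF3 feature(s) without a matching FASTA record ignored")
  }
  gff <- gff[idx]
  meta <- meta[idx, , drop = FALSE]

  rna_class <- if ("rna_class" %in% names(meta)) {
    as.character(meta$rna_class)
  } else {
    type <- as.character(gff$type)
    ifelse(grepl("piRNA", type, ignore.case = TRUE), "known_piRNA",
      "known_miRNA"
    )
  }
  bad_class <- !rna_class %in% c("known_miRNA", "novel_miRNA", "known_piRNA")
  if (any(bad_class)) {
    stop(
      "unrecognised rna_class for: ",
      paste(ids[bad_class], collapse = ", "),
      call. = FALSE
    )
  }

  ref <- tibble::tibble(
    id = ids,
    mature_seq = unname(mature),
    rna_class = rna_class,
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff))
  )
  ref$strand[!ref$strand %in% c("+", "-")] <- "+"

  len_mismatch <- (ref$end - ref$start + 1L) != nchar(ref$mature_seq)
  if (any(len_mismatch)) {
    stop(
      "interval length does not match sequence length for: ",
      paste(ref$id[len_mismatch], collapse = ", "),
      call. = FALSE
    )
  }
  ref
}

# Structural pre-check so a malformed GFF3 body line is reported with its line
# number rather than as an opaque parser failure.
validate_gff3_lines <- function(gff3_path) {
  lines <- readLines(gff3_path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad) > 0L) {
    stop(
      "malformed GFF3 line ", bad[1L], " in ", gff3_path,
      " (expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1L]], ")",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Write a reference set to FASTA + GFF3
#'
#' Inverse of [load_reference()] for reference tibbles produced in this
#' package (e.g. by [make_fixtures()]). Each record becomes one FASTA entry
#' and one GFF3 feature carrying `ID`, `Name`, and `rna_class` attributes.
#'
#' @param ref Reference tibble (`id`, `mature_seq`, `rna_class`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference <- function(ref, fasta_path, gff3_path) {
  stopifnot(all(c(
    "id", "mature_seq", "rna_class", "chrom", "start", "end", "strand"
  ) %in% names(ref)))
  writeLines(
    paste0(">", ref$id, "\n", normalize_seq(ref$mature_seq)),
    fasta_path
  )
  type <- ifelse(ref$rna_class == "known_piRNA", "piRNA", "miRNA")
  gff_lines <- c(
    "##gff-version 3",
    paste(
      ref$chrom, "mirbench", type, ref$start, ref$end, ".", ref$strand, ".",
      paste0("ID=", ref$id, ";Name=", ref$id, ";rna_class=", ref$rna_class),
      sep = "\t"
    )
  )
  writeLines(gff_lines, gff3_path)
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}
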