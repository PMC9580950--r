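#' Generate a toy mature small-RNA reference set
#'
#' Fabricates unique random mature sequences with realistic length bands
#' (known/novel miRNA 17-24 nt, piRNA 25-31 nt) and non-overlapping genomic
#' intervals spread round-robin across `n_chromosomes` chromosomes, so the
#' whole simulation/annotation/evaluation cycle can run offline. Fully
#' deterministic under `rng_seed`.
#'
#' @param n_mirna,n_pirna,n_novel Number of known miRNA, known piRNA, and
#'   novel miRNA records.
#' @param n_chromosomes Number of chromosomes to spread records over.
#' @param rng_seed Integer seed.
#' @param fasta_path,gff3_path Optional output paths; when both are given the
#'   reference is also written with [write_reference()].
#' @return Reference tibble (`id`, `mature_seq`, `rna_class`, `chrom`,
#'   `start`, `end`, `strand`), invisibly carrying the file paths in
#'   attributes `fasta` / `gff3` when written.
#' @export
make_fixtures <- function(n_mirna = 20L, n_pirna = 10L, n_novel = 5L,
                          n_chromosomes = 3L, rng_seed = 1L,
                          fasta_path = NULL, gff3_path = NULL) {
  n_mirna <- as.integer(n_mirna)
  n_pirna <- as.integer(n_pirna)
  n_novel <- as.integer(n_novel)
  if (any(c(n_mirna, n_pirna, n_novel) < 0L)) {
    stop("record counts must be non-negative", call. = FALSE)
  }
  total <- n_mirna + n_pirna + n_novel
  if (total == 0L) stop("at least one record is required", call. = FALSE)
  if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1", call. = FALSE)
  set.seed(as.integer(rng_seed))

  rand_seq <- function(n, len_min, len_max) {
    lens <- sample(len_min:len_max, n, replace = TRUE)
    vapply(lens, function(l) {
      paste(sample(c("a", "c", "g", "t"), l, replace = TRUE), collapse = "")
    }, character(1))
  }
  # draw until all sequences are unique (collision odds are tiny at 4^17)
  draw_unique <- function(n, len_min, len_max, taken) {
    out <- character(0)
    while (length(out) < n) {
      cand <- rand_seq(n - length(out), len_min, len_max)
      cand <- setdiff(unique(cand), c(taken, out))
      out <- c(out, cand)
    }
    out
  }

  mirna_seqs <- draw_unique(n_mirna, 17L, 24L, character(0))
  novel_seqs <- draw_unique(n_novel, 17L, 24L, mirna_seqs)
  pirna_seqs <- draw_unique(n_pirna, 25L, 31L, c(mirna_seqs, novel_seqs))

  ref <- tibble::tibble(
    id = c(
      sprintf("syn-mir-%d", seq_len(n_mirna)),
      sprintf("syn-novel-mir-%d", seq_len(n_novel)),
      sprintf("syn-pir-%d", seq_len(n_pirna))
    ),
    mature_seq = c(mirna_seqs, novel_seqs, pirna_seqs),
    rna_class = rep(
      c("known_miRNA", "novel_miRNA", "known_piRNA"),
      c(n_mirna, n_novel, n_pirna)
    )
  )
  ref$chrom <- paste0("chr", (seq_len(total) - 1L) %% n_chromosomes + 1L)
  # non-overlapping intervals: fixed 1 kb spacing per record within chromosome
  slot <- stats::ave(seq_len(total), ref$chrom, FUN = seq_along)
  ref$start <- 1000L + (slot - 1L) * 1000L
  ref$end <- ref$start + nchar(ref$mature_seq) - 1L
  ref$strand <- sample(c("+", "-"), total, replace = TRUE)

  if (!is.null(fasta_path) && !is.null(gff3_path)) {
    write_reference(ref, fasta_path, gff3_path)
    attr(ref, "fasta") <- fasta_path
    attr(ref, "gff3") <- gff3_path
  }
  ref
}
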