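# Shared fixture builders: everything is generated in code at test time.

toy_reference <- function() {
  tibble::tibble(
    id = c("mir-a", "mir-b", "pir-c"),
    mature_seq = c(
      "tgagguaguagguuguauaguu", # U-containing on purpose
      "tgacccccatgtcgcctctgtag",
      "tgggcctgggactgagaatcagtcgactga"
    ),
    rna_class = c("known_miRNA", "known_miRNA", "known_piRNA"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L),
    end = c(1021L, 5022L, 2029L),
    strand = c("+", "-", "+")
  )
}

write_toy_reference <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ref <- toy_reference()
  ref$mature_seq <- mirbench::normalize_seq(ref$mature_seq)
  fasta <- file.path(dir, "ref.fa")
  gff <- file.path(dir, "ref.gff3")
  mirbench::write_reference(ref, fasta, gff)
  list(ref = ref, fasta = fasta, gff3 = gff)
}

random_seq <- function(n, len_min = 17L, len_max = 24L) {
  lens <- if (len_min == len_max) {
    rep(len_min, n)
  } else {
    sample(len_min:len_max, n, replace = TRUE)
  }
  vapply(lens, function(l) {
    paste(sample(c("a", "c", "g", "t"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Independent brute-force confusion tally: counts agreements cell by cell in
# one explicit loop, no vectorised reuse of the package's logic.
brute_force_cells <- function(actual, predicted, w = rep(1, length(actual))) {
  cells <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(actual)) {
    a <- actual[i]
    p <- predicted[i]
    if (a != "other" && p == a) {
      cells["TP"] <- cells["TP"] + w[i]
    } else if (p != "other" && p != a) {
      cells["FP"] <- cells["FP"] + w[i]
    } else if (a != "other" && p == "other") {
      cells["FN"] <- cells["FN"] + w[i]
    } else {
      cells["TN"] <- cells["TN"] + w[i]
    }
  }
  cells
}
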