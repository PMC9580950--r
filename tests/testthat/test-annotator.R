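test_that("length triage is an exhaustive three-way partition", {
  reads <- c(strrep("a", 22L), strrep("c", 28L), strrep("g", 35L))
  tr <- triage_reads(reads)
  expect_equal(tr$mirna_track, reads[1L])
  expect_equal(tr$pirna_track, reads[2L])
  expect_equal(tr$rejected, reads[3L])

  set.seed(17)
  lens <- sample(10:40, 300L, replace = TRUE)
  seqs <- vapply(lens, function(l) strrep("a", l), character(1))
  tr <- triage_reads(seqs)
  expect_equal(
    length(tr$mirna_track) + length(tr$pirna_track) + length(tr$rejected), 300L
  )
  expect_true(all(nchar(tr$mirna_track) %in% 17:24))
  expect_true(all(nchar(tr$pirna_track) %in% 25:31))
  expect_true(all(nchar(tr$rejected) <= 16L | nchar(tr$rejected) >= 32L))
})

test_that("quality filtering drops reads with strictly more than 10% bases under Q20", {
  q40 <- strrep("I", 10L) # Q40
  q19 <- "4" # Phred+33 for Q19
  two_low <- paste0(strrep("I", 8L), q19, q19) # 20% below Q20
  one_low <- paste0(strrep("I", 9L), q19) # exactly 10%: kept
  expect_equal(quality_filter(c(q40, two_low, one_low)), c(TRUE, FALSE, TRUE))
  expect_error(quality_filter(""), "non-empty")
})

test_that("reverse-complement candidates at the known locus are re-annotated and merged", {
  known <- tibble::tibble(
    id = "hsa-mir-6859-3p",
    mature_seq = "tgacccccatgtcgcctctgtag",
    rna_class = "known_miRNA",
    chrom = "chr1", start = 17369L, end = 17391L, strand = "+"
  )
  idx <- build_known_index(known)
  det <- tibble::tibble(
    sequence = c("ctacagaggcgacatgggggtca", "tgacccccatgtcgcctctgtag"),
    label = c("novel-cand-1", "hsa-mir-6859-3p"),
    status = c("novel", "known"),
    chrom = "chr1", start = 17369L, end = 17391L,
    strand = c("-", "+"),
    count = c(7L, 40L)
  )
  out <- reannotate_reverse_complements(det, idx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$label, "hsa-mir-6859-3p")
  expect_equal(out$count, 47L)
  expect_match(out$member_ids, "novel-cand-1")
})

test_that("an RC match at a different locus stays novel; a forward match becomes known", {
  known <- tibble::tibble(
    id = "mir-k", mature_seq = "tgacccccatgtcgcctctgtag",
    rna_class = "known_miRNA",
    chrom = "chr1", start = 1000L, end = 1022L, strand = "+"
  )
  idx <- build_known_index(known)
  det <- tibble::tibble(
    sequence = c("ctacagaggcgacatgggggtca", "tgacccccatgtcgcctctgtag"),
    label = c("cand-elsewhere", "cand-forward"),
    status = "novel",
    chrom = c("chr5", "chr9"), start = c(900L, 1L), end = c(922L, 23L),
    strand = "+", count = c(3L, 4L)
  )
  out <- reannotate_reverse_complements(det, idx)
  expect_equal(out$status[out$label == "cand-elsewhere"], "novel")
  # forward sequence identity needs no locus agreement
  expect_equal(out$status[out$label == "mir-k"], "known")
})

test_that("novel clustering merges identical seeds with close xseed and locus", {
  det <- tibble::tibble(
    sequence = c("tgacccccatgtcgcctctgtag", "tgacccccatgtcgcctctgaag"),
    label = c("n1", "n2"),
    status = "novel",
    chrom = "chr1", start = c(100L, 102L), end = c(122L, 124L),
    strand = "+", count = c(7L, 3L)
  )
  cl <- cluster_novels(det)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$merged_count, 10)
  expect_equal(cl$sequence, "tgacccccatgtcgcctctgtag") # highest-count member
  expect_equal(cl$member_ids, "n1;n2")

  far <- det
  far$start <- c(100L, 600L)
  cl2 <- cluster_novels(far)
  expect_equal(nrow(cl2), 2L)

  single <- cluster_novels(det[1L, ])
  expect_equal(nrow(single), 1L)
  expect_equal(single$merged_count, 7)
})

test_that("clustering is idempotent and conserves counts on random tables", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:10, 1L)
    det <- tibble::tibble(
      sequence = random_seq(n, 20L, 23L),
      label = paste0("cand-", seq_len(n)),
      status = "novel",
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(1:50, n, replace = TRUE),
      end = 0L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      count = sample(1:20, n, replace = TRUE)
    )
    det$end <- det$start + nchar(det$sequence) - 1L
    cl <- cluster_novels(det)
    expect_equal(sum(cl$merged_count), sum(det$count))
    cl2 <- cluster_novels(
      tibble::tibble(
        sequence = cl$sequence, label = cl$label, status = "novel",
        chrom = cl$chrom, start = cl$start, end = cl$end,
        strand = cl$strand, count = cl$merged_count
      )
    )
    expect_equal(nrow(cl2), nrow(cl))
    expect_equal(sum(cl2$merged_count), sum(det$count))
  }
})

test_that("paralogue naming follows the anchor's seed with _n suffixes", {
  known <- tibble::tibble(
    id = "hsa-mir-339",
    mature_seq = "tccctgtcctccaggagctcacg",
    rna_class = "known_miRNA",
    chrom = "chr7", start = 1000L, end = 1022L, strand = "+"
  )
  # same seed (positions 2-8) as hsa-mir-339, different locus and xseed
  clusters <- tibble::tibble(
    sequence = c("tccctgtcctccaggagctc", "accctgtcgtccaggagctc", "ggggggggggggggggggga"),
    label = paste0("novel-cand-", 1:3),
    chrom = c("chr2", "chr3", "chr4"),
    start = c(500L, 700L, 900L),
    end = c(519L, 719L, 919L),
    strand = "+",
    merged_count = c(30, 12, 5),
    member_ids = paste0("novel-cand-", 1:3),
    n_members = 1L
  )
  out <- assign_functional_names(clusters, known)
  expect_equal(out$final_name[out$merged_count == 30], "hsa-mir-339_1")
  expect_equal(out$relation[out$merged_count == 30], "paralogue_of_known")
  expect_equal(out$anchor_id[out$merged_count == 30], "hsa-mir-339")
  expect_equal(out$final_name[out$merged_count == 12], "hsa-mir-339_2")
  expect_equal(out$relation[out$merged_count == 5], "unique_novel")

  # a cluster at the known's own locus is the known miRNA itself
  at_locus <- clusters[1L, ]
  at_locus$chrom <- "chr7"
  at_locus$start <- 1001L
  out2 <- assign_functional_names(at_locus, known)
  expect_equal(out2$relation, "known")
  expect_equal(out2$final_name, "hsa-mir-339")
})

test_that("novel-to-novel paralogues anchor on the first named unique novel", {
  known <- tibble::tibble(
    id = "mir-k", mature_seq = "aaaaaaaaaaaaaaaaaaaaaa",
    rna_class = "known_miRNA", chrom = "chr1",
    start = 10L, end = 31L, strand = "+"
  )
  clusters <- tibble::tibble(
    sequence = c("tgggcctgggactgagaatca", "tgggcctgggactgagactca"),
    label = c("c1", "c2"),
    chrom = c("chr2", "chr6"), start = c(100L, 5000L), end = c(120L, 5020L),
    strand = "+", merged_count = c(50, 10),
    member_ids = c("c1", "c2"), n_members = 1L
  )
  out <- assign_functional_names(clusters, known)
  expect_equal(out$final_name[1L], "novel-mir-1")
  expect_equal(out$relation[2L], "paralogue_of_novel")
  expect_equal(out$final_name[2L], "novel-mir-1_1")
  expect_equal(out$anchor_id[2L], "novel-mir-1")
})

test_that("naming is invariant to input row order", {
  known <- tibble::tibble(
    id = "mir-k", mature_seq = "tccctgtcctccaggagctcacg",
    rna_class = "known_miRNA", chrom = "chr7",
    start = 1000L, end = 1022L, strand = "+"
  )
  clusters <- tibble::tibble(
    sequence = c("tccctgtcctccaggagctc", "accctgtcgtccaggagctc", "ggggggggggggggggggga"),
    label = paste0("c", 1:3),
    chrom = c("chr2", "chr3", "chr4"), start = c(500L, 700L, 900L),
    end = c(519L, 719L, 919L), strand = "+",
    merged_count = c(30, 12, 5), member_ids = paste0("c", 1:3), n_members = 1L
  )
  a <- assign_functional_names(clusters, known)
  b <- assign_functional_names(clusters[c(3, 1, 2), ], known)
  expect_equal(
    a[order(a$label), c("label", "final_name", "relation", "anchor_id")],
    b[order(b$label), c("label", "final_name", "relation", "anchor_id")]
  )
})

test_that("deduplication collapses identical sequences keeping one count and all loci", {
  ct <- tibble::tibble(
    name = c("mir-x", "mir-x-copy", "mir-y"),
    sequence = c("tgacccccatgtcgcctctgtag", "tgacccccatgtcgcctctgtag", "acgtacgtacgtacgtacgtac"),
    chrom = c("chr1", "chr9", "chr2"),
    start = c(100L, 900L, 50L), end = c(122L, 922L, 71L),
    strand = "+", count = c(12L, 12L, 7L)
  )
  out <- deduplicate_counts(ct)
  expect_equal(nrow(out), 2L)
  dup <- out[out$n_loci == 2L, ]
  expect_equal(dup$count, 12)
  expect_match(dup$loci, "chr1:100-122\\(\\+\\);chr9:900-922\\(\\+\\)")

  distinct <- deduplicate_counts(ct[c(1L, 3L), ])
  expect_equal(nrow(distinct), 2L)
  expect_equal(distinct$count, c(12, 7))

  ct$count <- c(12L, 9L, 7L)
  expect_warning(out2 <- deduplicate_counts(ct), "keeping the maximum")
  expect_equal(out2$count[out2$n_loci == 2L], 12)
})

test_that("novel renaming honours external identifiers and stars every name", {
  res <- tibble::tibble(
    sequence = c("tgacccccatgtcgcctctgtag", "acgtacgtacgtacgtacgtac"),
    final_name = c("novel-mir-1", "novel-mir-2")
  )
  ext <- tibble::tibble(sequence = "tgacccccatgtcgcctctgtag", identifier = "mmu-mir-99")
  out <- rename_novels(res, ext)
  expect_equal(out$final_name, c("mmu-mir-99*", "novel-mir-2*"))

  blank <- tibble::tibble(sequence = res$sequence, final_name = c("", ""))
  out2 <- rename_novels(blank)
  expect_equal(out2$final_name, c("novel-mir-1*", "novel-mir-2*"))
  expect_true(all(endsWith(out2$final_name, "*")))

  expect_equal(nrow(rename_novels(res[0, ])), 0L)
  dup_ext <- tibble::tibble(sequence = res$sequence, identifier = c("x", "x"))
  expect_error(rename_novels(res, dup_ext), "duplicate identifiers")
})

test_that("detections fabricated from a simulation truth table annotate to their true classes", {
  ref <- make_fixtures(15, 8, 5, 3, rng_seed = 12)
  cfg <- sim_config(total_reads = 4000L, rng_seed = 19)
  sim <- simulate_reads(cfg, ref)
  truth <- sim$truth
  known <- ref[ref$rna_class == "known_miRNA", ]

  mirna_rows <- truth[truth$rna_class %in% c("known_miRNA", "novel_miRNA"), ]
  det <- tibble::tibble(
    sequence = mirna_rows$sequence,
    label = mirna_rows$molecule_name,
    status = ifelse(mirna_rows$rna_class == "known_miRNA", "known", "novel"),
    chrom = mirna_rows$chrom, start = mirna_rows$start,
    end = mirna_rows$end, strand = mirna_rows$strand,
    count = mirna_rows$expression_count
  )
  out <- annotate_detections(det, known)
  expect_equal(sum(out$merged_count), sum(det$count))
  known_names <- out$final_name[out$status == "known"]
  expect_true(all(known_names %in% known$id))
  expect_equal(sort(known_names), sort(mirna_rows$molecule_name[mirna_rows$rna_class == "known_miRNA"]))
  expect_equal(sum(out$status == "novel"), sum(mirna_rows$rna_class == "novel_miRNA"))
})
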