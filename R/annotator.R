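#' Triage reads into miRNA / piRNA / rejected tracks by insert length
#'
#' Post adapter removal, insert length alone decides the processing track:
#' 17-24 nt reads go to miRNA identification, 25-31 nt reads to piRNA
#' identification, and everything else (>= 32 nt, or <= 16 nt, too short to
#' be a mature miRNA) is rejected. The partition is exhaustive and disjoint.
#'
#' @param reads Character vector of insert sequences, or a data.frame with a
#'   `sequence` column.
#' @return A list with elements `mirna_track`, `pirna_track`, `rejected`,
#'   each the same type as the input subset.
#' @export
triage_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  len <- nchar(seqs)
  bin <- ifelse(len >= 17L & len <= 24L, "mirna",
    ifelse(len >= 25L & len <= 31L, "pirna", "rejected")
  )
  pick <- function(which) {
    if (is.data.frame(reads)) reads[bin == which, , drop = FALSE] else reads[bin == which]
  }
  list(
    mirna_track = pick("mirna"),
    pirna_track = pick("pirna"),
    rejected = pick("rejected")
  )
}

#' Filter reads on the fraction of low-quality bases
#'
#' A read is dropped when strictly more than `max_low_fraction` of its bases
#' have a Phred score below `q_threshold` (defaults: more than 10% of bases
#' below Q20). A read with exactly the threshold fraction is kept.
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @param max_low_fraction Maximum tolerated fraction of low-quality bases.
#' @param q_threshold Phred score below which a base counts as low quality.
#' @return Logical vector: `TRUE` to keep, `FALSE` to drop.
#' @export
quality_filter <- function(quality, max_low_fraction = 0.10, q_threshold = 20L) {
  if (length(quality) == 0L) {
    return(logical(0))
  }
  vapply(quality, function(q) {
    scores <- phred_scores(q)
    mean(scores < q_threshold) <= max_low_fraction
  }, logical(1), USE.NAMES = FALSE)
}

#' Build a known-sequence lookup index
#'
#' Local index over known mature sequences supporting exact forward lookup
#' and reverse-complement queries, used in place of a remote annotation-
#' database search so that re-annotation is deterministic and runs offline.
#'
#' @param reference_set Reference tibble (typically the known-miRNA subset).
#' @return An object of class `known_index`.
#' @export
build_known_index <- function(reference_set) {
  stopifnot(nrow(reference_set) > 0L)
  ref <- reference_set
  ref$mature_seq <- normalize_seq(ref$mature_seq)
  structure(
    list(
      by_seq = split(seq_len(nrow(ref)), ref$mature_seq),
      ref = ref
    ),
    class = "known_index"
  )
}

known_lookup <- function(index, seq) {
  hit <- index$by_seq[[normalize_seq(seq)]]
  if (is.null(hit)) NULL else index$ref[hit, , drop = FALSE]
}

#' Re-annotate reverse-complement novel candidates as known miRNAs
#'
#' Candidates labelled novel are checked against the known index: a candidate
#' whose forward sequence equals a known mature sequence becomes that known
#' miRNA directly; otherwise, if its reverse complement equals a known mature
#' sequence *at the same genomic location* (same chromosome and coordinates;
#' the strand is ignored because a reverse-complemented read maps to the
#' opposite strand of the same locus), the candidate is relabelled to that
#' known miRNA and its count merged. Candidates matching neither stay novel.
#'
#' Rows relabelled to the same known id (including pre-existing known rows
#' with that id) are merged into one row with summed counts; the
#' `member_ids` column records which input labels were merged.
#'
#' @param detections Tibble with columns `sequence`, `label`, `status`
#'   (`"known"`/`"novel"`), `chrom`, `start`, `end`, `strand`, `count`.
#' @param known_index A [build_known_index()] object.
#' @return The updated detections tibble with a `member_ids` column
#'   (`;`-separated input labels).
#' @export
reannotate_reverse_complements <- function(detections, known_index) {
  stopifnot(inherits(known_index, "known_index"))
  det <- tibble::as_tibble(detections)
  det$sequence <- normalize_seq(det$sequence)
  if (!"member_ids" %in% names(det)) det$member_ids <- det$label

  for (i in seq_len(nrow(det))) {
    if (det$status[i] != "novel") next
    fwd <- known_lookup(known_index, det$sequence[i])
    if (!is.null(fwd)) {
      det$label[i] <- fwd$id[1L]
      det$status[i] <- "known"
      next
    }
    rc_hit <- known_lookup(known_index, reverse_complement(det$sequence[i]))
    if (!is.null(rc_hit)) {
      same_locus <- rc_hit$chrom == det$chrom[i] &
        rc_hit$start == det$start[i] & rc_hit$end == det$end[i]
      if (any(same_locus)) {
        hit <- rc_hit[same_locus, ][1L, ]
        det$label[i] <- hit$id
        det$status[i] <- "known"
        det$sequence[i] <- hit$mature_seq
        det$start[i] <- hit$start
        det$end[i] <- hit$end
        det$strand[i] <- hit$strand
      }
    }
  }

  known <- det[det$status == "known", , drop = FALSE]
  novel <- det[det$status == "novel", , drop = FALSE]
  if (nrow(known) > 1L && anyDuplicated(known$label)) {
    sp <- split(seq_len(nrow(known)), factor(known$label, levels = unique(known$label)))
    known <- dplyr::bind_rows(lapply(sp, function(idx) {
      m <- known[idx, , drop = FALSE]
      merged <- m[1L, ]
      merged$count <- sum(m$count)
      merged$member_ids <- paste(m$member_ids, collapse = ";")
      merged
    }))
  }
  dplyr::bind_rows(known, novel)
}

#' Cluster novel detections on seed identity, xseed similarity and locus
#'
#' Two novel detections belong to the same cluster when their seed sequences
#' are identical (zero mismatch), their xseed regions differ by at most 2 nt
#' (Hamming; unequal lengths never merge), and they map to similar genomic
#' locations: same chromosome and strand with start positions at most 2 nt
#' apart. Merging is the transitive closure over these pairs; member counts
#' are summed and the representative is the highest-count member (ties:
#' smallest start, then lexicographically smallest sequence).
#'
#' @param detections Tibble with `sequence`, `label`, `chrom`, `start`,
#'   `end`, `strand`, `count` (novel candidates).
#' @param seed_range 1-based inclusive seed positions (default 2-8).
#' @param max_xseed_diff Maximum xseed Hamming distance within a cluster.
#' @param max_locus_diff Maximum start-position difference within a cluster.
#' @return A tibble with one row per cluster: representative `sequence`,
#'   `label`, locus columns, `merged_count`, `member_ids`, `n_members`.
#' @export
cluster_novels <- function(detections, seed_range = c(2L, 8L),
                           max_xseed_diff = 2L, max_locus_diff = 2L) {
  det <- tibble::as_tibble(detections)
  if (nrow(det) == 0L) {
    return(tibble::tibble(
      sequence = character(), label = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      merged_count = numeric(), member_ids = character(), n_members = integer()
    ))
  }
  det$sequence <- normalize_seq(det$sequence)
  seeds <- seed_of(det$sequence, seed_range)
  xseeds <- xseed_of(det$sequence, seed_range)

  n <- nrow(det)
  edges <- list()
  # candidate pairs only within identical-seed groups on one chromosome/strand
  grp <- split(seq_len(n), paste(seeds, det$chrom, det$strand, sep = "\r"))
  for (idx in grp) {
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq.int(a + 1L, length(idx))) {
        i <- idx[a]
        j <- idx[b]
        if (abs(det$start[i] - det$start[j]) <= max_locus_diff &&
          hamming_distance(xseeds[i], xseeds[j]) <= max_xseed_diff) {
          edges[[length(edges) + 1L]] <- c(i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, unlist(edges))
  }
  comp <- igraph::components(g)$membership

  out <- lapply(split(seq_len(n), comp), function(members) {
    m <- det[members, , drop = FALSE]
    rep_i <- order(-m$count, m$start, m$sequence)[1L]
    tibble::tibble(
      sequence = m$sequence[rep_i],
      label = m$label[rep_i],
      chrom = m$chrom[rep_i],
      start = m$start[rep_i],
      end = m$end[rep_i],
      strand = m$strand[rep_i],
      merged_count = sum(m$count),
      member_ids = paste(m$label[order(m$start, m$label)], collapse = ";"),
      n_members = nrow(m)
    )
  })
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$start, res$sequence), ]
}

#' Functionally annotate novel clusters against known and novel seeds
#'
#' A cluster sharing a known miRNA's seed at the same locus is that known
#' miRNA. A cluster sharing a known miRNA's seed at a *different* locus is a
#' paralogue of that known miRNA, named `<known>_n`; one sharing the seed of
#' an already-named unique novel miRNA at a different locus is named
#' `<novel>_n`. Seeds matching no anchor yield unique novel miRNAs named
#' sequentially (`novel-mir-1`, ...). Paralogue indices `n` are assigned in
#' descending merged-count order (ties by chromosome then start) so the
#' naming is reproducible for any input row order.
#'
#' @param clusters Cluster tibble from [cluster_novels()].
#' @param known_set Reference tibble of known miRNAs (`id`, `mature_seq`,
#'   `chrom`, `start`, `strand`).
#' @param seed_range 1-based inclusive seed positions.
#' @param max_locus_diff Start-position tolerance for "same locus".
#' @return A tibble with `final_name`, `relation` (`known`,
#'   `paralogue_of_known`, `paralogue_of_novel`, `unique_novel`),
#'   `anchor_id`, `merged_count`, `member_ids`, plus the cluster columns.
#' @export
assign_functional_names <- function(clusters, known_set,
                                    seed_range = c(2L, 8L),
                                    max_locus_diff = 2L) {
  cl <- tibble::as_tibble(clusters)
  if (nrow(cl) == 0L) {
    cl$final_name <- character(0)
    cl$relation <- character(0)
    cl$anchor_id <- character(0)
    return(cl)
  }
  ord <- order(-cl$merged_count, cl$chrom, cl$start, cl$sequence)
  cl <- cl[ord, ]
  cl_seed <- seed_of(cl$sequence, seed_range)

  known_seed <- seed_of(normalize_seq(known_set$mature_seq), seed_range)

  final_name <- character(nrow(cl))
  relation <- character(nrow(cl))
  anchor_id <- character(nrow(cl))
  paralogue_n <- new.env(parent = emptyenv())
  novel_anchors <- list() # seed -> list(id, chrom, start)
  n_unique <- 0L

  next_n <- function(anchor) {
    k <- (if (is.null(paralogue_n[[anchor]])) 0L else paralogue_n[[anchor]]) + 1L
    paralogue_n[[anchor]] <- k
    k
  }
  same_locus <- function(chrom_a, start_a, chrom_b, start_b) {
    chrom_a == chrom_b & abs(start_a - start_b) <= max_locus_diff
  }

  for (i in seq_len(nrow(cl))) {
    hits <- which(known_seed == cl_seed[i])
    if (length(hits) > 0L) {
      at_locus <- hits[same_locus(
        known_set$chrom[hits], known_set$start[hits], cl$chrom[i], cl$start[i]
      )]
      if (length(at_locus) > 0L) {
        anchor <- known_set$id[at_locus[1L]]
        final_name[i] <- anchor
        relation[i] <- "known"
        anchor_id[i] <- anchor
      } else {
        anchor <- known_set$id[hits[1L]]
        final_name[i] <- paste0(anchor, "_", next_n(anchor))
        relation[i] <- "paralogue_of_known"
        anchor_id[i] <- anchor
      }
      next
    }
    nov <- novel_anchors[[cl_seed[i]]]
    if (!is.null(nov) &&
      !same_locus(nov$chrom, nov$start, cl$chrom[i], cl$start[i])) {
      final_name[i] <- paste0(nov$id, "_", next_n(nov$id))
      relation[i] <- "paralogue_of_novel"
      anchor_id[i] <- nov$id
      next
    }
    n_unique <- n_unique + 1L
    id <- paste0("novel-mir-", n_unique)
    final_name[i] <- id
    relation[i] <- "unique_novel"
    anchor_id[i] <- ""
    if (is.null(nov)) {
      novel_anchors[[cl_seed[i]]] <- list(id = id, chrom = cl$chrom[i], start = cl$start[i])
    }
  }
  cl$final_name <- final_name
  cl$relation <- relation
  cl$anchor_id <- anchor_id
  cl
}

#' Deduplicate a final count table on identical mature sequences
#'
#' Identical mature sequences reported at multiple genomic loci are the same
#' molecule listed once per locus with the same expression count; such rows
#' collapse to a single row whose `loci` column lists every locus
#' (`chrom:start-end(strand)`, `;`-separated) and whose count is taken once
#' (not summed). If duplicated sequences carry unequal counts the input is
#' inconsistent: the maximum is kept and a warning raised.
#'
#' @param count_table Tibble with `name`, `sequence`, `chrom`, `start`,
#'   `end`, `strand`, `count`.
#' @return Deduplicated tibble with columns `name`, `sequence`, `count`,
#'   `loci`, `n_loci`.
#' @export
deduplicate_counts <- function(count_table) {
  ct <- tibble::as_tibble(count_table)
  if (nrow(ct) == 0L) {
    return(tibble::tibble(
      name = character(), sequence = character(), count = numeric(),
      loci = character(), n_loci = integer()
    ))
  }
  ct$sequence <- normalize_seq(ct$sequence)
  groups <- split(seq_len(nrow(ct)), ct$sequence)
  inconsistent <- character(0)
  out <- lapply(groups, function(idx) {
    m <- ct[idx[order(ct$chrom[idx], ct$start[idx])], , drop = FALSE]
    if (length(unique(m$count)) > 1L) {
      inconsistent <<- c(inconsistent, m$name[1L])
    }
    tibble::tibble(
      name = m$name[1L],
      sequence = m$sequence[1L],
      count = max(m$count),
      loci = paste0(
        m$chrom, ":", m$start, "-", m$end, "(", m$strand, ")",
        collapse = ";"
      ),
      n_loci = nrow(m)
    )
  })
  if (length(inconsistent) > 0L) {
    warning(
      "unequal counts for identical sequence(s); keeping the maximum: ",
      paste(inconsistent, collapse = ", "),
      call. = FALSE
    )
  }
  res <- dplyr::bind_rows(out)
  res[order(match(res$sequence, ct$sequence)), ]
}

#' Rename novel miRNAs, honouring externally annotated identifiers
#'
#' Novel results whose sequence appears in a user-supplied external
#' identifier table (sequence -> identifier, standing in for a cross-organism
#' homology search) take that identifier; the rest keep their functional name
#' or, lacking one, are named sequentially. Every final novel name receives a
#' `"*"` suffix marking it as putative.
#'
#' @param novel_results Tibble with at least `sequence` and `final_name`.
#' @param external_id_map Optional tibble with columns `sequence`,
#'   `identifier`; identifiers must be unique.
#' @return The input with `final_name` replaced by the renamed, `*`-suffixed
#'   names.
#' @export
rename_novels <- function(novel_results, external_id_map = NULL) {
  res <- tibble::as_tibble(novel_results)
  if (nrow(res) == 0L) {
    return(res)
  }
  if (!"final_name" %in% names(res)) res$final_name <- NA_character_
  res$sequence <- normalize_seq(res$sequence)
  mapped <- rep(NA_character_, nrow(res))
  if (!is.null(external_id_map) && nrow(external_id_map) > 0L) {
    if (anyDuplicated(external_id_map$identifier)) {
      stop("duplicate identifiers in external_id_map", call. = FALSE)
    }
    idx <- match(res$sequence, normalize_seq(external_id_map$sequence))
    mapped <- external_id_map$identifier[idx]
  }
  need_seq <- is.na(mapped) & (is.na(res$final_name) | res$final_name == "")
  res$final_name[need_seq] <- paste0("novel-mir-", cumsum(need_seq)[need_seq])
  res$final_name[!is.na(mapped)] <- mapped[!is.na(mapped)]
  res$final_name <- paste0(res$final_name, "*")
  res
}
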