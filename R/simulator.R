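#' Apportion an integer total proportionally to weights
#'
#' Largest-remainder (Hamilton) apportionment: each share is the floor of its
#' exact quota, and leftover units go to the largest fractional remainders
#' (ties broken by position). The result always sums exactly to `total`.
#'
#' @param total Non-negative integer to distribute.
#' @param weights Non-negative numeric weights, at least one positive.
#' @return Integer vector of the same length (and names) as `weights`.
#' @export
apportion_largest_remainder <- function(total, weights) {
  total <- as.integer(total)
  if (total < 0L) stop("total must be non-negative", call. = FALSE)
  if (length(weights) == 0L || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  quota <- total * weights / sum(weights)
  out <- floor(quota)
  left <- total - sum(out)
  if (left > 0L) {
    rem <- quota - out
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    out[take] <- out[take] + 1L
  }
  stats::setNames(as.integer(out), names(weights))
}

#' Allocate a read budget across chromosomes
#'
#' Reads are distributed directly proportionally to the number of reference
#' molecules on each chromosome, with largest-remainder rounding so the
#' budgets sum exactly to `total_reads`.
#'
#' @param total_reads Positive integer read budget.
#' @param reference_set Reference tibble as from [load_reference()].
#' @return Named integer vector, one entry per chromosome (sorted).
#' @export
allocate_reads_per_chromosome <- function(total_reads, reference_set) {
  if (is.null(reference_set) || nrow(reference_set) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  if (total_reads <= 0L) stop("total_reads must be positive", call. = FALSE)
  counts <- table(reference_set$chrom)
  counts <- counts[order(names(counts))]
  apportion_largest_remainder(total_reads, as.numeric(counts)) |>
    stats::setNames(names(counts))
}

#' Draw per-molecule expression counts
#'
#' Counts come from the configured distribution (Poisson or gamma); gamma
#' draws are rounded half-up to integers. Any draw below `min_depth` is
#' raised to `min_depth` so every molecule reaches the expression floor.
#'
#' @param molecule_count Number of molecules to draw for.
#' @param distribution `list(kind = "poisson", mean = ...)` or
#'   `list(kind = "gamma", shape = ..., scale = ...)`.
#' @param min_depth Expression floor (reads per molecule).
#' @return Integer vector of length `molecule_count`.
#' @export
draw_expression_profile <- function(molecule_count, distribution, min_depth = 1L) {
  if (molecule_count < 0L) stop("molecule_count must be >= 0", call. = FALSE)
  if (molecule_count == 0L) {
    return(integer(0))
  }
  if (identical(distribution$kind, "poisson")) {
    if (is.null(distribution$mean) || distribution$mean <= 0) {
      stop("poisson distribution needs a positive mean", call. = FALSE)
    }
    draws <- stats::rpois(molecule_count, distribution$mean)
  } else if (identical(distribution$kind, "gamma")) {
    if (is.null(distribution$shape) || is.null(distribution$scale) ||
      distribution$shape <= 0 || distribution$scale <= 0) {
      stop("gamma distribution needs positive shape and scale", call. = FALSE)
    }
    draws <- floor(stats::rgamma(
      molecule_count, shape = distribution$shape, scale = distribution$scale
    ) + 0.5)
  } else {
    stop("distribution kind must be 'poisson' or 'gamma'", call. = FALSE)
  }
  as.integer(pmax(draws, min_depth))
}

#' Generate a decoy sequence by altering seed and/or xseed bases
#'
#' Substitutes exactly `n_alterations` bases inside each targeted region
#' (seed, xseed, or both) with different bases, leaving the untargeted region
#' untouched. The result has the same length as the input and a Hamming
#' distance of `n_alterations` to it inside each altered region; such a
#' sequence is no longer a valid miRNA/piRNA and serves as a true negative.
#'
#' @param seq Source mature sequence.
#' @param mode One of `"seed"`, `"xseed"`, `"both"`.
#' @param n_alterations Substitutions per targeted region (>= 2).
#' @param seed_range 1-based inclusive seed positions.
#' @return The altered sequence, lower-case.
#' @export
generate_altered_sequence <- function(seq, mode, n_alterations = 2L,
                                      seed_range = c(2L, 8L)) {
  mode <- match.arg(mode, c("seed", "xseed", "both"))
  if (n_alterations < 2L) stop("n_alterations must be >= 2", call. = FALSE)
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (seed_range[2L] > n) {
    stop("seed_range exceeds sequence length", call. = FALSE)
  }
  seed_pos <- seq.int(seed_range[1L], seed_range[2L])
  xseed_pos <- setdiff(seq_len(n), seed_pos)
  targets <- switch(mode,
    seed = list(seed_pos),
    xseed = list(xseed_pos),
    both = list(seed_pos, xseed_pos)
  )
  bases <- strsplit(seq, "")[[1L]]
  alphabet <- c("a", "c", "g", "t")
  for (pos_set in targets) {
    if (length(pos_set) < n_alterations) {
      stop(
        "targeted region (", length(pos_set), " nt) shorter than n_alterations (",
        n_alterations, ")",
        call. = FALSE
      )
    }
    alter <- if (length(pos_set) == 1L) pos_set else sample(pos_set, n_alterations)
    for (p in alter) {
      bases[p] <- sample(setdiff(alphabet, bases[p]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Assemble a fixed-length sequencing read from a mature sequence
#'
#' The read starts with the mature sequence verbatim, followed by the 3'
#' adapter and then the primer repeated as filler, truncated to exactly
#' `read_length` nt. With empty adapter and primer, poly-A filler is used.
#'
#' @param mature_seq Character vector of mature sequences.
#' @param adapter_seq,primer_seq Adapter and primer strings (may be empty).
#' @param read_length Final read length (default 75).
#' @return Character vector of reads, each exactly `read_length` nt.
#' @export
assemble_read <- function(mature_seq,
                          adapter_seq = "tggaattctcgggtgccaagg",
                          primer_seq = "gttcagagttctacagtccgacgatc",
                          read_length = 75L) {
  mature_seq <- normalize_seq(mature_seq)
  adapter_seq <- if (nzchar(adapter_seq)) normalize_seq(adapter_seq) else ""
  primer_seq <- if (nzchar(primer_seq)) normalize_seq(primer_seq) else ""
  too_long <- nchar(mature_seq) > read_length
  if (any(too_long)) {
    stop(
      "mature sequence longer than read_length (", read_length, " nt): ",
      paste(utils::head(mature_seq[too_long], 3L), collapse = ", "),
      call. = FALSE
    )
  }
  unit <- if (nzchar(primer_seq)) {
    primer_seq
  } else if (nzchar(adapter_seq)) {
    adapter_seq
  } else {
    "a"
  }
  reps <- ceiling(read_length / nchar(unit)) + 1L
  tail_seq <- paste0(adapter_seq, strrep(unit, reps))
  substr(paste0(mature_seq, tail_seq), 1L, read_length)
}

#' Simulate a synthetic small RNA-seq read set with ground truth
#'
#' Emits `total_reads` FASTQ records drawn from the configured mixture of
#' unaltered known miRNAs, novel miRNAs, known piRNAs, and altered decoys,
#' plus a ground-truth table with one row per molecule. Reads are distributed
#' across chromosomes proportionally to the number of references per
#' chromosome; molecules are sampled without replacement per chromosome and
#' receive expression counts from the configured distribution, floored at
#' `min_depth`. The run is fully determined by `config$rng_seed`.
#'
#' In `rc_mode`, the mixture model is bypassed: every reference contributes
#' the reverse complement of its mature sequence at a fixed depth of
#' `config$min_depth` reads, the benchmark design used to probe whether
#' pipelines recover reverse-complemented known miRNAs.
#'
#' @param config A [sim_config()] object.
#' @param reference_set Reference tibble from [load_reference()] or
#'   [make_fixtures()].
#' @return A list with elements `reads` (tibble `id`, `sequence`, `quality`)
#'   and `truth` (ground-truth tibble; see [write_truth()] for columns).
#' @export
simulate_reads <- function(config, reference_set) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference_set) || nrow(reference_set) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  set.seed(config$rng_seed)

  truth <- if (config$rc_mode) {
    simulate_rc_truth(config, reference_set)
  } else {
    simulate_mixture_truth(config, reference_set)
  }

  reads_per_mol <- assemble_read(
    truth$sequence, config$adapter_seq, config$primer_seq, config$read_length
  )
  rep_idx <- rep.int(seq_len(nrow(truth)), truth$expression_count)
  read_no <- sequence(truth$expression_count)
  reads <- tibble::tibble(
    id = paste0(truth$molecule_name[rep_idx], "_", read_no),
    sequence = reads_per_mol[rep_idx],
    quality = strrep(config$quality_char, config$read_length)
  )
  list(reads = reads, truth = truth)
}

simulate_rc_truth <- function(config, reference_set) {
  ref <- reference_set[order(reference_set$chrom, reference_set$start, reference_set$id), ]
  tibble::tibble(
    molecule_name = paste0(ref$id, "-rc"),
    rna_class = ref$rna_class,
    sequence = reverse_complement(ref$mature_seq),
    chrom = ref$chrom,
    start = ref$start,
    end = ref$end,
    strand = ifelse(ref$strand == "+", "-", "+"),
    expression_count = as.integer(config$min_depth),
    cigar = paste0(nchar(ref$mature_seq), "M"),
    source_id = ref$id,
    alteration_mode = "none"
  )
}

simulate_mixture_truth <- function(config, reference_set) {
  pct_other <- 100 - config$pct_known_mirna - config$pct_novel_mirna -
    config$pct_pirna
  class_budget <- apportion_largest_remainder(
    config$total_reads,
    c(
      known_miRNA = config$pct_known_mirna,
      novel_miRNA = config$pct_novel_mirna,
      known_piRNA = config$pct_pirna,
      other = pct_other
    )
  )

  rows <- list()
  for (cls in c("known_miRNA", "novel_miRNA", "known_piRNA")) {
    budget <- class_budget[[cls]]
    if (budget == 0L) next
    refs <- reference_set[reference_set$rna_class == cls, ]
    if (nrow(refs) == 0L) {
      stop("requested reads for class ", cls, " but no references of that class",
        call. = FALSE
      )
    }
    rows[[cls]] <- simulate_class_molecules(refs, budget, config, decoy = FALSE)
  }
  if (class_budget[["other"]] > 0L) {
    src <- reference_set[
      reference_set$rna_class %in% c("known_miRNA", "known_piRNA"),
    ]
    if (nrow(src) == 0L) {
      stop("decoy reads requested but no miRNA/piRNA references to alter",
        call. = FALSE
      )
    }
    rows[["other"]] <- simulate_class_molecules(
      src, class_budget[["other"]], config,
      decoy = TRUE
    )
  }
  truth <- dplyr::bind_rows(rows)
  stopifnot(sum(truth$expression_count) == config$total_reads)
  truth
}

# Select molecules for one class and assign expression counts that sum exactly
# to the class read budget. Molecules are drawn without replacement per
# chromosome; the final molecule absorbs the budget tail so no molecule (other
# than a tail in an under-budgeted chromosome) falls below min_depth.
simulate_class_molecules <- function(refs, budget, config, decoy = FALSE) {
  chrom_budget <- allocate_reads_per_chromosome(budget, refs)
  chrom_budget <- chrom_budget[chrom_budget > 0L]
  out <- vector("list", length(chrom_budget))
  for (k in seq_along(chrom_budget)) {
    chrom <- names(chrom_budget)[k]
    b <- chrom_budget[[k]]
    pool <- refs[refs$chrom == chrom, ]
    pool <- pool[sample.int(nrow(pool)), ]
    draws <- draw_expression_profile(nrow(pool), config$distribution, config$min_depth)
    counts <- integer(0)
    used <- 0L
    remaining <- b
    while (remaining > 0L && used < nrow(pool)) {
      used <- used + 1L
      ct <- draws[used]
      if (ct >= remaining || remaining - ct < config$min_depth) {
        ct <- remaining
      }
      counts[used] <- ct
      remaining <- remaining - ct
    }
    if (remaining > 0L) {
      # reference pool exhausted: spread the leftover over selected molecules
      bump <- apportion_largest_remainder(remaining, rep(1, used))
      counts <- counts + bump
    }
    sel <- pool[seq_len(used), ]
    out[[k]] <- if (decoy) {
      decoy_rows(sel, counts, config)
    } else {
      tibble::tibble(
        molecule_name = sel$id,
        rna_class = sel$rna_class,
        sequence = sel$mature_seq,
        chrom = sel$chrom,
        start = sel$start,
        end = sel$end,
        strand = sel$strand,
        expression_count = counts,
        cigar = paste0(nchar(sel$mature_seq), "M"),
        source_id = "",
        alteration_mode = "none"
      )
    }
  }
  dplyr::bind_rows(out)
}

decoy_rows <- function(sel, counts, config) {
  n <- nrow(sel)
  mode_counts <- apportion_largest_remainder(n, config$error_profile)
  modes <- rep(names(config$error_profile), mode_counts)[sample.int(n)]
  altered <- character(n)
  for (i in seq_len(n)) {
    altered[i] <- generate_altered_sequence(
      sel$mature_seq[i], modes[i], config$n_alterations, config$seed_range
    )
  }
  tibble::tibble(
    molecule_name = paste0(sel$id, "-alt", seq_len(n)),
    rna_class = "other",
    sequence = altered,
    chrom = sel$chrom,
    start = sel$start,
    end = sel$end,
    strand = sel$strand,
    expression_count = counts,
    cigar = paste0(nchar(altered), "M"),
    source_id = sel$id,
    alteration_mode = modes
  )
}
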