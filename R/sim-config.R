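#' Simulation configuration
#'
#' Builds and validates the full set of simulator knobs. Percentages are
#' read-level shares of the total; whatever is left after the three named
#' classes becomes the decoy ("other") share: altered copies of real
#' miRNA/piRNA sequences that a correct pipeline must reject.
#'
#' @param total_reads Total number of FASTQ records to emit.
#' @param pct_known_mirna,pct_novel_mirna,pct_pirna Percentages of reads drawn
#'   from unaltered known miRNAs, novel miRNAs, and known piRNAs. Must sum to
#'   at most 100; the remainder is the decoy share.
#' @param error_profile Named numeric vector with entries `seed`, `xseed`,
#'   `both` giving the fraction of decoy molecules altered in each region;
#'   must sum to 1.
#' @param min_depth Minimum reads per non-decoy molecule (expression floor).
#' @param distribution Expression profile distribution: `list(kind =
#'   "poisson", mean = ...)` or `list(kind = "gamma", shape = ..., scale =
#'   ...)`.
#' @param read_length Final read length in nt after adapter/primer padding.
#' @param adapter_seq 3' adapter appended to the mature sequence (default:
#'   Illumina TruSeq small-RNA 3' adapter).
#' @param primer_seq Primer used as repeated filler after the adapter.
#' @param quality_char Single Phred+33 character used for every base (default
#'   `"I"`, Q40).
#' @param rc_mode If `TRUE`, emit the reverse complement of every reference at
#'   a fixed per-reference depth of `min_depth` instead of the mixture model.
#' @param n_alterations Exact number of substitutions per targeted region for
#'   decoys (minimum 2: within the mismatch tolerance of common aligners,
#'   altered reads still resemble their source).
#' @param seed_range 1-based inclusive seed-region positions, default 2-8.
#' @param rng_seed Integer seed; identical configs give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(total_reads = 50000L,
                       pct_known_mirna = 40,
                       pct_novel_mirna = 20,
                       pct_pirna = 20,
                       error_profile = c(seed = 1 / 3, xseed = 1 / 3, both = 1 / 3),
                       min_depth = 10L,
                       distribution = list(kind = "poisson", mean = 50),
                       read_length = 75L,
                       adapter_seq = "tggaattctcgggtgccaagg",
                       primer_seq = "gttcagagttctacagtccgacgatc",
                       quality_char = "I",
                       rc_mode = FALSE,
                       n_alterations = 2L,
                       seed_range = c(2L, 8L),
                       rng_seed = 1L) {
  cfg <- list(
    total_reads = as.integer(total_reads),
    pct_known_mirna = pct_known_mirna,
    pct_novel_mirna = pct_novel_mirna,
    pct_pirna = pct_pirna,
    error_profile = error_profile,
    min_depth = as.integer(min_depth),
    distribution = distribution,
    read_length = as.integer(read_length),
    adapter_seq = if (nzchar(adapter_seq)) normalize_seq(adapter_seq) else "",
    primer_seq = if (nzchar(primer_seq)) normalize_seq(primer_seq) else "",
    quality_char = quality_char,
    rc_mode = isTRUE(rc_mode),
    n_alterations = as.integer(n_alterations),
    seed_range = as.integer(seed_range),
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pcts <- c(cfg$pct_known_mirna, cfg$pct_novel_mirna, cfg$pct_pirna)
  if (any(pcts < 0) || any(pcts > 100) || sum(pcts) > 100 + 1e-9) {
    stop("class percentages must lie in [0, 100] and sum to at most 100",
      call. = FALSE
    )
  }
  if (cfg$total_reads <= 0L) {
    stop("total_reads must be positive", call. = FALSE)
  }
  ep <- cfg$error_profile
  if (!all(c("seed", "xseed", "both") %in% names(ep)) ||
    any(ep < 0) || abs(sum(ep) - 1) > 1e-9) {
    stop("error_profile needs non-negative seed/xseed/both fractions summing to 1",
      call. = FALSE
    )
  }
  if (cfg$min_depth < 1L) {
    stop("min_depth must be >= 1", call. = FALSE)
  }
  dist <- cfg$distribution
  if (identical(dist$kind, "poisson")) {
    if (is.null(dist$mean) || dist$mean <= 0) {
      stop("poisson distribution needs a positive mean", call. = FALSE)
    }
  } else if (identical(dist$kind, "gamma")) {
    if (is.null(dist$shape) || is.null(dist$scale) ||
      dist$shape <= 0 || dist$scale <= 0) {
      stop("gamma distribution needs positive shape and scale", call. = FALSE)
    }
  } else {
    stop("distribution kind must be 'poisson' or 'gamma'", call. = FALSE)
  }
  if (cfg$n_alterations < 2L) {
    stop("n_alterations must be >= 2", call. = FALSE)
  }
  if (nchar(cfg$quality_char) != 1L) {
    stop("quality_char must be a single character", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  total_reads:", x$total_reads, "\n")
  cat(
    "  class mix (%): known", x$pct_known_mirna, "/ novel", x$pct_novel_mirna,
    "/ piRNA", x$pct_pirna, "/ other",
    100 - x$pct_known_mirna - x$pct_novel_mirna - x$pct_pirna, "\n"
  )
  cat("  distribution:", x$distribution$kind, "| min_depth:", x$min_depth, "\n")
  cat(
    "  read_length:", x$read_length, "| rc_mode:", x$rc_mode,
    "| rng_seed:", x$rng_seed, "\n"
  )
  invisible(x)
}
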