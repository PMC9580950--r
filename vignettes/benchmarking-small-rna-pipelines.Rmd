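---
title: "Benchmarking small RNA-seq pipelines with simulated ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking small RNA-seq pipelines with simulated ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbench)
```

## Why simulate small RNA reads?

Pipelines that call known miRNAs, novel miRNAs, and piRNAs from small RNA-seq
data disagree substantially on the same input, and real data offers no ground
truth to arbitrate. `mirbench` takes the simulation route: it fabricates a
FASTQ read set whose composition is known molecule by molecule, emits that
composition as a machine-readable truth table, and scores any pipeline's
calls against it. The package also implements the post-alignment annotation
logic that distinguishes a careful small-RNA caller from a naive one — read
triage, reverse-complement rescue, seed-based clustering with paralogue
naming — so that the full detection-to-scoring loop can be exercised offline.

## The simulation model

A reference set is a table of mature sequences (known miRNA, novel miRNA,
known piRNA) with 1-based inclusive, stranded genomic intervals, read from
FASTA + GFF3 by `load_reference()`. A simulation is controlled by
`sim_config()`:

* **Class mix** — `pct_known_mirna`, `pct_novel_mirna`, `pct_pirna` are
  *read-level* percentages of `total_reads`; the remainder is the decoy
  ("other") share. We chose read-level rather than molecule-level shares
  because the quantities a pipeline is scored on are read assignments, and a
  read-level mix makes the expected confusion-table margins exact by
  construction. Budgets are integerised by largest-remainder apportionment,
  so realised shares deviate from the configured percentages by less than one
  read per class.
* **Spatial allocation** — each class's read budget is split across
  chromosomes in direct proportion to the number of references per
  chromosome, again with largest-remainder rounding
  (`allocate_reads_per_chromosome()`).
* **Expression** — molecules are sampled without replacement within a
  chromosome and receive counts from a Poisson (default, mean 50) or gamma
  distribution, rounded half-up for gamma and floored at `min_depth`
  (default 10 reads). Selection stops when the chromosome's budget is met;
  the last molecule absorbs the budget tail so no selected molecule falls
  below the floor unless the chromosome's whole budget is below it. If the
  reference pool runs out first, the leftover is spread evenly over the
  selected molecules — a deliberate, conservative choice that preserves read
  conservation without inventing molecules.
* **Decoys** — the "other" class draws source molecules from the known
  miRNA/piRNA references and substitutes exactly `n_alterations` bases
  (default 2, the mismatch tolerance of common small-RNA aligners; altered
  reads are therefore maximally confusable) inside the seed region, the
  xseed region, or both, per the `error_profile` fractions (default equal
  thirds). The untargeted region is untouched, so the truth table can assert
  exactly where each decoy differs from its source.
* **Read assembly** — every read is the mature sequence followed by the 3'
  adapter (default: Illumina TruSeq small-RNA adapter) and the primer
  repeated as filler, truncated to `read_length` (default 75 nt). Qualities
  are a constant Phred+33 character (default `I`, Q40). CIGAR strings record
  the mature portion as a full match (e.g. `22M`); the padding is not part of
  the alignment the CIGAR describes.
* **Reverse-complement mode** — `rc_mode = TRUE` bypasses the mixture and
  emits the reverse complement of every reference at a fixed depth of
  `min_depth` reads, the design used to probe whether pipelines rescue
  reverse-complemented known miRNAs.

Identical configurations (including `rng_seed`) give byte-identical FASTQ and
truth files.

### The seed region

The seed is taken as mature positions 2–8 (1-based), the field convention for
target recognition; it is exposed as `seed_range` everywhere rather than
hard-coded, since some applications prefer 2–7. The xseed is everything else,
kept in order, so seed plus xseed always partition the mature sequence.

## Post-alignment annotation

`annotate_detections()` chains the individual steps, each also exported:

1. **Triage** (`triage_reads()`): 17–24 nt inserts feed the miRNA track,
   25–31 nt the piRNA track; 32 nt and longer are rejected. Reads of 16 nt or
   shorter are also rejected — they are too short to be mature miRNAs and
   cannot enter either track.
2. **Quality filter** (`quality_filter()`): a read is dropped when *strictly
   more than* 10% of its bases are below Q20; a read at exactly 10% is kept.
3. **Reverse-complement rescue** (`reannotate_reverse_complements()`): a
   novel candidate whose forward sequence equals a known mature sequence is
   that known miRNA; failing that, if its reverse complement equals a known
   mature sequence at the *same coordinates*, it is relabelled and its count
   merged. The strand is deliberately ignored in the locus comparison: a
   reverse-complemented read maps to the opposite strand of the same locus,
   so requiring strand equality would defeat the rescue.
4. **Seed-based clustering** (`cluster_novels()`): novel detections merge
   when seeds are identical, xseed Hamming distance is at most 2 (unequal
   lengths never merge — no alignment is attempted), and starts are within
   2 nt on the same chromosome and strand. The 2-nt locus tolerance is
   applied to start positions only; applying it to both ends would make the
   rule sensitive to length differences already policed by the xseed test.
   Merging is the transitive closure over pairs, so chains of near-identical
   detections collapse into one cluster; the representative is the
   highest-count member (ties: smallest start, then lexicographic sequence),
   and re-clustering a clustered table is a no-op.
5. **Functional naming** (`assign_functional_names()`): a cluster sharing a
   known seed at a different locus becomes `<known>_n`; one sharing the seed
   of an earlier-named unique novel becomes `<novel>_n`; unmatched seeds get
   sequential unique-novel names. Indices `n` are assigned in descending
   merged-count order with locus tie-breaks, and the numbering is global
   across the input table, so naming is reproducible for any row order.
6. **Deduplication** (`deduplicate_counts()`): identical mature sequences
   reported at several loci are one molecule listed repeatedly with the same
   count; rows collapse to one, listing every locus, keeping the count once.
   Unequal counts for the same sequence indicate inconsistent input: the
   maximum is kept and a warning raised rather than silently summing.
7. **Renaming** (`rename_novels()`): sequences present in a user-supplied
   external identifier table (standing in for a cross-organism homology
   search, kept local for determinism and offline testability) adopt that
   identifier; all final novel names carry a `*` suffix marking them
   putative.

## Scoring

`score_against_truth()` tallies four classes — known miRNA, novel miRNA,
known piRNA, and the rejection class "other" — with reads (default) or
molecules as the unit. A correct positive call is a TP; a call into any
RNA class that is wrong (including the wrong RNA class) is an FP *to the
predicted class*; an RNA-class molecule rejected to "other" is an FN; a
decoy rejected to "other" is a TN. FN is reserved for rejection, so a
wrong-class call is not double-counted as FP and FN, and every scored read
lands in exactly one cell. Per-class tables use the same definitions
one-vs-rest; the overall table pools reads (micro-pooling).

Accuracy is `100·(TP+TN)/(TP+TN+FP+FN)`; F1 is the harmonic mean of
precision `TP/(TP+FP)` and recall `TP/(TP+FN)`, with the convention that a
zero denominator gives 0, making F1 total. The validation-style statistics
`pct_false_positive()`, `pct_false_negative()`, and `pct_concordant()`
*truncate* (not round) to two decimals, matching how such percentages are
conventionally printed (68.9655… → 68.96); `raw = TRUE` returns full
precision. `pirna_share()` is the piRNA fraction of annotated small RNAs.

## What the generator does and does not emulate

The fixture generator (`make_fixtures()`) draws uniform-random mature
sequences in realistic length bands (miRNA 17–24 nt, piRNA 25–31 nt) at
evenly spaced, non-overlapping loci. That suffices to exercise every code
path deterministically, but real references differ in ways that matter for
end-to-end pipeline claims: real miRNA families share seeds (random
sequences almost never collide), real loci cluster and overlap, base
composition is biased, and real reads carry sequencing errors and quality
decay, which this simulator intentionally omits (no error model, no
paired-end reads). Passing tests therefore demonstrate the correctness of
the simulation, annotation, and scoring logic — not that any particular
pipeline will reach a particular accuracy on biological data.

## Numerical and sizing choices

* Largest-remainder rounding everywhere an integer total is split; ties go
  to the earlier index, so allocation is deterministic.
* Gamma expression draws are rounded half-up before the depth floor.
* Hamming distance between unequal-length strings is defined as infinite.
* Degenerate inputs are rejected loudly: empty references, empty quality
  strings, all-zero confusion tables, percentages outside [0, 100].
* The test suite runs the simulator at 2,000–150,000 reads and the property
  suites at 200–1,000 replicates; these sizes give stable Monte-Carlo checks
  (e.g. a 3-standard-error band on a Poisson mean at n = 10,000) while
  keeping the default test run fast.

## Known limitations

Alignment itself is out of scope: detections enter the annotator as a table,
and the package neither maps reads nor evaluates precursor hairpins.
Differential expression is likewise out of scope — the truth table and count
outputs are designed to feed standard tools downstream. The simulator
defaults target human small RNAs; other genomes require adjusting read
length and seed coordinates.
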