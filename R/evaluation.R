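RNA_CLASSES <- c("known_miRNA", "novel_miRNA", "known_piRNA", "other")

#' Score predictions against simulation ground truth
#'
#' Four-class scoring over known miRNA, novel miRNA, known piRNA, and the
#' rejection class "other". Each scored read contributes to exactly one cell:
#' \describe{
#'   \item{TP}{true class among the three RNA classes, predicted correctly;}
#'   \item{FP}{predicted into one of the three RNA classes while truly
#'     belonging to a different class (including a wrong RNA class);}
#'   \item{FN}{truly an RNA class but rejected to "other";}
#'   \item{TN}{an altered decoy ("other") also labelled "other".}
#' }
#' A read predicted as the wrong RNA class counts as FP to the predicted
#' class only (FN is reserved for rejection). Per-class tallies use the same
#' cell definitions one-vs-rest with the rejection-based FN; the overall
#' table pools reads, so `TP + FP + FN + TN` equals the number scored.
#'
#' When `weight = "reads"` each row contributes its `expression_count`
#' (reads); with `weight = "molecules"` each row counts once.
#'
#' @param predictions Tibble with `molecule_name` and `predicted_class`.
#' @param truth Ground-truth tibble with `molecule_name`, `rna_class`, and
#'   (for read weighting) `expression_count`.
#' @param weight `"reads"` or `"molecules"`.
#' @return An object of class `confusion_summary`: list with `overall`
#'   (named numeric TP/FP/FN/TN), `per_class` (tibble), and `n_scored`.
#' @export
score_against_truth <- function(predictions, truth, weight = c("reads", "molecules")) {
  weight <- match.arg(weight)
  pred <- tibble::as_tibble(predictions)
  tru <- tibble::as_tibble(truth)
  stopifnot(
    all(c("molecule_name", "predicted_class") %in% names(pred)),
    all(c("molecule_name", "rna_class") %in% names(tru))
  )
  missing <- setdiff(pred$molecule_name, tru$molecule_name)
  if (length(missing) > 0L) {
    stop(
      "prediction id(s) absent from truth: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(tru$molecule_name, pred$molecule_name)
  predicted <- pred$predicted_class[idx]
  predicted[is.na(predicted)] <- "other" # unreported molecules were rejected
  if (!all(predicted %in% RNA_CLASSES)) {
    stop("predicted_class values must be one of: ",
      paste(RNA_CLASSES, collapse = ", "),
      call. = FALSE
    )
  }
  actual <- tru$rna_class
  w <- if (weight == "reads") {
    stopifnot("expression_count" %in% names(tru))
    as.numeric(tru$expression_count)
  } else {
    rep(1, nrow(tru))
  }

  positive <- setdiff(RNA_CLASSES, "other")
  tp <- actual %in% positive & predicted == actual
  fp <- predicted %in% positive & predicted != actual
  fn <- actual %in% positive & predicted == "other"
  tn <- actual == "other" & predicted == "other"

  per_class <- lapply(positive, function(cls) {
    tibble::tibble(
      class = cls,
      TP = sum(w[actual == cls & predicted == cls]),
      FP = sum(w[predicted == cls & actual != cls]),
      FN = sum(w[actual == cls & predicted == "other"]),
      TN = sum(w[tn])
    )
  })

  structure(
    list(
      overall = c(
        TP = sum(w[tp]), FP = sum(w[fp]), FN = sum(w[fn]), TN = sum(w[tn])
      ),
      per_class = dplyr::bind_rows(per_class),
      n_scored = sum(w)
    ),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> n =", x$n_scored, "\n")
  print(x$overall)
  invisible(x)
}

cells_of <- function(cs) {
  if (inherits(cs, "confusion_summary")) cs$overall else cs
}

#' Classification accuracy, percent
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cs A `confusion_summary` or named vector with `TP`, `FP`, `FN`, `TN`.
#' @return Accuracy in percent.
#' @export
accuracy <- function(cs) {
  c0 <- cells_of(cs)
  tot <- sum(c0[c("TP", "TN", "FP", "FN")])
  if (tot <= 0) stop("all-zero confusion summary: accuracy undefined", call. = FALSE)
  100 * (c0[["TP"]] + c0[["TN"]]) / tot
}

#' Precision, recall, and F1 score, percent
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`, and F1 their harmonic
#' mean, all scaled to percent. When a denominator is zero the corresponding
#' metric is defined as 0, so F1 is total.
#'
#' @inheritParams accuracy
#' @return The metric in percent.
#' @export
precision_pct <- function(cs) {
  c0 <- cells_of(cs)
  d <- c0[["TP"]] + c0[["FP"]]
  if (d == 0) 0 else 100 * c0[["TP"]] / d
}

#' @rdname precision_pct
#' @export
recall_pct <- function(cs) {
  c0 <- cells_of(cs)
  d <- c0[["TP"]] + c0[["FN"]]
  if (d == 0) 0 else 100 * c0[["TP"]] / d
}

#' @rdname precision_pct
#' @export
f1_score <- function(cs) {
  p <- precision_pct(cs)
  r <- recall_pct(cs)
  if (p + r == 0) {
    return(0)
  }
  2 * p * r / (p + r)
}

# Truncate (not round) to two decimals, the convention used for reported
# validation percentages (e.g. 68.9655... prints as 68.96).
truncate2 <- function(x) trunc(x * 100) / 100

#' Validation-style percent false positives
#'
#' Given the number of dysregulated miRNAs a pipeline identified and how many
#' of those were independently validated (e.g. by RT-qPCR),
#' `%FP = (1 - n_validated / n_identified) * 100`, truncated to two decimals
#' unless `raw = TRUE`.
#'
#' @param n_identified Total identified by the pipeline (> 0).
#' @param n_validated How many of those were validated (0..n_identified).
#' @param raw If `TRUE`, return full precision instead of truncating.
#' @return Percentage in `[0, 100]`.
#' @examples
#' pct_false_positive(31, 17) # 45.16
#' @export
pct_false_positive <- function(n_identified, n_validated, raw = FALSE) {
  if (n_identified <= 0) stop("n_identified must be positive", call. = FALSE)
  if (n_validated < 0 || n_validated > n_identified) {
    stop("n_validated must lie in [0, n_identified]", call. = FALSE)
  }
  x <- (1 - n_validated / n_identified) * 100
  if (raw) x else truncate2(x)
}

#' Validation-style percent false negatives
#'
#' `%FN = (1 - n_validated_found / n_total_validated) * 100`: the share of
#' independently validated miRNAs the pipeline failed to recover, truncated
#' to two decimals unless `raw = TRUE`.
#'
#' @param n_validated_found Validated miRNAs the pipeline recovered.
#' @param n_total_validated Total validated miRNAs (> 0).
#' @inheritParams pct_false_positive
#' @return Percentage in `[0, 100]`.
#' @examples
#' pct_false_negative(17, 31) # 45.16
#' @export
pct_false_negative <- function(n_validated_found, n_total_validated, raw = FALSE) {
  if (n_total_validated <= 0) stop("n_total_validated must be positive", call. = FALSE)
  if (n_validated_found < 0 || n_validated_found > n_total_validated) {
    stop("n_validated_found must lie in [0, n_total_validated]", call. = FALSE)
  }
  x <- (1 - n_validated_found / n_total_validated) * 100
  if (raw) x else truncate2(x)
}

#' Literature-concordance percentage
#'
#' Share of pipeline findings that are corroborated elsewhere:
#' `100 * n_matched / n_total`, truncated to two decimals unless `raw`.
#'
#' @param n_matched Findings matching the external source.
#' @param n_total Total findings (> 0).
#' @inheritParams pct_false_positive
#' @return Percentage in `[0, 100]`.
#' @examples
#' pct_concordant(27, 31) # 87.09
#' @export
pct_concordant <- function(n_matched, n_total, raw = FALSE) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_matched < 0 || n_matched > n_total) {
    stop("n_matched must lie in [0, n_total]", call. = FALSE)
  }
  x <- 100 * n_matched / n_total
  if (raw) x else truncate2(x)
}

#' piRNA share of annotated small RNAs
#'
#' `100 * piRNA / (piRNA + miRNA)` over annotated sequence counts.
#'
#' @param n_pirna,n_mirna Counts of sequences annotated as piRNA / miRNA.
#' @return Percentage in `[0, 100]`.
#' @export
pirna_share <- function(n_pirna, n_mirna) {
  if (n_pirna < 0 || n_mirna < 0) stop("counts must be non-negative", call. = FALSE)
  if (n_pirna + n_mirna == 0) {
    stop("no annotated sequences: share undefined", call. = FALSE)
  }
  100 * n_pirna / (n_pirna + n_mirna)
}

#' Full metric report from a confusion summary
#'
#' @inheritParams accuracy
#' @return A tibble with accuracy, precision, recall and F1 (percent).
#' @export
metric_report <- function(cs) {
  tibble::tibble(
    accuracy = accuracy(cs),
    precision = precision_pct(cs),
    recall = recall_pct(cs),
    f1 = f1_score(cs)
  )
}
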