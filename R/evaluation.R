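# DDIExtraction-2013-style scoring. The four positive classes each get
# TP/FP/FN counts; `other` never has its own row and contributes only as
# a source or sink of errors. A positive-to-positive misclassification
# counts both as FN of the gold class and FP of the predicted class, so
# the Overall row is the exact column-wise sum of the class rows.

#' Per-class confusion counts
#'
#' For each positive class `c`: `TP_c = #(gold = c & pred = c)`,
#' `FN_c = #(gold = c & pred != c)`, `FP_c = #(pred = c & gold != c)`,
#' and `total_c` is the gold count. True negatives (`other` predicted as
#' `other`) are not counted anywhere.
#'
#' @param gold,pred Aligned label vectors over [DDI_CLASSES].
#' @return An object of class `ddi_confusion`: data frame with one row
#'   per positive class and columns `class`, `tp`, `fp`, `fn`, `total`.
#' @export
count_confusions <- function(gold, pred) {
  gold <- as_ddi_label(gold)
  pred <- as_ddi_label(pred)
  if (length(gold) != length(pred)) {
    stop("gold and pred must have the same length")
  }
  rows <- lapply(DDI_POSITIVE_CLASSES, function(cl) {
    data.frame(class = cl,
               tp = sum(gold == cl & pred == cl),
               fp = sum(pred == cl & gold != cl),
               fn = sum(gold == cl & pred != cl),
               total = sum(gold == cl),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("ddi_confusion", "data.frame"))
}

#' Precision, recall and F1 from counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`, each as a
#' percentage. Conventions for empty denominators: `P = 0` if
#' `tp+fp = 0`, `R = 0` if `tp+fn = 0`, `F1 = 0` if `P+R = 0`, so a
#' class with no gold or predicted instances scores 0/0/0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return For scalar input, a named vector `c(P, R, F1)` in percent
#'   (unrounded; display rounds to two decimals); for vector input, a
#'   data frame with columns `P`, `R`, `F1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  P <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  R <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  F1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  if (length(tp) == 1) {
    c(P = 100 * P, R = 100 * R, F1 = 100 * F1)
  } else {
    data.frame(P = 100 * P, R = 100 * R, F1 = 100 * F1)
  }
}

#' Micro-averaged overall metrics
#'
#' Sums TP, FP and FN across the four positive classes (excluding
#' `other`, as in the shared task) and applies [precision_recall_f1()].
#'
#' @param counts A [count_confusions()] result.
#' @return Named vector `c(P, R, F1)` in percent.
#' @export
micro_overall <- function(counts) {
  precision_recall_f1(sum(counts$tp), sum(counts$fp), sum(counts$fn))
}

#' Full metrics report
#'
#' Per-class rows plus the micro-averaged Overall row, mirroring the
#' shared-task result tables.
#'
#' @param gold,pred Aligned label vectors.
#' @return An object of class `ddi_metrics`: data frame with columns
#'   `class`, `tp`, `fp`, `fn`, `total`, `P`, `R`, `F1` (percent,
#'   unrounded).
#' @export
metrics_report <- function(gold, pred) {
  counts <- count_confusions(gold, pred)
  per <- precision_recall_f1(counts$tp, counts$fp, counts$fn)
  overall <- data.frame(class = "Overall", tp = sum(counts$tp),
                        fp = sum(counts$fp), fn = sum(counts$fn),
                        total = sum(counts$total),
                        stringsAsFactors = FALSE)
  overall <- cbind(overall,
                   as.data.frame(as.list(micro_overall(counts))))
  out <- rbind(cbind(as.data.frame(counts), per), overall)
  rownames(out) <- NULL
  structure(out, class = c("ddi_metrics", "data.frame"))
}

#' @export
print.ddi_metrics <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$P <- sprintf("%.2f%%", round(shown$P, 2))
  shown$R <- sprintf("%.2f%%", round(shown$R, 2))
  shown$F1 <- sprintf("%.2f%%", round(shown$F1, 2))
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Per-subcorpus metrics report
#'
#' Partitions the instances by provenance (drugbank / medline /
#' synthetic) and scores each partition separately in addition to the
#' global report; the partition counts sum exactly to the global counts.
#'
#' @param provenance Character vector of provenance tags, aligned with
#'   the labels (e.g. the `provenance` column of [instances_meta()]).
#' @param gold,pred Aligned label vectors.
#' @return List with `overall` (a [metrics_report()]) and `by_corpus`, a
#'   named list of reports for each provenance present.
#' @export
per_corpus_report <- function(provenance, gold, pred) {
  stopifnot(length(provenance) == length(gold),
            length(gold) == length(pred))
  by_corpus <- lapply(split(seq_along(gold), provenance), function(ix) {
    metrics_report(gold[ix], pred[ix])
  })
  list(overall = metrics_report(gold, pred), by_corpus = by_corpus)
}

#' Chi-square comparison of two classifiers
#'
#' Scores both prediction sets against the same gold labels, builds the
#' 2x2 contingency table model-by-correctness over all candidate
#' instances, and computes the 1-df chi-square statistic without
#' continuity correction. Two models are declared significantly
#' different iff the statistic strictly exceeds 3.84 and the p-value is
#' below 0.05.
#'
#' @param gold Gold labels.
#' @param pred_a,pred_b Predictions of the two models over the same
#'   instance set (an error otherwise).
#' @return List with `chi_square`, `p_value`, `significant` and `table`.
#' @export
chi_square_compare <- function(gold, pred_a, pred_b) {
  if (length(pred_a) != length(gold) || length(pred_b) != length(gold)) {
    stop("both prediction sets must cover the same gold instances")
  }
  ca <- as_ddi_label(pred_a) == as_ddi_label(gold)
  cb <- as_ddi_label(pred_b) == as_ddi_label(gold)
  tab <- matrix(c(sum(ca), sum(!ca), sum(cb), sum(!cb)),
                nrow = 2, byrow = TRUE,
                dimnames = list(model = c("A", "B"),
                                outcome = c("correct", "incorrect")))
  if (any(colSums(tab) == 0) || identical(tab[1, ], tab[2, ])) {
    # degenerate margins or identical performance: no evidence of a
    # difference
    chi2 <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  list(chi_square = chi2, p_value = p,
       significant = (chi2 > 3.84) && (p < 0.05),
       table = tab)
}

#' Inter-entity token distance statistics
#'
#' Distribution of the token offsets `p2 - p1` between the two blinded
#' mentions; the corpus modes of this distribution motivate the
#' filter-size grid.
#'
#' @param instances A `ddi_instances` object or list of `ddi_instance`.
#' @return List with `distances`, `histogram` (a `table`), `mean` and
#'   `modes` (distances of maximal frequency).
#' @export
entity_distance_stats <- function(instances) {
  meta <- instances_meta(instances)
  d <- meta$p2 - meta$p1
  h <- table(d)
  list(distances = d, histogram = h, mean = mean(d),
       modes = as.integer(names(h)[h == max(h)]))
}

# ---- prediction files -----------------------------------------------------

#' Write predictions as a tab-separated file
#' @param meta Instance metadata ([instances_meta()]) aligned with the
#'   predictions.
#' @param pred Predicted labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(meta, pred, path) {
  stopifnot(nrow(meta) == length(pred))
  df <- data.frame(pair_id = meta$pair_id, gold = meta$label,
                   predicted = as.character(pred),
                   provenance = meta$provenance,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#' @param path Input path.
#' @return Data frame with columns `pair_id`, `gold`, `predicted`,
#'   `provenance`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
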