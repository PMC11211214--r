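# Imbalance-aware evaluation: average precision, thresholding at a fixed
# recall, confusion-derived rates, simple baselines, gene-conditioned
# filtering, density-stratified error analysis, and weak/strong contact
# partitions.

#' Average precision
#'
#' The mean, over positives taken in score-descending order, of the
#' precision at each positive's rank. Ties in score are broken by stable
#' input order. This is the non-interpolated estimator of the area under
#' the precision-recall curve, the scalar used throughout for model
#' comparison under extreme class imbalance.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels with at least one positive.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) stop("average precision undefined: no positives")
  ord <- order(-scores)                       # stable (radix) order
  l <- labels[ord]
  cum_pos <- cumsum(l == 1)
  prec_at_pos <- cum_pos[l == 1] / which(l == 1)
  sum(prec_at_pos) / npos
}

#' Threshold achieving a target recall
#'
#' The largest threshold `t` such that predicting positive for
#' `score >= t` attains recall at least `recall_target` — i.e. the
#' precision-maximizing operating point subject to the recall floor.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with at least one positive.
#' @param recall_target Target recall in (0, 1].
#' @return The threshold value (one of the observed scores).
#' @export
threshold_at_recall <- function(scores, labels, recall_target = 0.70) {
  if (recall_target <= 0 || recall_target > 1)
    stop("recall_target must be in (0, 1]")
  npos <- sum(labels == 1)
  if (npos == 0) stop("no positives; recall undefined")
  cand <- sort(unique(scores), decreasing = TRUE)
  for (t in cand) {
    if (sum(labels == 1 & scores >= t) / npos >= recall_target) return(t)
  }
  min(scores)
}

#' Confusion counts
#'
#' @param labels Binary labels.
#' @param predictions Binary predictions (same length).
#' @return Object of class `ep_confusion` with fields `tn`, `fp`, `fn`,
#'   `tp`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  structure(list(tn = sum(labels == 0 & predictions == 0),
                 fp = sum(labels == 0 & predictions == 1),
                 fn = sum(labels == 1 & predictions == 0),
                 tp = sum(labels == 1 & predictions == 1)),
            class = "ep_confusion")
}

#' @export
print.ep_confusion <- function(x, ...) {
  cat(sprintf("          pred neg  pred pos\n  neg   %9d %9d\n  pos   %9d %9d\n",
              x$tn, x$fp, x$fn, x$tp))
  invisible(x)
}

#' Rates derived from confusion counts
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, and false-positive rate
#' `fp/(fp+tn)`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param counts An `ep_confusion`, or the `tn` count if the four counts are
#'   given separately.
#' @param fp,fn,tp Individual counts when `counts` is numeric.
#' @return Named list `precision`, `recall`, `fpr`.
#' @export
confusion_rates <- function(counts, fp = NULL, fn = NULL, tp = NULL) {
  if (!inherits(counts, "ep_confusion")) {
    counts <- structure(list(tn = counts, fp = fp, fn = fn, tp = tp),
                        class = "ep_confusion")
  }
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  with(counts, list(precision = safe_div(tp, tp + fp),
                    recall = safe_div(tp, tp + fn),
                    fpr = safe_div(fp, fp + tn)))
}

#' Confusion matrix and rates at a threshold
#'
#' Tallies predictions `score >= threshold` against labels and derives the
#' rates.
#'
#' @param scores Numeric scores (or binary predictions with
#'   `threshold = 0.5`).
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return List with `counts` (`ep_confusion`) and `rates`.
#' @export
confusion_and_rates <- function(scores, labels, threshold) {
  counts <- confusion_counts(labels, as.integer(scores >= threshold))
  list(counts = counts, rates = confusion_rates(counts))
}

#' Baseline scores
#'
#' `abc` returns the ABC-score column; `inverse_distance` scores pairs by
#' `1/distance` (bp), with zero distances mapped just above the largest
#' finite score so they rank first.
#'
#' @param ep Table with `abc_score` and/or `distance` columns.
#' @param kind `"abc"` or `"inverse_distance"`.
#' @return Numeric score vector.
#' @export
baseline_scores <- function(ep, kind = c("abc", "inverse_distance")) {
  kind <- match.arg(kind)
  if (kind == "abc") {
    if (!"abc_score" %in% names(ep)) stop("no abc_score column")
    return(ep$abc_score)
  }
  d <- ep$distance
  s <- ifelse(d > 0, 1 / d, NA_real_)
  if (anyNA(s)) {
    mx <- max(s, na.rm = TRUE)
    s[is.na(s)] <- mx * (1 + 1e-6)
  }
  s
}

#' Keep only genes with at least one positive pair
#'
#' Retains every row whose gene has at least one positive pair anywhere in
#' the table — the gene-conditioned evaluation subset.
#'
#' @param ep Table with a `gene_id` column.
#' @param labels Binary labels aligned to rows.
#' @return Logical vector of rows to keep.
#' @export
filter_genes_with_positive <- function(ep, labels) {
  stopifnot("gene_id" %in% names(ep))
  pos_genes <- unique(ep$gene_id[labels == 1])
  ep$gene_id %in% pos_genes
}

#' Density-stratified error analysis
#'
#' Bins rows by a neighborhood-density column and tallies the confusion
#' counts and their within-bin proportions per bin. Empty bins are reported
#' with zero counts and `NA` proportions.
#'
#' @param density Numeric density values (e.g. total element count in the
#'   neighborhood).
#' @param predictions Binary predictions.
#' @param labels Binary labels.
#' @param bin_edges Numeric vector of bin edges (left-closed, right-open;
#'   last bin right-closed).
#' @return `data.table` with one row per bin: counts `tn,fp,fn,tp`, bin
#'   size, and proportions `p_tn,p_fp,p_fn,p_tp`.
#' @export
density_stratified_errors <- function(density, predictions, labels,
                                      bin_edges) {
  stopifnot(length(density) == length(labels),
            length(predictions) == length(labels))
  idx <- findInterval(density, bin_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  nb <- length(bin_edges) - 1L
  rows <- lapply(seq_len(nb), function(b) {
    in_bin <- which(idx == b)
    cc <- confusion_counts(labels[in_bin], predictions[in_bin])
    n <- length(in_bin)
    data.table::data.table(
      bin = b, lower = bin_edges[b], upper = bin_edges[b + 1L], n = n,
      tn = cc$tn, fp = cc$fp, fn = cc$fn, tp = cc$tp,
      p_tn = if (n) cc$tn / n else NA_real_,
      p_fp = if (n) cc$fp / n else NA_real_,
      p_fn = if (n) cc$fn / n else NA_real_,
      p_tp = if (n) cc$tp / n else NA_real_)
  })
  data.table::rbindlist(rows)
}

#' Weak/strong contact partition metrics
#'
#' Splits rows at a contact threshold (`>=` is strong) and reports, per
#' partition, the size, positive count, prevalence, and — when scores are
#' supplied and the partition has positives — the average precision.
#'
#' @param contact Numeric focal contact per row.
#' @param labels Binary labels.
#' @param threshold Contact threshold (e.g. 0.002 for the class analysis or
#'   0.005 for the distribution split).
#' @param scores Optional numeric model scores.
#' @return `data.table` with rows `strong` and `weak`.
#' @export
contact_partition_metrics <- function(contact, labels, threshold = 0.002,
                                      scores = NULL) {
  stopifnot(length(contact) == length(labels))
  strong <- contact >= threshold
  one <- function(sel, name) {
    n <- sum(sel); pos <- sum(labels[sel] == 1)
    ap <- if (!is.null(scores) && pos > 0)
      average_precision(scores[sel], labels[sel]) else NA_real_
    data.table::data.table(partition = name, n = n, positives = pos,
                           prevalence = if (n) pos / n else NA_real_,
                           ap = ap)
  }
  rbind(one(strong, "strong"), one(!strong, "weak"))
}
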