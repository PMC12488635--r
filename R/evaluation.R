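# Evaluation: confusion-matrix statistics and threshold-free curves.
# Metrics with a zero denominator are reported as NA with a reason --
# degenerate folds (e.g. no positives after under-sampling a small
# fold) are a real phenomenon under class imbalance and must never be
# silently coerced to 0.

#' Confusion counts for binary predictions
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels, same length.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("labels and predictions differ in length")
    if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
        stop("labels and predictions must be binary 0/1")
    list(TP = sum(labels == 1 & predictions == 1),
         FP = sum(labels == 0 & predictions == 1),
         TN = sum(labels == 0 & predictions == 0),
         FN = sum(labels == 1 & predictions == 0))
}

.safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP), sensitivity
#' (recall) TP/(TP+FN), specificity TN/(TN+FP) and F1 (harmonic mean
#' of precision and recall), applied literally. A metric whose
#' denominator is zero is `NA` (undefined), never 0.
#'
#' @param counts List from [confusionCounts()].
#' @return Named list `acc`, `prec`, `sens`, `spec`, `f1`.
#' @export
thresholdMetrics <- function(counts) {
    TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
    total <- TP + FP + TN + FN
    if (total == 0) stop("no evaluated samples")
    prec <- .safeRatio(TP, TP + FP)
    sens <- .safeRatio(TP, TP + FN)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    list(acc = (TP + TN) / total,
         prec = prec,
         sens = sens,
         spec = .safeRatio(TN, TN + FP),
         f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random
#' positive outscores a random negative, ties counted one half --
#' exactly the exhaustive pairwise-comparison statistic, and invariant
#' under strictly monotone transforms of the scores.
#'
#' @param labels True 0/1 labels.
#' @param scores Real-valued scores, higher = more positive.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
aucScore <- function(labels, scores) {
    stopifnot(length(labels) == length(scores))
    nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
    if (nPos == 0 || nNeg == 0) return(NA_real_)
    r <- rank(scores)                       # midranks handle ties
    (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise, non-interpolated area over a descending-score sweep:
#' at each distinct score threshold the precision is weighted by the
#' recall increment (`sum (R_k - R_{k-1}) * P_k`), with tied scores
#' handled as one group. This is the "average precision" dialect;
#' random scores concentrate near the positive prevalence.
#'
#' @inheritParams aucScore
#' @return AUPR in \[0, 1\], or `NA` if there are no positives.
#' @export
auprScore <- function(labels, scores) {
    stopifnot(length(labels) == length(scores))
    nPos <- sum(labels == 1)
    if (nPos == 0) return(NA_real_)
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]
    sc <- scores[ord]
    grp <- cumsum(!duplicated(sc))          # tied scores share a group
    tpCum <- cumsum(lab)
    predCum <- seq_along(lab)
    last <- which(!duplicated(grp, fromLast = TRUE))
    tp <- tpCum[last]
    npred <- predCum[last]
    precision <- tp / npred
    recall <- tp / nPos
    sum(diff(c(0, recall)) * precision)
}

#' Evaluate one set of predictions
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @param scores Positive-class scores for AUROC/AUPR.
#' @param fold Optional fold identifier.
#' @return One-row data.frame with the confusion counts, the seven
#'   metrics (`acc`, `prec`, `sens`, `spec`, `f1`, `auc`, `aupr`),
#'   `nPos`, `nNeg` and `fold`.
#' @export
evalReport <- function(labels, predictions, scores, fold = NA) {
    counts <- confusionCounts(labels, predictions)
    tm <- thresholdMetrics(counts)
    data.frame(fold = fold,
               TP = counts$TP, FP = counts$FP, TN = counts$TN,
               FN = counts$FN,
               nPos = sum(labels == 1), nNeg = sum(labels == 0),
               acc = tm$acc, prec = tm$prec, sens = tm$sens,
               spec = tm$spec, f1 = tm$f1,
               auc = aucScore(labels, scores),
               aupr = auprScore(labels, scores),
               stringsAsFactors = FALSE)
}

#' Aggregate per-fold reports
#'
#' Unweighted mean and standard deviation per metric over the folds
#' where the metric is defined; the number of undefined (NA) folds is
#' reported per metric rather than being folded into the average.
#'
#' @param reports data.frame of rows from [evalReport()].
#' @return data.frame with one row per metric: `metric`, `mean`, `sd`,
#'   `nFolds`, `nUndefined`.
#' @export
aggregateFolds <- function(reports) {
    stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
    metrics <- c("acc", "prec", "sens", "spec", "f1", "auc", "aupr")
    rows <- lapply(metrics, function(m) {
        v <- reports[[m]]
        ok <- !is.na(v)
        data.frame(metric = m,
                   mean = if (any(ok)) mean(v[ok]) else NA_real_,
                   sd = if (sum(ok) > 1L) sd(v[ok]) else
                        if (any(ok)) 0 else NA_real_,
                   nFolds = length(v),
                   nUndefined = sum(!ok),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Write evaluation reports as JSON and a Markdown table
#'
#' @param reports Per-fold data.frame from [evalReport()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeEvalReports <- function(reports, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    agg <- aggregateFolds(reports)
    jsonPath <- file.path(dir, "metrics.json")
    jsonlite::write_json(
        list(folds = reports, aggregate = agg),
        jsonPath, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    mdPath <- file.path(dir, "metrics.md")
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
    lines <- c(
        "| Metric | Mean | SD | Undefined folds |",
        "|---|---|---|---|",
        sprintf("| %s | %s | %s | %d |", toupper(agg$metric),
                fmt(agg$mean), fmt(agg$sd), agg$nUndefined))
    writeLines(lines, mdPath)
    # per-metric means in long form, ready for radar-chart plotting
    radarPath <- file.path(dir, "radar.csv")
    utils::write.csv(agg[, c("metric", "mean")], radarPath,
                     row.names = FALSE, quote = FALSE)
    invisible(c(jsonPath, mdPath, radarPath))
}
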