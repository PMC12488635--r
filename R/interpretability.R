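# Interpretability: the gate weights ARE the model's explanation of
# which expert stream it trusted for each sample. This module exports
# them (with Shannon entropies and group summaries) and the raw
# feature grids behind the post-fusion heatmaps; plotting is a thin
# optional layer over the exported matrices.

#' Shannon entropy of expert-weight rows
#'
#' `-sum(alpha * log(alpha))` per row, with `0 log 0 = 0`. Ranges from
#' 0 (fully specialized on one expert) to `log(2)` (indifferent).
#'
#' @param alpha n x 2 matrix of gate weights.
#' @return Numeric vector of entropies.
#' @export
gateEntropy <- function(alpha) {
    if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1L)
    terms <- ifelse(alpha > 0, alpha * log(alpha), 0)
    -rowSums(terms)
}

#' Export per-sample gate weights
#'
#' Recomputes the gate forward pass on the dataset (after the model's
#' stored normalization), bit-identical to what fusion used, and
#' attaches per-label group means as an attribute.
#'
#' @param model A fitted [MoEClassifier-class].
#' @param dataset A [PairDataset-class].
#' @return data.frame `sampleId`, `label`, `alpha1`, `alpha2`,
#'   `entropy`; attribute `groupMeans` holds mean alpha by label.
#' @export
exportGateWeights <- function(model, dataset) {
    stopifnot(is(model, "MoEClassifier"), is(dataset, "PairDataset"))
    ds <- if (length(model@scalers)) applyScalers(dataset, model@scalers)
          else dataset
    gf <- gateForward(model@gate, statsBlock(ds))
    out <- data.frame(
        sampleId = sampleIds(dataset),
        label = pairLabels(dataset),
        alpha1 = gf$alpha[, 1L],
        alpha2 = gf$alpha[, 2L],
        entropy = gateEntropy(gf$alpha),
        stringsAsFactors = FALSE
    )
    gm <- do.call(rbind, lapply(split(out, out$label), function(g) {
        data.frame(label = g$label[1L], meanAlpha1 = mean(g$alpha1),
                   meanAlpha2 = mean(g$alpha2), n = nrow(g))
    }))
    rownames(gm) <- NULL
    attr(out, "groupMeans") <- gm
    out
}

#' Feature heatmap matrix
#'
#' The samples x features value grid of one feature block as the
#' classifier sees it (post-normalization; the fused block is the
#' post-fusion, pre-classifier representation). No rescaling beyond
#' the pipeline's own normalization is applied. Rows can optionally
#' be grouped by label (a permutation of the input order, recorded in
#' the `rowOrder` attribute).
#'
#' @param model A fitted [MoEClassifier-class].
#' @param dataset A [PairDataset-class].
#' @param block One of `"stats"`, `"expert1"`, `"expert2"`, `"fused"`,
#'   `"combined"`.
#' @param order `"input"` (as given) or `"label"` (grouped by label,
#'   positives first).
#' @return Numeric matrix with attributes `rowOrder` and `block`.
#' @export
heatmapMatrix <- function(model, dataset,
                          block = c("stats", "expert1", "expert2",
                                    "fused", "combined"),
                          order = c("input", "label")) {
    block <- match.arg(block)
    order <- match.arg(order)
    stopifnot(is(model, "MoEClassifier"), is(dataset, "PairDataset"))
    ds <- if (length(model@scalers)) applyScalers(dataset, model@scalers)
          else dataset
    m <- switch(block,
        stats = statsBlock(ds),
        expert1 = expertBlock(ds, 1L),
        expert2 = expertBlock(ds, 2L),
        fused = ,
        combined = {
            gf <- gateForward(model@gate, statsBlock(ds))
            fused <- fuseExperts(gf$alpha, expertBlock(ds, 1L),
                                 expertBlock(ds, 2L))
            if (block == "fused") fused
            else concatCombined(fused, statsBlock(ds))
        })
    rowOrder <- seq_len(nrow(m))
    if (order == "label")
        rowOrder <- order(-pairLabels(dataset))
    out <- m[rowOrder, , drop = FALSE]
    rownames(out) <- sampleIds(dataset)[rowOrder]
    attr(out, "rowOrder") <- rowOrder
    attr(out, "block") <- block
    out
}

#' Write gate weights and a heatmap matrix as CSV
#'
#' @param model A fitted [MoEClassifier-class].
#' @param dataset A [PairDataset-class].
#' @param dir Output directory.
#' @param block Feature block for the heatmap export.
#' @return Invisibly, the paths written.
#' @export
exportExplanations <- function(model, dataset, dir, block = "fused") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gw <- exportGateWeights(model, dataset)
    gwPath <- file.path(dir, "gate_weights.csv")
    utils::write.csv(gw, gwPath, row.names = FALSE, quote = FALSE)
    hm <- heatmapMatrix(model, dataset, block = block)
    hmPath <- file.path(dir, paste0("heatmap_", block, ".csv"))
    utils::write.csv(data.frame(sampleId = rownames(hm), hm,
                                check.names = FALSE),
                     hmPath, row.names = FALSE, quote = FALSE)
    invisible(c(gwPath, hmPath))
}
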