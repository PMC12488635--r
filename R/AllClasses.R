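#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
#' @importFrom utils tail
NULL

#' PairDataset: labelled phage-host samples with their feature blocks
#'
#' The central container of the package. Each sample is one phage-host
#' pair carrying three feature blocks -- the interpretable statistical
#' descriptor block (`stats`), and the two expert embedding blocks
#' (`expert1`, `expert2`, equal width) -- plus a binary interaction
#' label derived from the infection-score threshold rule. Feature
#' blocks are samples x features matrices; per-sample metadata lives in
#' a [S4Vectors::DataFrame] with columns `phageId`, `hostId`, `label`.
#'
#' @slot stats Numeric matrix, n x s (s = 26 under defaults).
#' @slot expert1,expert2 Numeric matrices, n x d each, identical d.
#' @slot pairInfo `DataFrame` with `phageId`, `hostId`, `label`.
#'
#' @examples
#' spec <- fixtureSpec(nHosts = 4, nPhages = 5, embedDim = 8, seed = 1)
#' ds <- genPairDataset(spec)
#' ds
#' dim(statsBlock(ds))
#' table(pairLabels(ds))
#' @aliases PairDataset
#' @export
setClass("PairDataset",
    representation(
        stats    = "matrix",
        expert1  = "matrix",
        expert2  = "matrix",
        pairInfo = "DataFrame"
    )
)

setValidity("PairDataset", function(object) {
    n <- nrow(object@stats)
    msgs <- character()
    if (nrow(object@expert1) != n || nrow(object@expert2) != n ||
        nrow(object@pairInfo) != n)
        msgs <- c(msgs, "all blocks must have the same number of samples")
    if (ncol(object@expert1) != ncol(object@expert2))
        msgs <- c(msgs, "expert blocks must share the same width d")
    if (!all(c("phageId", "hostId", "label") %in% colnames(object@pairInfo)))
        msgs <- c(msgs, "pairInfo needs columns phageId, hostId, label")
    else if (!all(object@pairInfo$label %in% c(0L, 1L)))
        msgs <- c(msgs, "labels must be 0 or 1")
    if (any(!is.finite(object@stats)) || any(!is.finite(object@expert1)) ||
        any(!is.finite(object@expert2)))
        msgs <- c(msgs, "feature blocks must be finite")
    if (length(msgs)) msgs else TRUE
})

#' Construct a PairDataset
#'
#' @param stats n x s numeric matrix of statistical descriptors.
#' @param expert1,expert2 n x d numeric embedding matrices.
#' @param phageId,hostId Character vectors of length n.
#' @param label Integer 0/1 vector of length n.
#' @return A [PairDataset-class] object.
#' @export
PairDataset <- function(stats, expert1, expert2, phageId, hostId, label) {
    new("PairDataset",
        stats = as.matrix(stats),
        expert1 = as.matrix(expert1),
        expert2 = as.matrix(expert2),
        pairInfo = S4Vectors::DataFrame(
            phageId = as.character(phageId),
            hostId = as.character(hostId),
            label = as.integer(label)
        ))
}

#' @describeIn PairDataset-class number of samples
#' @param x,object A `PairDataset`.
#' @export
setMethod("length", "PairDataset", function(x) nrow(x@stats))

#' @describeIn PairDataset-class the statistical descriptor block
#' @export
statsBlock <- function(x) {
    stopifnot(is(x, "PairDataset"))
    x@stats
}

#' @describeIn PairDataset-class one expert embedding block
#' @param which 1 or 2.
#' @export
expertBlock <- function(x, which = 1L) {
    stopifnot(is(x, "PairDataset"), which %in% c(1L, 2L))
    if (which == 1L) x@expert1 else x@expert2
}

#' @describeIn PairDataset-class the 0/1 labels
#' @export
pairLabels <- function(x) {
    stopifnot(is(x, "PairDataset"))
    x@pairInfo$label
}

#' @describeIn PairDataset-class per-sample metadata DataFrame
#' @export
pairInfo <- function(x) {
    stopifnot(is(x, "PairDataset"))
    x@pairInfo
}

#' @describeIn PairDataset-class stable per-sample identifiers
#'   (`phageId:hostId`, suffixed on duplication by resampling)
#' @export
sampleIds <- function(x) {
    stopifnot(is(x, "PairDataset"))
    ids <- paste(x@pairInfo$phageId, x@pairInfo$hostId, sep = ":")
    make.unique(ids, sep = "#")
}

#' @describeIn PairDataset-class subset samples
#' @param i Integer or logical index over samples.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PairDataset", function(x, i, j, ..., drop = FALSE) {
    new("PairDataset",
        stats = x@stats[i, , drop = FALSE],
        expert1 = x@expert1[i, , drop = FALSE],
        expert2 = x@expert2[i, , drop = FALSE],
        pairInfo = x@pairInfo[i, , drop = FALSE])
})

#' @describeIn PairDataset-class display summary
#' @export
setMethod("show", "PairDataset", function(object) {
    lab <- object@pairInfo$label
    cat("PairDataset with", length(object), "samples\n")
    cat("  stats block:  ", ncol(object@stats), "features\n")
    cat("  expert blocks:", ncol(object@expert1), "features each\n")
    cat("  labels:       ", sum(lab == 1L), "positive /",
        sum(lab == 0L), "negative\n")
})

#' GateParams: the two-layer gating network of the mixture-of-experts
#'
#' Trainable parameters of the router that maps the statistical
#' descriptor vector (width s) through a hidden ReLU layer (width 64 by
#' default) to two expert logits, softmaxed into the expert weights
#' (alpha1, alpha2).
#'
#' @slot W1 s x hidden weight matrix.
#' @slot b1 hidden bias vector.
#' @slot W2 hidden x 2 weight matrix.
#' @slot b2 length-2 bias vector.
#' @aliases GateParams
#' @export
setClass("GateParams",
    representation(W1 = "matrix", b1 = "numeric",
                   W2 = "matrix", b2 = "numeric"))

setValidity("GateParams", function(object) {
    msgs <- character()
    h <- ncol(object@W1)
    if (length(object@b1) != h)
        msgs <- c(msgs, "b1 length must equal ncol(W1)")
    if (nrow(object@W2) != h || ncol(object@W2) != 2L)
        msgs <- c(msgs, "W2 must be hidden x 2")
    if (length(object@b2) != 2L)
        msgs <- c(msgs, "b2 must have length 2")
    if (!all(is.finite(object@W1)) || !all(is.finite(object@b1)) ||
        !all(is.finite(object@W2)) || !all(is.finite(object@b2)))
        msgs <- c(msgs, "gate parameters must be finite")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn GateParams-class display summary
#' @param object A `GateParams`.
#' @export
setMethod("show", "GateParams", function(object) {
    cat("GateParams:", nrow(object@W1), "->", ncol(object@W1),
        "-> 2 (softmax)\n")
})

#' ConvNetModel: the 1D convolutional prediction head
#'
#' Conv blocks (conv1d -> ReLU -> batch norm -> max pool), a global
#' average pool, a fully connected ReLU layer with dropout, and a final
#' linear layer emitting two class logits. Parameters and batch-norm
#' running statistics are stored as plain numeric arrays; `config`
#' records the architecture so shapes are never hard-coded.
#'
#' @slot params Named list of parameter arrays.
#' @slot running Named list of batch-norm running means/variances.
#' @slot config The [modelConfig()] list.
#' @slot inputWidth Width of the combined input vector.
#' @aliases ConvNetModel
#' @export
setClass("ConvNetModel",
    representation(params = "list", running = "list",
                   config = "list", inputWidth = "integer"))

#' @describeIn ConvNetModel-class display summary
#' @param object A `ConvNetModel`.
#' @export
setMethod("show", "ConvNetModel", function(object) {
    cfg <- object@config
    cat("ConvNetModel: input width", object@inputWidth,
        "| conv channels", paste(cfg$channels, collapse = "-"),
        "| kernel", cfg$kernel,
        "| fc", cfg$fcWidth, "\n")
    cat("  parameters:", sum(vapply(object@params, length, integer(1L))), "\n")
})

#' MoEClassifier: a fitted gate + CNN model with preprocessing state
#'
#' Bundles everything needed to score new phage-host pairs: the fitted
#' gating network, the fitted CNN head, the min-max scaler parameters
#' fitted on the training portion, the training configuration and the
#' per-epoch loss trajectory.
#'
#' @slot gate A [GateParams-class].
#' @slot cnn A [ConvNetModel-class].
#' @slot scalers List of per-block min-max parameters (or empty list).
#' @slot config The [modelConfig()] used for training.
#' @slot history Numeric vector of per-epoch mean training losses.
#' @aliases MoEClassifier
#' @export
setClass("MoEClassifier",
    representation(gate = "GateParams", cnn = "ConvNetModel",
                   scalers = "list", config = "list",
                   history = "numeric"))

#' @describeIn MoEClassifier-class display summary
#' @param object A `MoEClassifier`.
#' @export
setMethod("show", "MoEClassifier", function(object) {
    cat("MoEClassifier (gated two-expert fusion + 1D CNN)\n")
    show(object@gate)
    show(object@cnn)
    if (length(object@history))
        cat("  trained", length(object@history), "epochs; final loss",
            signif(tail(object@history, 1L), 4), "\n")
})

#' @describeIn MoEClassifier-class the fitted gating network
#' @param x A `MoEClassifier`.
#' @export
gateParams <- function(x) {
    stopifnot(is(x, "MoEClassifier"))
    x@gate
}

#' @describeIn MoEClassifier-class per-epoch mean training loss
#' @export
lossHistory <- function(x) {
    stopifnot(is(x, "MoEClassifier"))
    x@history
}
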