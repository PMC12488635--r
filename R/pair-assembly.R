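# Pair assembly: interaction matrix -> labelled phage-host samples.
# Covers the 1.5-threshold labelling rule, phage/host feature
# combination, min-max normalization, over/under-sampling and
# stratified cross-validation folds.

#' Read a host x phage interaction matrix from CSV
#'
#' First column = host id, header row = phage ids, cells numeric
#' infection scores; empty cells are missing values (NA), never zero.
#'
#' @param path CSV file.
#' @return Numeric matrix, hosts in rows, phages in columns.
#' @export
readInteractionMatrix <- function(path) {
    if (!file.exists(path)) stop("interaction matrix not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("interaction matrix needs >= 1 phage column")
    hosts <- as.character(df[[1L]])
    if (anyDuplicated(hosts)) stop("duplicate host ids in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyDuplicated(colnames(m))) stop("duplicate phage ids in ", path)
    if (any(is.infinite(m), na.rm = TRUE))
        stop("non-finite infection scores in ", path)
    rownames(m) <- hosts
    m
}

#' Write an interaction matrix as CSV
#'
#' @param m Numeric matrix, hosts in rows, phages in columns.
#' @param path Output file.
#' @export
writeInteractionMatrix <- function(m, path) {
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    df <- data.frame(host = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Binarize infection scores into interaction labels
#'
#' Scores strictly above the threshold become 1 (significant
#' infection), scores at or below it become 0. The default threshold
#' of 1.5 is the immersion-assay cut the labelling rule was defined
#' with; a score of exactly 1.5 maps to 0 (strict "above"). Missing
#' cells are skipped and counted.
#'
#' @param m Interaction matrix from [readInteractionMatrix()].
#' @param threshold Numeric cut, default 1.5.
#' @return data.frame with columns `hostId`, `phageId`, `score`,
#'   `label`; attribute `nMissing` counts skipped cells.
#' @export
binarizeLabels <- function(m, threshold = 1.5) {
    stopifnot(is.matrix(m), nrow(m) >= 1L, ncol(m) >= 1L)
    present <- which(!is.na(m), arr.ind = TRUE)
    if (nrow(present) == 0L) stop("interaction matrix is all-missing")
    scores <- m[present]
    out <- data.frame(
        hostId = rownames(m)[present[, 1L]],
        phageId = colnames(m)[present[, 2L]],
        score = scores,
        label = as.integer(scores > threshold),
        stringsAsFactors = FALSE
    )
    attr(out, "nMissing") <- length(m) - nrow(out)
    out
}

# combine one phage-block row and one host-block row
.combineBlock <- function(phage, host, mode) {
    if (length(phage) != length(host))
        stop("phage/host feature width mismatch: ", length(phage),
             " vs ", length(host))
    if (mode == "mean") (phage + host) / 2 else c(phage, host)
}

#' Assemble labelled phage-host samples
#'
#' Joins the labelled (host, phage) pairs with per-entity feature
#' matrices. `mode = "mean"` averages the phage and host vectors
#' element-wise, keeping each block at its per-entity width (26 / d);
#' `mode = "concat"` concatenates them (phage first), doubling every
#' width.
#'
#' @param pairs data.frame from [binarizeLabels()].
#' @param hostStats,phageStats Per-entity descriptor matrices
#'   (rownames = entity ids).
#' @param hostExpert1,phageExpert1,hostExpert2,phageExpert2 Per-entity
#'   embedding matrices for the two expert streams.
#' @param mode `"mean"` (default) or `"concat"`.
#' @return A [PairDataset-class].
#' @export
assemblePairs <- function(pairs, hostStats, phageStats,
                          hostExpert1, phageExpert1,
                          hostExpert2, phageExpert2,
                          mode = c("mean", "concat")) {
    mode <- match.arg(mode)
    stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
    if (ncol(hostExpert1) != ncol(hostExpert2))
        stop("the two expert streams must share the same width d")
    missH <- setdiff(pairs$hostId, rownames(hostStats))
    missP <- setdiff(pairs$phageId, rownames(phageStats))
    if (length(missH) || length(missP))
        stop("entities without features: ",
             paste(head(c(missH, missP), 5L), collapse = ", "))
    rowsFor <- function(phageM, hostM) {
        t(vapply(seq_len(nrow(pairs)), function(i) {
            .combineBlock(phageM[pairs$phageId[i], ],
                          hostM[pairs$hostId[i], ], mode)
        }, numeric(ncol(phageM) * if (mode == "concat") 2L else 1L)))
    }
    PairDataset(
        stats = rowsFor(phageStats, hostStats),
        expert1 = rowsFor(phageExpert1, hostExpert1),
        expert2 = rowsFor(phageExpert2, hostExpert2),
        phageId = pairs$phageId, hostId = pairs$hostId,
        label = pairs$label
    )
}

#' Fit per-feature min-max parameters
#'
#' @param x Numeric matrix (samples x features), the fit (training)
#'   set; must be non-empty.
#' @return List with `min` and `max` per feature.
#' @export
fitMinMax <- function(x) {
    stopifnot(is.matrix(x))
    if (nrow(x) == 0L) stop("cannot fit min-max on an empty set")
    list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

#' Apply min-max normalization
#'
#' `x' = (x - min) / (max - min)` per feature (fitted on the training
#' portion). Constant features (max == min) map to 0. Values outside
#' the fitted range (e.g. test-set extremes) may fall outside \[0, 1\]
#' and are deliberately not clipped.
#'
#' @param x Numeric matrix.
#' @param params List from [fitMinMax()].
#' @return Matrix of the same shape.
#' @export
applyMinMax <- function(x, params) {
    stopifnot(is.matrix(x), length(params$min) == ncol(x))
    span <- params$max - params$min
    out <- sweep(x, 2L, params$min, "-")
    nz <- span > 0
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/")
    out[, !nz] <- 0
    out
}

#' Fit min-max scalers for all three feature blocks of a dataset
#'
#' @param dataset A [PairDataset-class] (the training portion).
#' @return Named list of scaler parameter lists
#'   (`stats`, `expert1`, `expert2`).
#' @export
fitScalers <- function(dataset) {
    list(stats = fitMinMax(statsBlock(dataset)),
         expert1 = fitMinMax(expertBlock(dataset, 1L)),
         expert2 = fitMinMax(expertBlock(dataset, 2L)))
}

#' Apply fitted scalers to every block of a dataset
#'
#' @param dataset A [PairDataset-class].
#' @param scalers List from [fitScalers()].
#' @return A normalized [PairDataset-class].
#' @export
applyScalers <- function(dataset, scalers) {
    PairDataset(
        stats = applyMinMax(statsBlock(dataset), scalers$stats),
        expert1 = applyMinMax(expertBlock(dataset, 1L), scalers$expert1),
        expert2 = applyMinMax(expertBlock(dataset, 2L), scalers$expert2),
        phageId = pairInfo(dataset)$phageId,
        hostId = pairInfo(dataset)$hostId,
        label = pairLabels(dataset)
    )
}

.checkTwoClasses <- function(labels) {
    if (length(unique(labels)) < 2L)
        stop("resampling needs both classes present")
}

#' Random over-sampling of the minority class
#'
#' Duplicates randomly chosen minority-class samples (with
#' replacement) until both classes have the majority count. Majority
#' samples are untouched; every added row is a copy of an original
#' minority row.
#'
#' @param dataset A [PairDataset-class] with both classes present.
#' @param seed Integer seed.
#' @return A class-balanced [PairDataset-class].
#' @export
oversample <- function(dataset, seed = 1L) {
    labels <- pairLabels(dataset)
    .checkTwoClasses(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == nNeg) return(dataset)
    minority <- if (nPos < nNeg) 1L else 0L
    need <- abs(nNeg - nPos)
    minIdx <- which(labels == minority)
    extra <- .withSeed(seed, sample(minIdx, need, replace = TRUE))
    dataset[c(seq_along(labels), extra)]
}

#' Random under-sampling of the majority class
#'
#' Removes randomly chosen majority-class samples (without
#' replacement) until both classes have the minority count; the output
#' is a subset of the input.
#'
#' @inheritParams oversample
#' @return A class-balanced [PairDataset-class].
#' @export
undersample <- function(dataset, seed = 1L) {
    labels <- pairLabels(dataset)
    .checkTwoClasses(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == nNeg) return(dataset)
    majority <- if (nPos > nNeg) 1L else 0L
    majIdx <- which(labels == majority)
    keepMaj <- .withSeed(seed, sample(majIdx, min(nPos, nNeg)))
    keep <- sort(c(which(labels != majority), keepMaj))
    dataset[keep]
}

#' Stratified k-fold split
#'
#' Partitions sample indices into k disjoint test folds preserving the
#' class ratio within one sample per fold; each (train, test) pair
#' covers all samples.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds (>= 2); each class must have >= k members.
#' @param seed Integer seed.
#' @return List of k lists with integer vectors `train` and `test`.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
    k <- as.integer(k)
    stopifnot(k >= 2L)
    counts <- table(factor(labels, levels = c(0L, 1L)))
    if (any(counts < k))
        stop("each class needs >= k members (have ",
             paste(counts, collapse = "/"), ", k = ", k, ")")
    assign01 <- .withSeed(seed, {
        fold <- integer(length(labels))
        for (cl in c(0L, 1L)) {
            idx <- sample(which(labels == cl))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        fold
    })
    lapply(seq_len(k), function(f) {
        test <- which(assign01 == f)
        list(train = setdiff(seq_along(labels), test), test = test)
    })
}
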