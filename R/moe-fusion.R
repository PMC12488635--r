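# The mixture-of-experts layer: a two-layer gating network maps each
# sample's statistical descriptor vector to a softmax pair of expert
# weights (alpha1, alpha2); the two expert embeddings are fused by the
# per-sample convex combination and the fused vector is concatenated
# with the statistical block. The gate is written over a weight vector
# of arbitrary length internally, so a K-expert generalization is a
# configuration change; the public API fixes two experts.

# numerically stable row-wise softmax (max-shifted)
.softmaxRows <- function(x) {
    shifted <- x - apply(x, 1L, max)
    e <- exp(shifted)
    e / rowSums(e)
}

#' Initialize gating-network parameters
#'
#' Glorot-uniform weights (limit sqrt(6 / (fanIn + fanOut))), zero
#' biases, seeded. With zero biases and zero-mean inputs the initial
#' expert weights sit near (0.5, 0.5): the gate starts indifferent and
#' specializes only if training pushes it.
#'
#' @param s Width of the statistical descriptor vector (>= 1).
#' @param hidden Hidden-layer width, default 64.
#' @param seed Integer seed.
#' @return A [GateParams-class].
#' @export
initGate <- function(s, hidden = 64L, seed = 1L) {
    s <- as.integer(s); hidden <- as.integer(hidden)
    stopifnot(s >= 1L, hidden >= 1L)
    .withSeed(seed, {
        lim1 <- sqrt(6 / (s + hidden))
        lim2 <- sqrt(6 / (hidden + 2))
        new("GateParams",
            W1 = matrix(runif(s * hidden, -lim1, lim1), s, hidden),
            b1 = numeric(hidden),
            W2 = matrix(runif(hidden * 2L, -lim2, lim2), hidden, 2L),
            b2 = numeric(2L))
    })
}

#' Gating-network forward pass
#'
#' Per-sample, no cross-sample coupling:
#' `H = ReLU(stats %*% W1 + b1)`, `G = H %*% W2 + b2`,
#' `alpha = softmax(G)` (max-shifted for stability). Each row of
#' `alpha` is a probability distribution over the two experts.
#'
#' @param params A [GateParams-class].
#' @param stats Numeric matrix n x s (or a single vector of length s).
#' @return List with `H` (n x hidden), `G` (n x 2), `alpha` (n x 2).
#' @export
gateForward <- function(params, stats) {
    stopifnot(is(params, "GateParams"))
    if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1L)
    if (ncol(stats) != nrow(params@W1))
        stop("stats width ", ncol(stats), " does not match gate input ",
             nrow(params@W1))
    H <- stats %*% params@W1
    H <- sweep(H, 2L, params@b1, "+")
    H[H < 0] <- 0
    G <- sweep(H %*% params@W2, 2L, params@b2, "+")
    list(H = H, G = G, alpha = .softmaxRows(G))
}

#' Fuse the two expert embeddings with the gate weights
#'
#' Element-wise convex combination per sample:
#' `fused_i = alpha_i1 * expert1_i + alpha_i2 * expert2_i`. Every
#' fused value lies within the element-wise envelope of the two
#' experts.
#'
#' @param alpha n x 2 matrix of gate weights (rows sum to 1).
#' @param expert1,expert2 n x d embedding matrices.
#' @return n x d fused matrix.
#' @export
fuseExperts <- function(alpha, expert1, expert2) {
    if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1L)
    if (is.null(dim(expert1))) expert1 <- matrix(expert1, nrow = 1L)
    if (is.null(dim(expert2))) expert2 <- matrix(expert2, nrow = 1L)
    if (!identical(dim(expert1), dim(expert2)))
        stop("expert blocks differ in shape")
    if (nrow(alpha) != nrow(expert1) || ncol(alpha) != 2L)
        stop("alpha must be n x 2 matching the expert blocks")
    expert1 * alpha[, 1L] + expert2 * alpha[, 2L]
}

#' Concatenate fused and statistical blocks
#'
#' `combined = [fused, stats]`, fused block first; with the default
#' widths d = 1024 and s = 26 the combined width is 1050. All
#' downstream dimensionality derives from the actual widths, never
#' from constants.
#'
#' @param fused n x d matrix.
#' @param stats n x s matrix.
#' @return n x (d + s) matrix.
#' @export
concatCombined <- function(fused, stats) {
    if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
    if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1L)
    stopifnot(nrow(fused) == nrow(stats))
    cbind(fused, stats)
}
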