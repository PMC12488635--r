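# The prediction head: a small 1D CNN over the combined feature
# vector, trained jointly with the gating network by cross-entropy.
# Forward and backward passes are written in vectorized base R
# (im2col convolution, batch normalization, max pooling, global
# average pooling, fully connected layers, inverted dropout) together
# with an Adam optimizer, so the gate and the CNN share one
# computational graph and one unified update step.

#' Training / architecture configuration
#'
#' The architecture is conv blocks (conv1d, ReLU, batch norm, max
#' pool) repeated once per entry of `channels`, then global average
#' pooling, one fully connected ReLU layer with dropout, and a linear
#' layer emitting two class logits.
#'
#' @param channels Integer vector of conv channel widths, one per
#'   block; default `c(32, 64)`.
#' @param kernel Odd kernel size >= 1; default 3 (same-padding).
#' @param poolWidth Max-pool width/stride per block; default 2.
#' @param fcWidth Fully connected layer width; default 64.
#' @param dropout Dropout rate in \[0, 1); default 0.3.
#' @param lr Adam learning rate (> 0); default 1e-3.
#' @param batchSize Mini-batch size; default 32.
#' @param epochs Training epochs; default 50.
#' @param hidden Gating-network hidden width; default 64.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param patience Optional early-stopping patience on the training
#'   loss (`NULL` = off).
#' @return A validated `modelConfig` list.
#' @export
modelConfig <- function(channels = c(32L, 64L), kernel = 3L,
                        poolWidth = 2L, fcWidth = 64L, dropout = 0.3,
                        lr = 1e-3, batchSize = 32L, epochs = 50L,
                        hidden = 64L, seed = 1L, patience = NULL) {
    channels <- as.integer(channels)
    kernel <- as.integer(kernel)
    stopifnot(length(channels) >= 1L, all(channels >= 1L))
    if (kernel < 1L || kernel %% 2L == 0L)
        stop("kernel size must be odd and >= 1")
    if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
    if (lr <= 0) stop("learning rate must be > 0")
    structure(list(channels = channels, kernel = kernel,
                   poolWidth = as.integer(poolWidth),
                   fcWidth = as.integer(fcWidth), dropout = dropout,
                   lr = lr, batchSize = as.integer(batchSize),
                   epochs = as.integer(epochs),
                   hidden = as.integer(hidden),
                   seed = as.integer(seed), patience = patience),
              class = "modelConfig")
}

.glorot <- function(fanIn, fanOut, dims) {
    lim <- sqrt(6 / (fanIn + fanOut))
    array(runif(prod(dims), -lim, lim), dims)
}

# widths of the signal after each pooling stage; errors name the stage
.stageWidths <- function(config, inputWidth) {
    L <- inputWidth
    widths <- integer(length(config$channels))
    for (i in seq_along(config$channels)) {
        L <- L %/% config$poolWidth
        if (L < 1L)
            stop("input width too small: max-pool in conv block ", i,
                 " reduces the signal width to 0")
        widths[i] <- L
    }
    widths
}

#' Build an (untrained) 1D-CNN prediction head
#'
#' Glorot-uniform weight initialization, zero biases, batch-norm
#' scale 1 / shift 0, all seeded from `config$seed`. The parameter
#' count is deterministic given the configuration.
#'
#' @param config A [modelConfig()].
#' @param inputWidth Width of the combined feature vector (>= kernel).
#' @return A [ConvNetModel-class].
#' @export
buildConvNet <- function(config, inputWidth) {
    stopifnot(inherits(config, "modelConfig"))
    inputWidth <- as.integer(inputWidth)
    if (inputWidth < config$kernel)
        stop("input width ", inputWidth, " smaller than kernel ",
             config$kernel, " in conv block 1")
    .stageWidths(config, inputWidth)   # validates pooling stack
    K <- config$kernel
    params <- list(); running <- list()
    .withSeed(config$seed, {
        cin <- 1L
        for (i in seq_along(config$channels)) {
            cout <- config$channels[i]
            params[[paste0("conv", i, ".W")]] <-
                .glorot(K * cin, K * cout, c(K, cin, cout))
            params[[paste0("conv", i, ".b")]] <- numeric(cout)
            params[[paste0("conv", i, ".gamma")]] <- rep(1, cout)
            params[[paste0("conv", i, ".beta")]] <- numeric(cout)
            running[[paste0("conv", i)]] <-
                list(mean = numeric(cout), var = rep(1, cout))
            cin <- cout
        }
        params[["fc1.W"]] <- .glorot(cin, config$fcWidth,
                                     c(cin, config$fcWidth))
        params[["fc1.b"]] <- numeric(config$fcWidth)
        params[["fc2.W"]] <- .glorot(config$fcWidth, 2L,
                                     c(config$fcWidth, 2L))
        params[["fc2.b"]] <- numeric(2L)
    })
    new("ConvNetModel", params = params, running = running,
        config = unclass(config), inputWidth = inputWidth)
}

#' Number of trainable parameters of a CNN head
#'
#' @param model A [ConvNetModel-class].
#' @return Integer count.
#' @export
countParameters <- function(model) {
    stopifnot(is(model, "ConvNetModel"))
    sum(vapply(model@params, length, integer(1L)))
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# -- conv1d, same padding, channel-last arrays A[n, L, C] -------------

.im2col <- function(Ap, n, L, K, C) {
    M <- matrix(0, n * L, K * C)
    for (c in seq_len(C)) {
        for (k in seq_len(K)) {
            M[, (c - 1L) * K + k] <- as.vector(Ap[, k:(k + L - 1L), c])
        }
    }
    M
}

.convForward <- function(A, W, b) {
    dims <- dim(A); n <- dims[1L]; L <- dims[2L]; C <- dims[3L]
    K <- dim(W)[1L]; cout <- dim(W)[3L]
    p <- (K - 1L) %/% 2L
    Ap <- array(0, c(n, L + 2L * p, C))
    Ap[, (p + 1L):(p + L), ] <- A
    M <- .im2col(Ap, n, L, K, C)
    O <- M %*% matrix(W, K * C, cout)
    O <- sweep(O, 2L, b, "+")
    list(out = array(O, c(n, L, cout)), M = M, n = n, L = L, C = C,
         K = K, p = p)
}

.convBackward <- function(cache, W, dOut) {
    n <- cache$n; L <- cache$L; C <- cache$C; K <- cache$K; p <- cache$p
    cout <- dim(W)[3L]
    dO <- matrix(dOut, n * L, cout)
    dW <- array(crossprod(cache$M, dO), dim(W))
    db <- colSums(dO)
    dM <- dO %*% t(matrix(W, K * C, cout))
    dAp <- array(0, c(n, L + 2L * p, C))
    for (c in seq_len(C)) {
        for (k in seq_len(K)) {
            dAp[, k:(k + L - 1L), c] <- dAp[, k:(k + L - 1L), c] +
                matrix(dM[, (c - 1L) * K + k], n, L)
        }
    }
    list(dA = dAp[, (p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

# -- batch norm over (samples x positions) per channel ----------------

.bnForward <- function(A, gamma, beta, run, training) {
    dims <- dim(A); n <- dims[1L]; L <- dims[2L]; C <- dims[3L]
    m <- n * L
    X <- matrix(A, m, C)
    if (training) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        run$mean <- (1 - .BN_MOMENTUM) * run$mean + .BN_MOMENTUM * mu
        run$var <- (1 - .BN_MOMENTUM) * run$var + .BN_MOMENTUM * v
    } else {
        mu <- run$mean
        v <- run$var
    }
    invstd <- 1 / sqrt(v + .BN_EPS)
    xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, invstd, "*")
    Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
    list(out = array(Y, dims), xhat = xhat, invstd = invstd, run = run,
         m = m, dims = dims)
}

.bnBackward <- function(cache, gamma, dOut, training) {
    dY <- matrix(dOut, cache$m, length(gamma))
    dbeta <- colSums(dY)
    dgamma <- colSums(dY * cache$xhat)
    dxhat <- sweep(dY, 2L, gamma, "*")
    if (training) {
        s1 <- colSums(dxhat) / cache$m
        s2 <- colSums(dxhat * cache$xhat) / cache$m
        dX <- sweep(dxhat, 2L, s1, "-") -
            sweep(cache$xhat, 2L, s2, "*")
        dX <- sweep(dX, 2L, cache$invstd, "*")
    } else {
        dX <- sweep(dxhat, 2L, cache$invstd, "*")
    }
    list(dA = array(dX, cache$dims), dgamma = dgamma, dbeta = dbeta)
}

# -- max pool, width = stride = w; ties resolved to the first slot ----

.poolForward <- function(A, w) {
    dims <- dim(A); n <- dims[1L]; L <- dims[2L]; C <- dims[3L]
    L2 <- L %/% w
    best <- A[, seq(1L, L2 * w, by = w), , drop = FALSE]
    arg <- array(1L, c(n, L2, C))
    if (w > 1L) {
        for (j in 2L:w) {
            cand <- A[, seq(j, L2 * w, by = w), , drop = FALSE]
            better <- cand > best
            best[better] <- cand[better]
            arg[better] <- j
        }
    }
    list(out = best, arg = arg, L = L, w = w)
}

.poolBackward <- function(cache, dOut) {
    dims <- dim(cache$arg); n <- dims[1L]; L2 <- dims[2L]; C <- dims[3L]
    w <- cache$w
    dA <- array(0, c(n, cache$L, C))
    for (j in seq_len(w)) {
        sel <- cache$arg == j
        tmp <- array(0, c(n, L2, C))
        tmp[sel] <- dOut[sel]
        dA[, seq(j, L2 * w, by = w), ] <- tmp
    }
    dA
}

# -- full network forward; X is n x inputWidth --------------------------

.cnnForward <- function(params, running, config, X, training) {
    n <- nrow(X)
    A <- array(X, c(n, ncol(X), 1L))
    caches <- list()
    for (i in seq_along(config$channels)) {
        cv <- .convForward(A, params[[paste0("conv", i, ".W")]],
                           params[[paste0("conv", i, ".b")]])
        pre <- cv$out
        relu <- pre
        relu[relu < 0] <- 0
        bn <- .bnForward(relu, params[[paste0("conv", i, ".gamma")]],
                         params[[paste0("conv", i, ".beta")]],
                         running[[paste0("conv", i)]], training)
        running[[paste0("conv", i)]] <- bn$run
        pl <- .poolForward(bn$out, config$poolWidth)
        caches[[i]] <- list(conv = cv, pre = pre, bn = bn, pool = pl)
        A <- pl$out
    }
    Lfin <- dim(A)[2L]
    Fpool <- colMeans(aperm(A, c(2L, 1L, 3L)))       # n x C global avg
    if (is.null(dim(Fpool))) Fpool <- matrix(Fpool, nrow = n)
    Z1 <- sweep(Fpool %*% params[["fc1.W"]], 2L, params[["fc1.b"]], "+")
    A1 <- Z1; A1[A1 < 0] <- 0
    if (training && config$dropout > 0) {
        mask <- (matrix(runif(length(A1)), nrow(A1)) >= config$dropout) /
            (1 - config$dropout)
    } else {
        mask <- NULL
    }
    A1d <- if (is.null(mask)) A1 else A1 * mask
    logits <- sweep(A1d %*% params[["fc2.W"]], 2L, params[["fc2.b"]], "+")
    list(logits = logits, running = running,
         cache = list(blocks = caches, Lfin = Lfin, Fpool = Fpool,
                      Z1 = Z1, A1d = A1d, mask = mask, n = n))
}

# dLogits is n x 2; returns gradients for all CNN params plus dX
.cnnBackward <- function(params, config, cache, dLogits, training) {
    grads <- list()
    grads[["fc2.W"]] <- crossprod(cache$A1d, dLogits)
    grads[["fc2.b"]] <- colSums(dLogits)
    dA1d <- dLogits %*% t(params[["fc2.W"]])
    dA1 <- if (is.null(cache$mask)) dA1d else dA1d * cache$mask
    dZ1 <- dA1 * (cache$Z1 > 0)
    grads[["fc1.W"]] <- crossprod(cache$Fpool, dZ1)
    grads[["fc1.b"]] <- colSums(dZ1)
    dF <- dZ1 %*% t(params[["fc1.W"]])
    n <- cache$n; Lfin <- cache$Lfin; Cfin <- ncol(dF)
    dA <- aperm(array(dF / Lfin, c(n, Cfin, Lfin)), c(1L, 3L, 2L))
    for (i in rev(seq_along(config$channels))) {
        blk <- cache$blocks[[i]]
        dBn <- .poolBackward(blk$pool, dA)
        bnb <- .bnBackward(blk$bn, params[[paste0("conv", i, ".gamma")]],
                           dBn, training)
        grads[[paste0("conv", i, ".gamma")]] <- bnb$dgamma
        grads[[paste0("conv", i, ".beta")]] <- bnb$dbeta
        dRelu <- bnb$dA
        dRelu[blk$pre < 0] <- 0
        cvb <- .convBackward(blk$conv, params[[paste0("conv", i, ".W")]],
                             dRelu)
        grads[[paste0("conv", i, ".W")]] <- cvb$dW
        grads[[paste0("conv", i, ".b")]] <- cvb$db
        dA <- cvb$dA
    }
    list(grads = grads, dX = matrix(dA, n, dim(dA)[2L]))
}

#' Forward pass of a CNN head in inference mode
#'
#' Dropout off, batch norm on running statistics; deterministic and
#' batch-size invariant.
#'
#' @param model A [ConvNetModel-class].
#' @param X Numeric matrix, samples x inputWidth.
#' @return n x 2 matrix of class logits.
#' @export
cnnLogits <- function(model, X) {
    stopifnot(is(model, "ConvNetModel"), is.matrix(X))
    if (ncol(X) != model@inputWidth)
        stop("input width ", ncol(X), " does not match the model (",
             model@inputWidth, ")")
    .cnnForward(model@params, model@running, model@config, X,
                training = FALSE)$logits
}

#' Binary cross-entropy from predicted probabilities
#'
#' `L = -(1/N) sum( y log p + (1 - y) log(1 - p) )`, probabilities
#' clamped to \[1e-12, 1 - 1e-12\] before the logarithm. Computed from
#' probabilities (not logits) to mirror the loss definition literally;
#' the fused log-softmax form is numerically preferable and agrees to
#' rounding, which the test suite asserts.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted positive-class probabilities, same length.
#' @return Scalar mean loss.
#' @export
crossEntropyLoss <- function(labels, probs) {
    if (length(labels) != length(probs))
        stop("labels and probabilities differ in length")
    p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Adam step over flat named parameter lists
.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    c1 <- 1 - beta1^state$t
    c2 <- 1 - beta2^state$t
    for (nm in names(grads)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    }
    list(params = params, state = state)
}

#' Jointly train the gating network and the CNN head
#'
#' One unified Adam step updates the gate and the CNN: the fusion of
#' the two expert embeddings happens inside the computational graph,
#' so gradients of the cross-entropy loss flow through the combined
#' vector into the softmax gate. Mini-batch shuffling, dropout masks
#' and all initializations are driven by `config$seed`, making the
#' whole trajectory reproducible. The gate consumes the same
#' (normalized) statistical block the classifier sees.
#'
#' @param dataset A [PairDataset-class] (already normalized) with both
#'   classes present.
#' @param config A [modelConfig()].
#' @param scalers Optional list of fitted min-max scaler parameters to
#'   store with the model (applied automatically at prediction time).
#' @param freezeGate If TRUE the gate parameters are not updated
#'   (diagnostic; gradients still flow through the fusion).
#' @return A fitted [MoEClassifier-class].
#' @export
trainMoE <- function(dataset, config = modelConfig(), scalers = list(),
                     freezeGate = FALSE) {
    stopifnot(is(dataset, "PairDataset"), inherits(config, "modelConfig"))
    y <- pairLabels(dataset)
    if (length(unique(y)) < 2L)
        stop("training set must contain both classes")
    stats <- statsBlock(dataset)
    e1 <- expertBlock(dataset, 1L)
    e2 <- expertBlock(dataset, 2L)
    s <- ncol(stats); d <- ncol(e1)
    gate <- initGate(s, config$hidden, seed = config$seed)
    cnn <- buildConvNet(config, inputWidth = d + s)
    params <- c(cnn@params,
                list(gate.W1 = gate@W1, gate.b1 = gate@b1,
                     gate.W2 = gate@W2, gate.b2 = gate@b2))
    running <- cnn@running
    gateNames <- c("gate.W1", "gate.b1", "gate.W2", "gate.b2")
    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    n <- length(y)
    history <- numeric(0L)
    .withSeed(config$seed + 1L, {
        best <- Inf; stall <- 0L
        for (epoch in seq_len(config$epochs)) {
            ord <- sample.int(n)
            starts <- seq(1L, n, by = config$batchSize)
            epochLoss <- 0
            for (st in starts) {
                idx <- ord[st:min(st + config$batchSize - 1L, n)]
                sb <- stats[idx, , drop = FALSE]
                e1b <- e1[idx, , drop = FALSE]
                e2b <- e2[idx, , drop = FALSE]
                yb <- y[idx]
                gp <- new("GateParams", W1 = params$gate.W1,
                          b1 = params$gate.b1, W2 = params$gate.W2,
                          b2 = params$gate.b2)
                gf <- gateForward(gp, sb)
                fused <- fuseExperts(gf$alpha, e1b, e2b)
                Xc <- concatCombined(fused, sb)
                fw <- .cnnForward(params, running, config, Xc,
                                  training = TRUE)
                running <- fw$running
                probs <- .softmaxRows(fw$logits)
                loss <- crossEntropyLoss(yb, probs[, 2L])
                if (!is.finite(loss))
                    stop("non-finite loss at epoch ", epoch,
                         " (exploding gradients? lower the learning rate)")
                epochLoss <- epochLoss + loss * length(idx)
                dLogits <- (probs - cbind(1 - yb, yb)) / length(idx)
                dimnames(dLogits) <- NULL
                bw <- .cnnBackward(params, config, fw$cache, dLogits,
                                   training = TRUE)
                grads <- bw$grads
                dFused <- bw$dX[, seq_len(d), drop = FALSE]
                dAlpha <- cbind(rowSums(dFused * e1b),
                                rowSums(dFused * e2b))
                dG <- gf$alpha *
                    (dAlpha - rowSums(dAlpha * gf$alpha))
                dH <- dG %*% t(params$gate.W2)
                dH[gf$H <= 0] <- 0
                grads[["gate.W2"]] <- crossprod(gf$H, dG)
                grads[["gate.b2"]] <- colSums(dG)
                grads[["gate.W1"]] <- crossprod(sb, dH)
                grads[["gate.b1"]] <- colSums(dH)
                if (freezeGate) grads[gateNames] <- NULL
                upd <- .adamStep(params, grads, state, config$lr)
                params <- upd$params
                state <- upd$state
            }
            history <- c(history, epochLoss / n)
            if (!is.null(config$patience)) {
                if (tail(history, 1L) < best - 1e-6) {
                    best <- tail(history, 1L); stall <- 0L
                } else {
                    stall <- stall + 1L
                    if (stall >= config$patience) break
                }
            }
        }
    })
    fittedGate <- new("GateParams", W1 = params$gate.W1,
                      b1 = params$gate.b1, W2 = params$gate.W2,
                      b2 = params$gate.b2)
    fittedCnn <- new("ConvNetModel",
                     params = params[setdiff(names(params), gateNames)],
                     running = running, config = unclass(config),
                     inputWidth = d + s)
    new("MoEClassifier", gate = fittedGate, cnn = fittedCnn,
        scalers = scalers, config = unclass(config), history = history)
}

#' Score phage-host pairs with a fitted model
#'
#' Deterministic inference: dropout off, batch norm uses its running
#' statistics, so batch composition never changes a prediction. The
#' positive-class probability is the softmax over the two logits and
#' `yHat = 1` iff `pHat >= 0.5` (the boundary case predicts 1). If the
#' model carries fitted scalers they are applied to the dataset first.
#'
#' @param model A fitted [MoEClassifier-class].
#' @param dataset A [PairDataset-class] on the model's feature widths.
#' @return data.frame with `sampleId`, `z0`, `z1`, `pHat`, `yHat`,
#'   `alpha1`, `alpha2`.
#' @export
predictPairs <- function(model, dataset) {
    stopifnot(is(model, "MoEClassifier"), is(dataset, "PairDataset"))
    if (length(model@scalers))
        dataset <- applyScalers(dataset, model@scalers)
    stats <- statsBlock(dataset)
    e1 <- expertBlock(dataset, 1L)
    e2 <- expertBlock(dataset, 2L)
    width <- ncol(e1) + ncol(stats)
    if (width != model@cnn@inputWidth)
        stop("feature width ", width, " does not match the fitted model (",
             model@cnn@inputWidth, ")")
    gf <- gateForward(model@gate, stats)
    fused <- fuseExperts(gf$alpha, e1, e2)
    Xc <- concatCombined(fused, stats)
    fw <- .cnnForward(model@cnn@params, model@cnn@running,
                      unclass(model@config), Xc, training = FALSE)
    probs <- .softmaxRows(fw$logits)
    data.frame(
        sampleId = sampleIds(dataset),
        z0 = fw$logits[, 1L], z1 = fw$logits[, 2L],
        pHat = probs[, 2L],
        yHat = as.integer(probs[, 2L] >= 0.5),
        alpha1 = gf$alpha[, 1L], alpha2 = gf$alpha[, 2L],
        stringsAsFactors = FALSE
    )
}

#' Save / load a fitted model checkpoint
#'
#' One archive holding the gate, CNN parameters and running
#' statistics, scaler parameters, configuration and feature widths.
#'
#' @param model A [MoEClassifier-class].
#' @param path Checkpoint file (RDS).
#' @return `path` (write) / the restored model (read).
#' @export
writeModelCheckpoint <- function(model, path) {
    stopifnot(is(model, "MoEClassifier"))
    saveRDS(list(format = "phageMoE-checkpoint-1",
                 gate = list(W1 = model@gate@W1, b1 = model@gate@b1,
                             W2 = model@gate@W2, b2 = model@gate@b2),
                 cnnParams = model@cnn@params,
                 cnnRunning = model@cnn@running,
                 inputWidth = model@cnn@inputWidth,
                 scalers = model@scalers, config = model@config,
                 history = model@history,
                 rVersion = as.character(getRversion())),
            path)
    invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
    x <- readRDS(path)
    if (!identical(x$format, "phageMoE-checkpoint-1"))
        stop("not a recognized model checkpoint: ", path)
    gate <- new("GateParams", W1 = x$gate$W1, b1 = x$gate$b1,
                W2 = x$gate$W2, b2 = x$gate$b2)
    cnn <- new("ConvNetModel", params = x$cnnParams,
               running = x$cnnRunning, config = x$config,
               inputWidth = as.integer(x$inputWidth))
    new("MoEClassifier", gate = gate, cnn = cnn, scalers = x$scalers,
        config = x$config, history = x$history)
}
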