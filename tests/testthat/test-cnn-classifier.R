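test_that("config validation rejects malformed architectures", {
    expect_error(modelConfig(kernel = 2), "odd")
    expect_error(modelConfig(dropout = 1), "dropout")
    expect_error(modelConfig(lr = 0), "learning rate")
})

test_that("the head builds at full and toy widths and emits 2 logits", {
    full <- buildConvNet(modelConfig(seed = 1), inputWidth = 1050)
    X <- matrix(rnorm(3 * 1050), 3, 1050)
    z <- cnnLogits(full, X)
    expect_equal(dim(z), c(3L, 2L))

    toy <- buildConvNet(modelConfig(seed = 1), inputWidth = 11)
    zt <- cnnLogits(toy, matrix(rnorm(2 * 11), 2, 11))
    expect_equal(dim(zt), c(2L, 2L))

    # pooling stack too deep for the width: error names the stage
    expect_error(buildConvNet(modelConfig(seed = 1), inputWidth = 3),
                 "conv block 2")
    expect_error(buildConvNet(modelConfig(seed = 1), inputWidth = 2),
                 "kernel")
})

test_that("parameter count matches hand arithmetic for a 1-block config", {
    cfg <- modelConfig(channels = 4L, kernel = 3L, fcWidth = 5L, seed = 2)
    m <- buildConvNet(cfg, inputWidth = 10)
    # conv: 3*1*4 W + 4 b + 4 gamma + 4 beta; fc1: 4*5 + 5; fc2: 5*2 + 2
    expect_equal(countParameters(m),
                 (3 * 1 * 4 + 4 + 4 + 4) + (4 * 5 + 5) + (5 * 2 + 2))
    m2 <- buildConvNet(cfg, inputWidth = 10)
    expect_identical(m@params, m2@params)   # seeded init
})

test_that("cross-entropy matches closed forms and the per-sample oracle", {
    expect_equal(crossEntropyLoss(1, 0.5), log(2))
    expect_lt(crossEntropyLoss(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-10)
    expect_error(crossEntropyLoss(c(1, 0), 0.5), "length")

    set.seed(17)
    y <- rbinom(40, 1, 0.4)
    p <- runif(40, 0.01, 0.99)
    perSample <- -(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(crossEntropyLoss(y, p), mean(perSample))

    # equivalence with the fused log-softmax form on real logits
    z <- matrix(rnorm(80), 40, 2)
    lse <- log(exp(z[, 1]) + exp(z[, 2]))
    probs <- exp(z[, 2] - lse)
    fused <- -mean(y * (z[, 2] - lse) + (1 - y) * (z[, 1] - lse))
    expect_equal(crossEntropyLoss(y, probs), fused, tolerance = 1e-9)
})

test_that("joint backprop matches finite differences on a toy graph", {
    set.seed(19)
    n <- 6; d <- 6; s <- 4
    stats <- matrix(runif(n * s), n, s)
    e1 <- matrix(runif(n * d, -1, 1), n, d)
    e2 <- matrix(runif(n * d, -1, 1), n, d)
    y <- c(0, 1, 1, 0, 1, 0)
    cfg <- modelConfig(channels = 3L, kernel = 3L, fcWidth = 4L,
                       dropout = 0, seed = 2)
    gate <- initGate(s, hidden = 5L, seed = 3)
    cnn <- buildConvNet(cfg, d + s)
    params <- c(cnn@params,
                list(gate.W1 = gate@W1, gate.b1 = gate@b1,
                     gate.W2 = gate@W2, gate.b2 = gate@b2))
    running <- cnn@running
    lossOf <- function(p) {
        gp <- new("GateParams", W1 = p$gate.W1, b1 = p$gate.b1,
                  W2 = p$gate.W2, b2 = p$gate.b2)
        gf <- gateForward(gp, stats)
        Xc <- concatCombined(fuseExperts(gf$alpha, e1, e2), stats)
        fw <- phageMoE:::.cnnForward(p, running, unclass(cfg), Xc, TRUE)
        pr <- phageMoE:::.softmaxRows(fw$logits)
        crossEntropyLoss(y, pr[, 2])
    }
    gp <- new("GateParams", W1 = params$gate.W1, b1 = params$gate.b1,
              W2 = params$gate.W2, b2 = params$gate.b2)
    gf <- gateForward(gp, stats)
    Xc <- concatCombined(fuseExperts(gf$alpha, e1, e2), stats)
    fw <- phageMoE:::.cnnForward(params, running, unclass(cfg), Xc, TRUE)
    pr <- phageMoE:::.softmaxRows(fw$logits)
    dLogits <- (pr - cbind(1 - y, y)) / n
    bw <- phageMoE:::.cnnBackward(params, unclass(cfg), fw$cache,
                                  dLogits, TRUE)
    grads <- bw$grads
    dFused <- bw$dX[, seq_len(d), drop = FALSE]
    dAlpha <- cbind(rowSums(dFused * e1), rowSums(dFused * e2))
    dG <- gf$alpha * (dAlpha - rowSums(dAlpha * gf$alpha))
    dH <- dG %*% t(params$gate.W2); dH[gf$H <= 0] <- 0
    grads$gate.W2 <- crossprod(gf$H, dG); grads$gate.b2 <- colSums(dG)
    grads$gate.W1 <- crossprod(stats, dH); grads$gate.b1 <- colSums(dH)

    eps <- 1e-6
    for (nm in names(grads)) {
        g <- grads[[nm]]
        for (i in sample(length(g), min(3L, length(g)))) {
            pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
            pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
            num <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
            expect_equal(unname(g[i]), num, tolerance = 1e-4,
                         label = paste("grad", nm, i))
        }
    }
})

test_that("training is deterministic, NaN-guarded and gate-aware", {
    spec <- fixtureSpec(n = 60, embedDim = 6, seed = 21)
    ds <- genSeparableDataset(spec, sStats = 4L)
    cfg <- modelConfig(channels = 4L, fcWidth = 6L, epochs = 3,
                       batchSize = 16L, seed = 7)
    m1 <- trainMoE(ds, cfg)
    m2 <- trainMoE(ds, cfg)
    expect_identical(lossHistory(m1), lossHistory(m2))
    expect_length(lossHistory(m1), 3L)

    # frozen gate keeps its initial parameters; joint training moves them
    frozen <- trainMoE(ds, cfg, freezeGate = TRUE)
    init <- initGate(ncol(statsBlock(ds)), cfg$hidden, seed = cfg$seed)
    expect_identical(gateParams(frozen)@W1, init@W1)
    expect_false(identical(gateParams(m1)@W1, init@W1))

    expect_error(trainMoE(ds[pairLabels(ds) == 1L], cfg), "both classes")
})

test_that("prediction is deterministic, batch-invariant and thresholded at 0.5", {
    spec <- fixtureSpec(n = 40, embedDim = 6, seed = 22)
    ds <- genSeparableDataset(spec, sStats = 4L)
    cfg <- modelConfig(channels = 4L, fcWidth = 6L, epochs = 2,
                       batchSize = 16L, seed = 8)
    m <- trainMoE(ds, cfg)
    pAll <- predictPairs(m, ds)
    pOne <- do.call(rbind, lapply(seq_len(length(ds)), function(i)
        predictPairs(m, ds[i])))
    expect_equal(pAll$pHat, pOne$pHat, tolerance = 1e-12)
    expect_equal(pAll$yHat, as.integer(pAll$pHat >= 0.5))
    # the two-class softmax sums to 1 per sample
    pk <- exp(pAll$z1) / (exp(pAll$z0) + exp(pAll$z1))
    expect_equal(pAll$pHat, pk, tolerance = 1e-9)

    wrong <- genSeparableDataset(fixtureSpec(n = 10, embedDim = 8,
                                             seed = 2), sStats = 4L)
    expect_error(predictPairs(m, wrong), "width")
})

test_that("equal logits give probability one half and prediction 1", {
    m <- buildConvNet(modelConfig(seed = 3), inputWidth = 11)
    # zero the final layer: logits are (b, b) so pHat is exactly 0.5
    m@params$fc2.W[] <- 0
    m@params$fc2.b <- c(0.3, 0.3)
    z <- cnnLogits(m, matrix(rnorm(4 * 11), 4, 11))
    expect_equal(z[, 1], z[, 2])
    p <- exp(z[, 2]) / (exp(z[, 1]) + exp(z[, 2]))
    expect_equal(p, rep(0.5, 4))
    expect_equal(as.integer(p >= 0.5), rep(1L, 4))
})

test_that("model checkpoints round-trip through a single archive", {
    spec <- fixtureSpec(n = 30, embedDim = 6, seed = 23)
    ds <- genSeparableDataset(spec, sStats = 4L)
    cfg <- modelConfig(channels = 4L, fcWidth = 6L, epochs = 2,
                       batchSize = 16L, seed = 9)
    m <- trainMoE(ds, cfg, scalers = fitScalers(ds))
    path <- withr::local_tempfile(fileext = ".rds")
    writeModelCheckpoint(m, path)
    back <- readModelCheckpoint(path)
    expect_equal(predictPairs(back, ds), predictPairs(m, ds))
    bad <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(format = "something-else"), bad)
    expect_error(readModelCheckpoint(bad), "not a recognized")
})
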