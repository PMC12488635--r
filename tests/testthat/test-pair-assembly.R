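test_that("score binarization follows the strict above-1.5 rule", {
    m <- matrix(c(1.6, 1.4, 1.5, NA), 2, 2,
                dimnames = list(c("h1", "h2"), c("p1", "p2")))
    out <- binarizeLabels(m)
    lab <- setNames(out$label, paste(out$hostId, out$phageId))
    expect_equal(lab[["h1 p1"]], 1L)   # above -> 1
    expect_equal(lab[["h2 p1"]], 0L)   # below -> 0
    expect_equal(lab[["h1 p2"]], 0L)   # exactly 1.5 -> 0
    expect_equal(attr(out, "nMissing"), 1L)
    expect_error(binarizeLabels(matrix(NA_real_, 2, 2,
        dimnames = list(c("a", "b"), c("c", "d")))), "all-missing")
})

test_that("interaction matrix CSV round-trips with missing cells intact", {
    tmp <- withr::local_tempdir()
    m <- matrix(c(1.7, NA, 0.3, 2.2), 2, 2,
                dimnames = list(c("h1", "h2"), c("p1", "p2")))
    path <- file.path(tmp, "m.csv")
    writeInteractionMatrix(m, path)
    back <- readInteractionMatrix(path)
    expect_equal(back, m)
    expect_true(is.na(back["h2", "p1"]))
})

test_that("pair combination modes keep or double the printed widths", {
    pairs <- data.frame(hostId = "h1", phageId = "p1", score = 2,
                        label = 1L)
    hs <- matrix(1:4 / 10, 1, 4, dimnames = list("h1", NULL))
    ps <- matrix(5:8 / 10, 1, 4, dimnames = list("p1", NULL))
    he <- matrix(rep(0.5, 6), 1, 6, dimnames = list("h1", NULL))
    pe <- matrix(rep(-0.5, 6), 1, 6, dimnames = list("p1", NULL))

    mean_ds <- assemblePairs(pairs, hs, ps, he, pe, he, pe, mode = "mean")
    expect_equal(ncol(statsBlock(mean_ds)), 4L)
    expect_equal(unname(statsBlock(mean_ds)[1, ]), (1:4 / 10 + 5:8 / 10) / 2)
    # mean of v and -v is the zero vector
    expect_equal(unname(expertBlock(mean_ds, 1L)[1, ]), rep(0, 6))

    cat_ds <- assemblePairs(pairs, hs, ps, he, pe, he, pe, mode = "concat")
    expect_equal(ncol(statsBlock(cat_ds)), 8L)
    expect_equal(ncol(expertBlock(cat_ds, 1L)), 12L)

    # identical phage and host vectors: mean is idempotent
    hsAsP <- hs; rownames(hsAsP) <- "p1"
    heAsP <- he; rownames(heAsP) <- "p1"
    same <- assemblePairs(pairs, hs, hsAsP, he, heAsP, he, heAsP,
                          mode = "mean")
    expect_equal(unname(statsBlock(same)[1, ]), unname(hs[1, ]))
    expect_equal(unname(expertBlock(same, 1L)[1, ]), unname(he[1, ]))
})

test_that("min-max normalization maps the fitted range to [0, 1]", {
    x <- matrix(c(0, 5, 10), 3, 1)
    p <- fitMinMax(x)
    expect_equal(as.vector(applyMinMax(x, p)), c(0, 0.5, 1))

    const <- matrix(7, 4, 1)
    expect_true(all(applyMinMax(const, fitMinMax(const)) == 0))

    set.seed(41)
    m <- matrix(rnorm(60), 12, 5)
    p <- fitMinMax(m)
    z <- applyMinMax(m, p)
    for (j in 1:5) {                       # column-scan oracle
        expect_equal(z[which.min(m[, j]), j], 0)
        expect_equal(z[which.max(m[, j]), j], 1)
    }
    expect_true(all(z >= 0 & z <= 1))
    # out-of-range values are not clipped
    probe <- matrix(max(m[, 1]) + 1, 1, 5)
    expect_gt(applyMinMax(probe, p)[1, 1], 1)
    expect_error(fitMinMax(matrix(numeric(0), 0, 3)), "empty")
})

test_that("oversampling equalizes counts by duplicating minority rows only", {
    ds <- makeTinyDataset(3, 7)
    out <- oversample(ds, seed = 5)
    expect_equal(sum(pairLabels(out) == 1L), 7L)
    expect_equal(sum(pairLabels(out) == 0L), 7L)
    # majority untouched, additions are copies of minority originals
    key <- function(d) paste(pairInfo(d)$phageId, pairInfo(d)$hostId)
    added <- table(key(out)) - table(key(ds))[names(table(key(out)))]
    minorityKeys <- key(ds)[pairLabels(ds) == 1L]
    expect_true(all(names(added)[added > 0] %in% minorityKeys))

    balanced <- makeTinyDataset(4, 4)
    expect_identical(oversample(balanced, 1), balanced)
    expect_error(oversample(makeTinyDataset(5, 0)), "both classes")
})

test_that("undersampling equalizes counts with a strict subset", {
    ds <- makeTinyDataset(3, 7)
    out <- undersample(ds, seed = 5)
    expect_equal(sum(pairLabels(out) == 1L), 3L)
    expect_equal(sum(pairLabels(out) == 0L), 3L)
    key <- function(d) paste(pairInfo(d)$phageId, pairInfo(d)$hostId)
    expect_true(all(key(out) %in% key(ds)))
    expect_equal(anyDuplicated(key(out)), 0L)

    balanced <- makeTinyDataset(4, 4)
    expect_identical(undersample(balanced, 1), balanced)
    expect_error(undersample(makeTinyDataset(0, 5)), "both classes")
})

test_that("stratified folds partition samples and preserve class ratios", {
    labels <- c(rep(1L, 10), rep(0L, 10))
    folds <- stratifiedFolds(labels, k = 5, seed = 3)
    expect_length(folds, 5)
    tests <- lapply(folds, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_along(labels))
    for (f in folds) {
        expect_equal(sum(labels[f$test] == 1L), 2L)
        expect_equal(sum(labels[f$test] == 0L), 2L)
        expect_equal(sort(c(f$train, f$test)), seq_along(labels))
    }

    # counting oracle on an uneven split: per-fold counts within 1
    set.seed(4)
    labels2 <- sample(c(rep(1L, 13), rep(0L, 22)))
    folds2 <- stratifiedFolds(labels2, k = 4, seed = 9)
    posCounts <- vapply(folds2, function(f) sum(labels2[f$test] == 1L),
                        integer(1))
    expect_lte(diff(range(posCounts)), 1L)
    expect_error(stratifiedFolds(c(1L, 1L, 0L), k = 2), ">= k")
})

test_that("resampled training folds never leak into the test fold", {
    ds <- makeTinyDataset(8, 24, seed = 6)
    folds <- stratifiedFolds(pairLabels(ds), k = 4, seed = 2)
    key <- function(d) paste(pairInfo(d)$phageId, pairInfo(d)$hostId)
    for (f in folds) {
        trainRes <- oversample(ds[f$train], seed = 8)
        expect_length(intersect(key(trainRes), key(ds[f$test])), 0L)
    }
})
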