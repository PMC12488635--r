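test_that("confusion counts match per-element enumeration", {
    c1 <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
    expect_equal(c1, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
    c2 <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
    expect_equal(c2$FP + c2$FN, 0L)

    set.seed(51)
    y <- rbinom(200, 1, 0.3); p <- rbinom(200, 1, 0.5)
    cc <- confusionCounts(y, p)
    oracle <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (i in seq_along(y)) {
        slot <- if (y[i] == 1 && p[i] == 1) "TP"
                else if (y[i] == 0 && p[i] == 1) "FP"
                else if (y[i] == 0 && p[i] == 0) "TN" else "FN"
        oracle[slot] <- oracle[slot] + 1L
    }
    expect_equal(unlist(cc), oracle)
    expect_equal(sum(unlist(cc)), length(y))
    expect_error(confusionCounts(c(1, 2), c(0, 1)), "binary")
})

test_that("threshold metrics apply the formulas literally, NA when undefined", {
    tm <- thresholdMetrics(list(TP = 8, FP = 2, TN = 5, FN = 5))
    expect_equal(tm$acc, 0.65)
    expect_equal(tm$prec, 0.8)
    expect_equal(tm$sens, 8 / 13, tolerance = 1e-4)
    expect_equal(tm$spec, 5 / 7, tolerance = 1e-4)
    expect_equal(tm$f1, 2 * 0.8 * (8 / 13) / (0.8 + 8 / 13),
                 tolerance = 1e-4)

    perfect <- thresholdMetrics(list(TP = 4, FP = 0, TN = 6, FN = 0))
    expect_true(all(unlist(perfect) == 1))

    # no predicted positives: precision undefined, never 0
    deg <- thresholdMetrics(list(TP = 0, FP = 0, TN = 9, FN = 3))
    expect_true(is.na(deg$prec))
    expect_true(is.na(deg$f1))
    expect_equal(deg$spec, 1)

    # F1 equals the harmonic-mean closed form whenever both are defined
    set.seed(52)
    for (i in 1:25) {
        counts <- as.list(setNames(rpois(4, 6) + 1, c("TP","FP","TN","FN")))
        tm <- thresholdMetrics(counts)
        expect_equal(tm$f1, 2 / (1 / tm$prec + 1 / tm$sens))
        expect_equal(tm$acc, (counts$TP + counts$TN) / sum(unlist(counts)))
    }
})

test_that("AUC equals the exhaustive pairwise statistic with tie handling", {
    expect_equal(aucScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
    expect_equal(aucScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
    expect_true(is.na(aucScore(c(1, 1), c(0.3, 0.4))))

    set.seed(53)
    for (i in 1:20) {
        y <- rbinom(30, 1, 0.4)
        if (length(unique(y)) < 2) next
        sc <- sample(round(runif(30), 2))    # rounded: forces ties
        expect_equal(aucScore(y, sc), oracleAUC(y, sc))
    }
})

test_that("AUC is monotone-transform invariant and label-swap symmetric", {
    set.seed(54)
    y <- rbinom(60, 1, 0.35)
    sc <- rnorm(60)
    a <- aucScore(y, sc)
    expect_equal(aucScore(y, exp(sc)), a)
    expect_equal(aucScore(y, 2 * sc + 7), a)
    expect_equal(aucScore(y, -sc), 1 - a)
})

test_that("AUPR matches a brute-force sweep and concentrates at prevalence", {
    expect_equal(auprScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
    expect_true(is.na(auprScore(c(0, 0), c(0.1, 0.9))))

    set.seed(55)
    for (i in 1:20) {
        y <- rbinom(10, 1, 0.4)
        if (sum(y) == 0) next
        sc <- round(runif(10), 1)
        expect_equal(auprScore(y, sc), oracleAUPR(y, sc))
    }

    yBig <- rbinom(10000, 1, 0.2)
    expect_equal(auprScore(yBig, runif(10000)), 0.2, tolerance = 0.03)
})

test_that("fold aggregation is NA-aware and matches arithmetic", {
    r1 <- evalReport(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0.9, 0.4, 0.3, 0.1),
                     fold = 1)
    expect_equal(r1$acc, 0.75)
    same <- rbind(r1, r1, r1)
    agg <- aggregateFolds(same)
    expect_equal(agg$mean[agg$metric == "acc"], 0.75)
    expect_equal(agg$sd[agg$metric == "acc"], 0)

    # one degenerate fold: mean over the defined rest, flagged count 1
    r2 <- evalReport(c(1, 1, 0, 0), c(0, 0, 0, 0), c(0.2, 0.1, 0.4, 0.3),
                     fold = 2)
    expect_true(is.na(r2$prec))
    agg2 <- aggregateFolds(rbind(r1, r2))
    precRow <- agg2[agg2$metric == "prec", ]
    expect_equal(precRow$nUndefined, 1L)
    expect_equal(precRow$mean, r1$prec)

    set.seed(56)
    reps <- do.call(rbind, lapply(1:5, function(f) {
        y <- rbinom(30, 1, 0.5); sc <- runif(30)
        evalReport(y, as.integer(sc > 0.5), sc, fold = f)
    }))
    agg3 <- aggregateFolds(reps)
    expect_equal(agg3$mean[agg3$metric == "auc"], mean(reps$auc))
    expect_equal(agg3$sd[agg3$metric == "f1"], sd(reps$f1))
})

test_that("report writer emits valid JSON and a Markdown table", {
    tmp <- withr::local_tempdir()
    r <- evalReport(c(1, 0, 1, 0), c(1, 0, 0, 0), c(0.8, 0.2, 0.4, 0.3),
                    fold = 1)
    paths <- writeEvalReports(r, tmp)
    j <- jsonlite::read_json(file.path(tmp, "metrics.json"))
    expect_equal(j$folds[[1]]$acc, 0.75)
    md <- readLines(file.path(tmp, "metrics.md"))
    expect_true(any(grepl("^\\| ACC", md)))
})
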