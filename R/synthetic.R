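# Seeded synthetic fixture generators: desk-scale inputs with the
# structure the pipeline assumes (entities with several protein
# sequences over the 20-letter alphabet, a continuous infection-score
# matrix straddling the 1.5 threshold, configurable class imbalance,
# and a specialization scenario with known ground-truth gating
# structure). Every generator is a pure function of the FixtureSpec.

#' Specification for the synthetic fixture generators
#'
#' @param nHosts,nPhages Entity counts (>= 1).
#' @param proteinsPerEntity Length-2 range of proteins per entity.
#' @param seqLength Length-2 range of protein sequence lengths.
#' @param positiveFraction Target fraction of cells whose score
#'   exceeds the 1.5 labelling threshold; must lie in \[0.02, 0.98\]
#'   (values near 0 or 1 leave a class empty at desk scale and are
#'   rejected).
#' @param noiseScale Scale of the score spread around the threshold.
#' @param embedDim Width d of the synthetic expert embeddings.
#' @param seed Integer seed fixing all generator output.
#' @param flagColumn Index of the stats feature carrying the binary
#'   routing flag in the specialization scenario.
#' @param n Number of samples for the specialization / separable
#'   scenarios.
#' @return A validated `fixtureSpec` list.
#' @export
fixtureSpec <- function(nHosts = 8L, nPhages = 10L,
                        proteinsPerEntity = c(1L, 3L),
                        seqLength = c(60L, 180L),
                        positiveFraction = 0.2,
                        noiseScale = 0.5,
                        embedDim = 16L,
                        seed = 1L,
                        flagColumn = 1L,
                        n = 400L) {
    stopifnot(nHosts >= 1L, nPhages >= 1L,
              length(proteinsPerEntity) == 2L,
              proteinsPerEntity[1L] >= 1L,
              length(seqLength) == 2L, seqLength[1L] >= 1L,
              noiseScale > 0, embedDim >= 2L, n >= 4L)
    if (positiveFraction < 0.02 || positiveFraction > 0.98)
        stop("positiveFraction must be in [0.02, 0.98]")
    structure(list(nHosts = as.integer(nHosts),
                   nPhages = as.integer(nPhages),
                   proteinsPerEntity = as.integer(proteinsPerEntity),
                   seqLength = as.integer(seqLength),
                   positiveFraction = positiveFraction,
                   noiseScale = noiseScale,
                   embedDim = as.integer(embedDim),
                   seed = as.integer(seed),
                   flagColumn = as.integer(flagColumn),
                   n = as.integer(n)),
              class = "fixtureSpec")
}

.randomSequences <- function(count, lenRange) {
    vapply(seq_len(count), function(i) {
        len <- sample(lenRange[1L]:lenRange[2L], 1L)
        paste(sample(.AA_ALPHABET, len, replace = TRUE), collapse = "")
    }, character(1L))
}

.genEntityList <- function(spec, prefix, count) {
    lapply(setNames(seq_len(count), sprintf("%s%03d", prefix,
                                            seq_len(count))),
           function(i) {
               k <- sample(spec$proteinsPerEntity[1L]:
                           spec$proteinsPerEntity[2L], 1L)
               .randomSequences(k, spec$seqLength)
           })
}

#' Generate random host and phage protein entities
#'
#' Uniform sequences over the 20-letter alphabet, deterministic per
#' seed. If `dir` is given, `hosts.fasta` and `phages.fasta` are
#' written (one record per protein, header `<entityId> protein <k>`,
#' byte-identical across runs with the same spec).
#'
#' @param spec A [fixtureSpec()].
#' @param dir Optional output directory for FASTA files.
#' @return List with named sequence lists `hosts` and `phages` (and
#'   `paths` when written).
#' @export
genEntities <- function(spec, dir = NULL) {
    stopifnot(inherits(spec, "fixtureSpec"))
    out <- .withSeed(spec$seed, {
        list(hosts = .genEntityList(spec, "host", spec$nHosts),
             phages = .genEntityList(spec, "phage", spec$nPhages))
    })
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        paths <- c(hosts = file.path(dir, "hosts.fasta"),
                   phages = file.path(dir, "phages.fasta"))
        for (grp in c("hosts", "phages")) {
            recs <- unlist(lapply(names(out[[grp]]), function(id) {
                seqs <- out[[grp]][[id]]
                setNames(seqs, sprintf("%s protein %d", id,
                                       seq_along(seqs)))
            }))
            aa <- Biostrings::AAStringSet(recs)
            Biostrings::writeXStringSet(aa, paths[[grp]])
        }
        out$paths <- paths
    }
    out
}

#' Generate a continuous infection-score matrix
#'
#' Each cell is positive with probability `positiveFraction`;
#' positives score `1.5 + gap`, negatives `1.5 - gap`, with
#' exponential gaps of scale `noiseScale` (plus a 0.01 guard so no
#' score sits exactly on the threshold). Scores therefore straddle
#' 1.5 and binarization recovers the requested positive fraction up
#' to binomial noise.
#'
#' @param spec A [fixtureSpec()].
#' @return Numeric hosts x phages matrix with entity ids as dimnames.
#' @export
genInteractionMatrix <- function(spec) {
    stopifnot(inherits(spec, "fixtureSpec"))
    .withSeed(spec$seed + 1L, {
        nCell <- spec$nHosts * spec$nPhages
        pos <- runif(nCell) < spec$positiveFraction
        gap <- 0.01 + stats::rexp(nCell, rate = 1 / spec$noiseScale)
        scores <- ifelse(pos, 1.5 + gap, pmax(1.5 - gap, 0))
        matrix(scores, spec$nHosts, spec$nPhages,
               dimnames = list(sprintf("host%03d", seq_len(spec$nHosts)),
                               sprintf("phage%03d", seq_len(spec$nPhages))))
    })
}

#' Assemble a full synthetic PairDataset
#'
#' Runs the real pipeline stages on generated inputs: entities ->
#' descriptors, synthetic expert embeddings (two streams with
#' different provider seeds), score matrix -> threshold labels ->
#' assembled pairs.
#'
#' @param spec A [fixtureSpec()].
#' @param mode Pair combination mode, `"mean"` or `"concat"`.
#' @return A [PairDataset-class].
#' @export
genPairDataset <- function(spec, mode = "mean") {
    ents <- genEntities(spec)
    scores <- genInteractionMatrix(spec)
    pairs <- binarizeLabels(scores)
    spec1 <- providerSpec("synthetic", d = spec$embedDim,
                          seed = spec$seed + 11L)
    spec2 <- providerSpec("synthetic", d = spec$embedDim,
                          seed = spec$seed + 23L)
    assemblePairs(pairs,
                  hostStats = statsMatrix(ents$hosts),
                  phageStats = statsMatrix(ents$phages),
                  hostExpert1 = embedEntities(spec1, ents$hosts),
                  phageExpert1 = embedEntities(spec1, ents$phages),
                  hostExpert2 = embedEntities(spec2, ents$hosts),
                  phageExpert2 = embedEntities(spec2, ents$phages),
                  mode = mode)
}

#' Specialization scenario with known gating ground truth
#'
#' Generates `n` samples whose label rule depends on expert 1 when a
#' designated binary stats flag is 1 and on expert 2 when the flag is
#' 0: `label = step(w . expert_relevant)` with a single shared signal
#' weight vector `w`. A model that recovers the routing structure
#' must weight expert 1 higher on flag-1 samples. Samples within a
#' small margin of the decision boundary are redrawn so the rule is
#' cleanly learnable.
#'
#' @param spec A [fixtureSpec()]; uses `n`, `embedDim`, `flagColumn`,
#'   `seed`.
#' @param sStats Width of the stats block (default 6).
#' @param margin Minimum |w . expert| accepted (default 0.5).
#' @return A [PairDataset-class] with attributes `weights` (the true
#'   w), `flag` (the per-sample routing flag) and `flagColumn`.
#' @export
genSpecializationDataset <- function(spec, sStats = 6L, margin = 0.5) {
    stopifnot(inherits(spec, "fixtureSpec"),
              spec$flagColumn <= sStats)
    d <- spec$embedDim
    n <- spec$n
    .withSeed(spec$seed + 2L, {
        w <- rnorm(d)
        w <- w / sqrt(sum(w^2))
        flag <- as.integer(runif(n) < 0.5)
        stats <- matrix(runif(n * sStats), n, sStats)
        stats[, spec$flagColumn] <- flag
        draw <- function(count) matrix(runif(count * d, -1, 1), count, d)
        e1 <- draw(n); e2 <- draw(n)
        # redraw boundary-hugging rows of the relevant expert
        for (iter in seq_len(50L)) {
            rel <- ifelse(flag == 1L, abs(e1 %*% w), abs(e2 %*% w))
            bad <- which(rel < margin)
            if (!length(bad)) break
            e1[bad, ] <- draw(length(bad))
            e2[bad, ] <- draw(length(bad))
        }
        signal <- ifelse(flag == 1L, e1 %*% w, e2 %*% w)
        label <- as.integer(signal > 0)
        ds <- PairDataset(stats = stats, expert1 = e1, expert2 = e2,
                          phageId = sprintf("p%04d", seq_len(n)),
                          hostId = sprintf("h%04d", seq_len(n)),
                          label = label)
        attr(ds, "weights") <- w
        attr(ds, "flag") <- flag
        attr(ds, "flagColumn") <- spec$flagColumn
        ds
    })
}

#' Linearly separable toy dataset
#'
#' Labels follow a linear rule on the element-wise mean of the two
#' expert blocks plus the stats block, with a margin, so a correctly
#' wired gate + CNN can fit it to high accuracy within a few dozen
#' epochs.
#'
#' @param spec A [fixtureSpec()]; uses `n`, `embedDim`, `seed`.
#' @param sStats Width of the stats block (default 3).
#' @param margin Minimum |signal| accepted (default 0.5).
#' @return A [PairDataset-class] with attribute `weights`.
#' @export
genSeparableDataset <- function(spec, sStats = 3L, margin = 0.5) {
    stopifnot(inherits(spec, "fixtureSpec"))
    d <- spec$embedDim
    n <- spec$n
    .withSeed(spec$seed + 3L, {
        w <- rnorm(d); w <- w / sqrt(sum(w^2))
        stats <- matrix(runif(n * sStats), n, sStats)
        draw <- function(count) matrix(runif(count * d, -1, 1), count, d)
        e1 <- draw(n); e2 <- draw(n)
        for (iter in seq_len(50L)) {
            signal <- ((e1 + e2) / 2) %*% w
            bad <- which(abs(signal) < margin)
            if (!length(bad)) break
            e1[bad, ] <- draw(length(bad))
            e2[bad, ] <- draw(length(bad))
        }
        label <- as.integer(((e1 + e2) / 2) %*% w > 0)
        ds <- PairDataset(stats = stats, expert1 = e1, expert2 = e2,
                          phageId = sprintf("p%04d", seq_len(n)),
                          hostId = sprintf("h%04d", seq_len(n)),
                          label = label)
        attr(ds, "weights") <- w
        ds
    })
}
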