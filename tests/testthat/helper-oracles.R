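# Independent brute-force oracles, deliberately written as plain loops
# so they share no code path with the package implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomSeq <- function(len) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# letter-counting oracle for amino acid composition
oracleAAC <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    vapply(AA20, function(a) sum(chars == a) / length(chars), numeric(1))
}

# per-residue accumulation oracle for atomic composition
oracleAC <- function(seq, tab) {
    chars <- strsplit(seq, "")[[1]]
    totals <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (ch in chars) {
        row <- tab[tab$code == ch, ]
        for (el in names(totals)) totals[el] <- totals[el] + row[[el]]
    }
    totals / sum(totals)
}

# residue-by-residue mass summation oracle
oracleMW <- function(seq, tab) {
    chars <- strsplit(seq, "")[[1]]
    total <- 0
    for (ch in chars) total <- total + tab$mass[tab$code == ch]
    total
}

# straightforward per-sample two-layer forward oracle for the gate
oracleGate <- function(W1, b1, W2, b2, statsRow) {
    h <- as.vector(statsRow %*% W1) + b1
    h[h < 0] <- 0
    g <- as.vector(h %*% W2) + b2
    e <- exp(g - max(g))
    list(H = h, G = g, alpha = e / sum(e))
}

# exhaustive pairwise-comparison AUC with ties counted one half
oracleAUC <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    if (!length(pos) || !length(neg)) return(NA_real_)
    total <- 0
    for (p in pos) {
        for (q in neg) {
            total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
        }
    }
    total / (length(pos) * length(neg))
}

# brute-force precision/recall sweep over descending unique scores
oracleAUPR <- function(labels, scores) {
    nPos <- sum(labels == 1)
    if (nPos == 0) return(NA_real_)
    cuts <- sort(unique(scores), decreasing = TRUE)
    prevRecall <- 0
    area <- 0
    for (cut in cuts) {
        pred <- as.integer(scores >= cut)
        tp <- sum(pred == 1 & labels == 1)
        prec <- tp / sum(pred == 1)
        recall <- tp / nPos
        area <- area + (recall - prevRecall) * prec
        prevRecall <- recall
    }
    area
}

# tiny labelled dataset for resampling / training unit tests
makeTinyDataset <- function(nPos, nNeg, d = 6L, s = 4L, seed = 1L) {
    set.seed(seed)
    n <- nPos + nNeg
    PairDataset(
        stats = matrix(runif(n * s), n, s),
        expert1 = matrix(runif(n * d, -1, 1), n, d),
        expert2 = matrix(runif(n * d, -1, 1), n, d),
        phageId = sprintf("p%03d", seq_len(n)),
        hostId = sprintf("h%03d", seq_len(n)),
        label = c(rep(1L, nPos), rep(0L, nNeg))
    )
}
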