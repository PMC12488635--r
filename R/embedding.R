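# Embedding providers: the two high-dimensional "expert" streams are
# consumed as fixed-length per-entity vectors through a uniform
# contract. The synthetic provider is a pure function of (seed,
# sequence content) so every test and fixture is reproducible without
# any pre-trained model; the table provider reads precomputed
# per-entity vectors from TSV.

#' Describe an embedding provider
#'
#' @param name `"synthetic"` (content-addressed seeded vectors) or
#'   `"table"` (precomputed per-entity TSV).
#' @param d Embedding width (>= 2); both expert streams of a run must
#'   share the same d. Default 1024, the width of the pre-trained
#'   protein language-model embeddings the pipeline was designed
#'   around.
#' @param seed Integer seed (synthetic provider only).
#' @param path TSV path (table provider only).
#' @param pool `"mean"` or `"max"` pooling of per-protein vectors into
#'   one per-entity vector.
#' @return A `providerSpec` list.
#' @export
providerSpec <- function(name = c("synthetic", "table"), d = 1024L,
                         seed = 1L, path = NULL,
                         pool = c("mean", "max")) {
    name <- match.arg(name)
    pool <- match.arg(pool)
    d <- as.integer(d)
    if (is.na(d) || d < 2L) stop("embedding width d must be >= 2")
    if (name == "table" && is.null(path))
        stop("table provider needs a path")
    structure(list(name = name, d = d, seed = as.integer(seed),
                   path = path, pool = pool),
              class = "providerSpec")
}

# deterministic 31-bit string hash (Horner scheme); pure arithmetic so
# it is identical across platforms and R sessions
.hashString <- function(s) {
    codes <- utf8ToInt(s)
    h <- 0
    for (k in codes) h <- (h * 31 + k) %% 2147483647
    as.integer(h)
}

# run expr under a temporary RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Deterministic synthetic embedding of a set of sequences
#'
#' A pure function of `(seed, sequence content)`: each sequence is
#' hashed, the hash (combined with the seed) seeds a uniform draw in
#' \[-1, 1\]^d, and per-sequence vectors are pooled into one entity
#' vector. Content addressing means the order of the sequences never
#' matters, and identical inputs give bit-identical vectors across
#' processes.
#'
#' @param seed Integer provider seed.
#' @param d Embedding width (>= 2).
#' @param sequences Character vector of (sanitized) sequences.
#' @param pool `"mean"` or `"max"`.
#' @return Numeric vector of length d with values in \[-1, 1\].
#' @export
syntheticEmbed <- function(seed, d, sequences, pool = c("mean", "max")) {
    pool <- match.arg(pool)
    d <- as.integer(d)
    stopifnot(d >= 2L, length(sequences) >= 1L)
    sequences <- sort(sequences)
    per <- vapply(sequences, function(s) {
        .withSeed((as.integer(seed) + .hashString(s)) %% 2147483647,
                  runif(d, -1, 1))
    }, numeric(d))
    # per is d x nseq
    if (pool == "mean") rowMeans(per) else apply(per, 1L, max)
}

#' Embed one entity through a provider
#'
#' @param spec A [providerSpec()].
#' @param sequences Character vector of the entity's sanitized protein
#'   sequences (at least one).
#' @param entityId Identifier, required for the table provider lookup.
#' @return Numeric vector of length `spec$d`.
#' @export
embedEntity <- function(spec, sequences, entityId = NULL) {
    stopifnot(inherits(spec, "providerSpec"), length(sequences) >= 1L)
    if (spec$name == "synthetic") {
        return(syntheticEmbed(spec$seed, spec$d, sequences, spec$pool))
    }
    tab <- loadEmbeddingTable(spec$path)
    if (is.null(entityId) || !entityId %in% rownames(tab)) {
        stop("entity '", entityId %||% "<missing>",
             "' not found in embedding table ", spec$path)
    }
    v <- tab[entityId, ]
    if (length(v) != spec$d)
        stop("embedding table width ", length(v),
             " does not match requested d = ", spec$d)
    unname(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed every entity in a grouped sequence list
#'
#' @param spec A [providerSpec()].
#' @param entities Named list of sequence vectors, as from
#'   [readEntityProteins()].
#' @return Numeric matrix, one row per entity, `spec$d` columns.
#' @export
embedEntities <- function(spec, entities) {
    stopifnot(is.list(entities), !is.null(names(entities)))
    out <- t(vapply(names(entities),
                    function(id) embedEntity(spec, entities[[id]], id),
                    numeric(spec$d)))
    rownames(out) <- names(entities)
    out
}

#' Read a per-entity embedding table
#'
#' Strict TSV: header `id` then `e0001 .. e{d}`, every row exactly
#' 1 + d fields; a ragged or non-numeric row is rejected with its line
#' number.
#'
#' @param path TSV file.
#' @return Numeric matrix with entity ids as rownames.
#' @export
loadEmbeddingTable <- function(path) {
    if (!file.exists(path)) stop("embedding table not found: ", path)
    lines <- readLines(path)
    if (length(lines) < 2L) stop("embedding table has no data rows: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    width <- length(fields[[1L]])
    if (width < 3L || fields[[1L]][1L] != "id")
        stop("embedding table header must be 'id' plus >= 2 columns")
    rows <- vector("list", length(lines) - 1L)
    ids <- character(length(lines) - 1L)
    for (i in seq_along(rows)) {
        f <- fields[[i + 1L]]
        if (length(f) != width)
            stop("embedding table ", path, ": line ", i + 1L, " has ",
                 length(f), " fields, expected ", width)
        v <- suppressWarnings(as.numeric(f[-1L]))
        if (anyNA(v))
            stop("embedding table ", path, ": line ", i + 1L,
                 " has non-numeric values")
        ids[i] <- f[1L]
        rows[[i]] <- v
    }
    out <- do.call(rbind, rows)
    rownames(out) <- ids
    colnames(out) <- fields[[1L]][-1L]
    out
}

#' Write a per-entity embedding table
#'
#' Inverse of [loadEmbeddingTable()]: header `id` then
#' `e0001 .. e{d}`, values at full precision (round-trip identity).
#'
#' @param mat Numeric matrix with entity ids as rownames.
#' @param path Output TSV file.
#' @export
writeEmbeddingTable <- function(mat, path) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)))
    d <- ncol(mat)
    header <- c("id", sprintf("e%04d", seq_len(d)))
    body <- vapply(seq_len(nrow(mat)), function(i) {
        paste(c(rownames(mat)[i],
                format(mat[i, ], digits = 17, trim = TRUE,
                       scientific = FALSE)),
              collapse = "\t")
    }, character(1L))
    writeLines(c(paste(header, collapse = "\t"), body), path)
    invisible(path)
}
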