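#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head
NULL

#' Sanitize a raw protein sequence
#'
#' Uppercases the sequence and removes every character outside the
#' 20-letter standard amino-acid alphabet (ambiguity codes X/B/Z/J, the
#' rare U/O, stop `*`, gap characters, whitespace and digits). A warning
#' reports how many characters were dropped; a sequence with nothing
#' left is an error naming the offending record.
#'
#' @param raw Character scalar, the raw sequence.
#' @param id Record identifier used in warnings/errors.
#' @return Character scalar over the 20-letter alphabet, length >= 1.
#' @examples
#' sanitizeSequence("acd")      # "ACD"
#' suppressWarnings(sanitizeSequence("AXC*"))  # "AC"
#' @export
sanitizeSequence <- function(raw, id = "<unnamed>") {
    stopifnot(is.character(raw), length(raw) == 1L)
    up <- toupper(gsub("\\s", "", raw))
    if (!nzchar(up)) {
        stop("sequence '", id, "' is empty")
    }
    chars <- strsplit(up, "", fixed = TRUE)[[1L]]
    keep <- chars %in% .AA_ALPHABET
    nDropped <- sum(!keep)
    if (nDropped > 0L) {
        dropped <- table(chars[!keep])
        warning(sprintf(
            "sequence '%s': dropped %d non-standard character(s) (%s)",
            id, nDropped,
            paste(names(dropped), dropped, sep = "x", collapse = ", ")
        ), call. = FALSE)
    }
    out <- paste(chars[keep], collapse = "")
    if (!nzchar(out)) {
        stop("sequence '", id, "' has no standard amino-acid characters ",
             "left after sanitization")
    }
    out
}

.checkSanitized <- function(seq) {
    stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% .AA_ALPHABET)) {
        stop("sequence contains non-standard characters; ",
             "run sanitizeSequence() first")
    }
    chars
}

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues: `AAC_i = n_i / L`
#' where `n_i` is the count of residue i and `L` the sequence length.
#' Returned in alphabetical one-letter order; the fractions sum to 1.
#'
#' @param seq Sanitized sequence (see [sanitizeSequence()]).
#' @return Named numeric vector of 20 fractions.
#' @examples
#' aminoAcidComposition("ACDE")
#' @export
aminoAcidComposition <- function(seq) {
    chars <- .checkSanitized(seq)
    counts <- table(factor(chars, levels = .AA_ALPHABET))
    setNames(as.vector(counts) / length(chars), .AA_ALPHABET)
}

#' Atomic composition (AC)
#'
#' Fraction of C, H, N, O and S atoms contributed by the sequence's
#' residues, counting the elemental formula of each free amino acid:
#' `AC_j = a_j / sum_k a_k`. The five fractions sum to 1.
#'
#' @inheritParams aminoAcidComposition
#' @param tables Residue table as from [residueTables()].
#' @return Named numeric vector of 5 fractions, order C, H, N, O, S.
#' @examples
#' atomicComposition("GG")  # identical to atomicComposition("G")
#' @export
atomicComposition <- function(seq, tables = residueTables()) {
    chars <- .checkSanitized(seq)
    counts <- as.vector(table(factor(chars, levels = tables$code)))
    atoms <- vapply(.ELEMENTS,
                    function(el) sum(counts * tables[[el]]),
                    numeric(1L))
    atoms / sum(atoms)
}

#' Molecular weight (MW)
#'
#' Summed mass of the sequence, `MW(S) = sum_i n_i * M(A_i)` with
#' `M(A_i)` the average mass of the free amino acid. This is the literal
#' weighted sum of residue counts times table masses; no water-loss
#' correction is applied, so concatenation is additive:
#' `MW(s1 || s2) = MW(s1) + MW(s2)`.
#'
#' @inheritParams atomicComposition
#' @return Mass in daltons.
#' @examples
#' molecularWeight("GG") == 2 * molecularWeight("G")
#' @export
molecularWeight <- function(seq, tables = residueTables()) {
    chars <- .checkSanitized(seq)
    counts <- as.vector(table(factor(chars, levels = tables$code)))
    sum(counts * tables$mass)
}

#' Full 26-dimensional statistical descriptor vector
#'
#' Fixed, documented concatenation: 20 AAC fractions (alphabetical
#' one-letter order), then 5 AC fractions (C, H, N, O, S), then MW.
#'
#' @inheritParams atomicComposition
#' @return Named numeric vector of length 26.
#' @export
statsVector <- function(seq, tables = residueTables()) {
    c(aminoAcidComposition(seq),
      atomicComposition(seq, tables),
      MW = molecularWeight(seq, tables))
}

#' Per-entity statistical descriptor matrix
#'
#' Computes the 26-feature descriptor for every entity in a named list
#' of sanitized protein sequences (one entity may own several
#' proteins); multi-protein entities are reduced to one row by pooling
#' the per-protein descriptor vectors.
#'
#' @param entities Named list; each element a character vector of
#'   sanitized sequences for one entity.
#' @param pool `"mean"` (default) or `"max"` pooling across an entity's
#'   proteins.
#' @param tables Residue table as from [residueTables()].
#' @return Numeric matrix, one row per entity, 26 columns.
#' @export
statsMatrix <- function(entities, pool = c("mean", "max"),
                        tables = residueTables()) {
    pool <- match.arg(pool)
    stopifnot(is.list(entities), length(entities) >= 1L,
              !is.null(names(entities)))
    poolFun <- if (pool == "mean") colMeans else function(m) apply(m, 2L, max)
    rows <- lapply(entities, function(seqs) {
        per <- t(vapply(seqs, statsVector, numeric(26L), tables = tables))
        poolFun(per)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- names(entities)
    out
}

#' Read entity-grouped protein sequences from a FASTA file
#'
#' Records are parsed with [Biostrings::readAAStringSet()]; the entity
#' id is extracted from each record description with `idRegex` (first
#' capture group; default = the first whitespace-delimited token), and
#' records sharing an id are grouped into one entity. Sequences are
#' sanitized on the way in.
#'
#' @param path FASTA file.
#' @param idRegex Regex whose first capture group is the entity id.
#' @return Named list of character vectors of sanitized sequences.
#' @export
readEntityProteins <- function(path, idRegex = "^(\\S+)") {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L) stop("no records in FASTA file: ", path)
    ids <- sub(paste0(idRegex, ".*$"), "\\1", names(aa))
    seqs <- as.character(aa)
    clean <- mapply(sanitizeSequence, seqs, names(aa),
                    SIMPLIFY = TRUE, USE.NAMES = FALSE)
    split(clean, factor(ids, levels = unique(ids)))
}

#' Write a per-entity descriptor table as TSV
#'
#' 27 columns: `id` plus the 26 named features, full precision.
#'
#' @param stats Matrix from [statsMatrix()].
#' @param path Output file.
#' @export
writeDescriptorTable <- function(stats, path) {
    stopifnot(is.matrix(stats), ncol(stats) == 26L)
    df <- data.frame(id = rownames(stats), stats,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
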