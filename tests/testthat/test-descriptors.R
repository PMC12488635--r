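test_that("sanitization uppercases, drops non-standard codes, errors on empty", {
    expect_identical(sanitizeSequence("acd"), "ACD")
    expect_warning(out <- sanitizeSequence("AXC*", id = "rec1"),
                   "dropped 2")
    expect_identical(out, "AC")
    expect_error(suppressWarnings(sanitizeSequence("XXX", id = "rec2")),
                 "rec2")
    expect_error(sanitizeSequence("  ", id = "rec3"), "empty")
})

test_that("amino acid composition matches direct counting", {
    homo <- aminoAcidComposition("AAAA")
    expect_equal(unname(homo[["A"]]), 1)
    expect_equal(sum(homo), 1)
    expect_true(all(homo[setdiff(names(homo), "A")] == 0))

    quad <- aminoAcidComposition("ACDE")
    expect_equal(unname(quad[c("A", "C", "D", "E")]),
                 rep(0.25, 4), ignore_attr = TRUE)

    set.seed(11)
    s <- randomSeq(50)
    expect_equal(unname(aminoAcidComposition(s)), unname(oracleAAC(s)))
})

test_that("atomic composition is a scale-invariant atom-count ratio", {
    tab <- residueTables()
    one <- atomicComposition("G", tab)
    gRow <- tab[tab$code == "G", c("C", "H", "N", "O", "S")]
    expect_equal(unname(one), unlist(gRow) / sum(gRow),
                 ignore_attr = TRUE)
    expect_equal(atomicComposition("GG", tab), atomicComposition("G", tab))
    expect_equal(sum(one), 1)

    set.seed(12)
    s <- randomSeq(30)
    expect_equal(unname(atomicComposition(s, tab)),
                 unname(oracleAC(s, tab)))
})

test_that("molecular weight is the literal residue-mass sum, additive", {
    tab <- residueTables()
    expect_equal(molecularWeight("G"), tab$mass[tab$code == "G"])
    expect_equal(molecularWeight("GG"), 2 * tab$mass[tab$code == "G"])
    set.seed(13)
    s1 <- randomSeq(40); s2 <- randomSeq(25)
    expect_equal(molecularWeight(s1), oracleMW(s1, tab))
    expect_equal(molecularWeight(paste0(s1, s2)),
                 molecularWeight(s1) + molecularWeight(s2))
})

test_that("stats vector is the documented 20 + 5 + 1 concatenation", {
    v <- statsVector("AAAA")
    expect_length(v, 26)
    expect_equal(unname(v[1]), 1)
    expect_true(all(v[2:20] == 0))

    set.seed(14)
    s <- randomSeq(35)
    v <- statsVector(s)
    expect_equal(unname(v[1:20]), unname(aminoAcidComposition(s)))
    expect_equal(unname(v[21:25]), unname(atomicComposition(s)))
    expect_equal(unname(v[26]), molecularWeight(s))
})

test_that("descriptors are permutation invariant and blocks sum to one", {
    set.seed(15)
    for (i in 1:20) {
        s <- randomSeq(sample(5:80, 1))
        v <- statsVector(s)
        expect_equal(sum(v[1:20]), 1, tolerance = 1e-9)
        expect_equal(sum(v[21:25]), 1, tolerance = 1e-9)
        expect_gt(v[26], 0)
        perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
        expect_equal(statsVector(perm), v)
    }
})

test_that("FASTA round trip: entity grouping, pooling, TSV export", {
    tmp <- withr::local_tempdir()
    fa <- file.path(tmp, "ent.fasta")
    writeLines(c(">entA protein 1", "ACDE", ">entA protein 2", "GGGG",
                 ">entB protein 1", "MKLV"), fa)
    ents <- readEntityProteins(fa)
    expect_named(ents, c("entA", "entB"))
    expect_length(ents$entA, 2)

    m <- statsMatrix(ents)
    expect_equal(dim(m), c(2L, 26L))
    expect_equal(unname(m["entA", ]),
                 unname((statsVector("ACDE") + statsVector("GGGG")) / 2))
    mx <- statsMatrix(ents, pool = "max")
    expect_equal(unname(mx["entB", ]), unname(statsVector("MKLV")))

    out <- file.path(tmp, "desc.tsv")
    writeDescriptorTable(m, out)
    back <- read.delim(out, check.names = FALSE)
    expect_equal(ncol(back), 27L)
    expect_equal(back$id, c("entA", "entB"))
    expect_equal(as.numeric(back[1, -1]), unname(m[1, ]))
})

test_that("CRLF and LF FASTA parse identically", {
    tmp <- withr::local_tempdir()
    lf <- file.path(tmp, "lf.fasta"); crlf <- file.path(tmp, "crlf.fasta")
    writeLines(c(">e1 x", "ACDE"), lf)
    writeBin(charToRaw(">e1 x\r\nACDE\r\n"), crlf)
    expect_identical(readEntityProteins(lf), readEntityProteins(crlf))
})
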