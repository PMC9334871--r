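test_that("self-alignment scores the matrix diagonal at 100% identity", {
    s <- "HEAGAWGHEE"
    sub <- flowAbVal:::getSubstitutionMatrix("BLOSUM62")
    chars <- strsplit(s, "")[[1]]
    expected <- sum(sub[cbind(chars, chars)])
    for (mode in c("local", "global")) {
        r <- alignPair(s, s, mode = mode)
        expect_equal(r@score, expected)
        expect_equal(r@identity, 100)
        expect_equal(r@gaps, 0L)
    }
})

test_that("alignment scores are symmetric in their arguments", {
    set.seed(5)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:10) {
        a <- paste(sample(aas, 8, TRUE), collapse = "")
        b <- paste(sample(aas, 12, TRUE), collapse = "")
        expect_equal(alignLocal(a, b)@score, alignLocal(b, a)@score)
        expect_equal(alignGlobal(a, b)@score, alignGlobal(b, a)@score)
    }
})

test_that("DP scores equal the exhaustive-enumeration oracle", {
    sub <- testSubmat()
    alphabet <- rownames(sub)
    # every pair up to length 2, plus seeded random pairs up to length 6,
    # under both gap-cost conventions
    short <- unlist(lapply(1:2, function(L)
        apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")))
    set.seed(99)
    pairs <- c(lapply(1:60, function(i)
                   c(randomTestSeq(sample(3:6, 1)),
                     randomTestSeq(sample(3:6, 1)))),
               lapply(1:40, function(i) c(sample(short, 1),
                                          sample(short, 1))))
    for (conv in c("open_plus_size", "open_plus_size_minus_one")) {
        for (p in pairs) {
            expect_equal(
                alignPair(p[1], p[2], "local", submat = sub, gapOpen = 3,
                          gapExtend = 1, gapCost = conv)@score,
                bruteLocalScore(p[1], p[2], sub, 3, 1, conv),
                info = paste("local", conv, p[1], p[2]))
            expect_equal(
                alignPair(p[1], p[2], "global", submat = sub, gapOpen = 3,
                          gapExtend = 1, gapCost = conv)@score,
                bruteGlobalScore(p[1], p[2], sub, 3, 1, conv),
                info = paste("global", conv, p[1], p[2]))
        }
    }
})

test_that("alignment scores match an independent implementation", {
    # Biostrings::pairwiseAlignment as external oracle on real peptides
    set.seed(11)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:25) {
        a <- paste(sample(aas, sample(4:15, 1), TRUE), collapse = "")
        b <- paste(sample(aas, sample(4:15, 1), TRUE), collapse = "")
        ref_l <- suppressWarnings(Biostrings::pairwiseAlignment(
            a, b, type = "local", substitutionMatrix = "BLOSUM62",
            gapOpening = 10, gapExtension = 0.5))
        expect_equal(alignLocal(a, b)@score,
                     max(Biostrings::score(ref_l), 0))
        ref_g <- suppressWarnings(Biostrings::pairwiseAlignment(
            a, b, type = "overlap", substitutionMatrix = "BLOSUM62",
            gapOpening = 10, gapExtension = 0.5))
        expect_equal(alignGlobal(a, b)@score,
                     max(Biostrings::score(ref_g), 0))
    }
})

test_that("reported statistics are consistent with the aligned strings", {
    set.seed(23)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:15) for (mode in c("local", "global")) {
        a <- paste(sample(aas, sample(5:20, 1), TRUE), collapse = "")
        b <- paste(sample(aas, sample(5:20, 1), TRUE), collapse = "")
        r <- alignPair(a, b, mode)
        st <- alignmentStats(r@pattern, r@subject)
        expect_equal(r@identity, st[["identity"]])
        expect_equal(r@similarity, st[["similarity"]])
        expect_equal(r@gaps, as.integer(st[["gaps"]]))
        expect_lte(r@identity, r@similarity)
        expect_lte(r@similarity, 100)
        # de-gapped strings recover the aligned spans / full sequences
        dg <- gsub("-", "", r@pattern, fixed = TRUE)
        if (mode == "global") expect_equal(dg, a)
        else if (nchar(dg))
            expect_equal(dg, substr(a, r@patternRange[1], r@patternRange[2]))
    }
})

test_that("local alignment is nonnegative and monotone under extension", {
    set.seed(31)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:15) {
        a <- paste(sample(aas, 10, TRUE), collapse = "")
        b <- paste(sample(aas, 10, TRUE), collapse = "")
        s0 <- alignLocal(a, b)@score
        expect_gte(s0, 0)
        ext <- paste(sample(aas, 4, TRUE), collapse = "")
        expect_gte(alignLocal(paste0(a, ext), b)@score, s0)
        expect_gte(alignLocal(a, paste0(ext, b))@score, s0)
    }
})

test_that("invalid residues and degenerate inputs are rejected", {
    expect_error(alignLocal("ACDB1", "ACD"), "invalid residue")
    expect_error(alignLocal("", "ACD"), "non-empty")
    # a no-positive-pair local comparison yields the empty alignment
    sub <- testSubmat()
    sub[] <- -1
    r <- alignPair("A", "C", "local", submat = sub)
    expect_equal(r@score, 0)
    expect_equal(nchar(r@pattern), 0L)
})

test_that("epitope extraction is 1-based inclusive with bounds checks", {
    seqs <- referenceSequences()
    asyn <- as.character(seqs[["SYUA_HUMAN"]])
    expect_equal(nchar(asyn), 140L)
    lb <- extractEpitope(asyn, 115, 122)
    expect_equal(unname(nchar(lb)), 8L)
    expect_equal(unname(nchar(extractEpitope(asyn, 61, 95))), 35L)
    expect_equal(unname(nchar(extractEpitope(asyn, 118, 123))), 6L)
    expect_equal(unname(extractEpitope(asyn, 1, 140)), asyn)
    expect_error(extractEpitope(asyn, 120, 141), "out of bounds")
})

test_that("the cross-reactivity table reports self-identity and spans", {
    asyn <- as.character(referenceSequences()[["SYUA_HUMAN"]])
    tab <- epitopeCrossreactivityTable(
        asyn, antibodyEpitopes()["LB509"],
        c(self = asyn))
    loc <- tab$epitope_table[tab$epitope_table$mode == "local", ]
    expect_true(all(loc$identity == 100))
    # global identity is diluted by the free end-gap columns around the
    # epitope (denominator = full alignment length)
    glo <- tab$epitope_table[tab$epitope_table$mode == "global", ]
    expect_equal(glo$identity, 100 * 8 / nchar(asyn))
    expect_equal(tab$antigen_table$identity, 100)
    expect_equal(tab$antigen_table$identity_LB509, 100)

    empty <- epitopeCrossreactivityTable(asyn, antibodyEpitopes()["LB509"],
                                         character(0))
    expect_equal(nrow(empty$epitope_table), 0L)
})

test_that("the tubulin-similar region of the antigen covers the LB509 epitope", {
    seqs <- referenceSequences()
    asyn <- as.character(seqs[["SYUA_HUMAN"]])
    r <- alignLocal(asyn, as.character(seqs[["TBB3_HUMAN"]]))
    expect_lte(r@patternRange[1], 115)
    expect_gte(r@patternRange[2], 122)
})
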