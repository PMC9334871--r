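# Test fixtures are built in code: a minimal FCS 3.0 writer (the package
# itself only reads FCS), brute-force alignment scoring oracles, and an
# exhaustive-scan Li threshold oracle.

# --- minimal FCS 3.0 writer (list mode, $DATATYPE F, little endian) ----

writeMinimalFCS <- function(path, m, names = colnames(m), n_tot = nrow(m)) {
    k <- ncol(m)
    delim <- "/"
    kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
            "$PAR", as.character(k), "$TOT", as.character(n_tot))
    for (i in seq_len(k))
        kw <- c(kw, paste0("$P", i, "N"), names[i],
                paste0("$P", i, "B"), "32",
                paste0("$P", i, "R"), "262144")
    text <- paste0(delim, paste(kw, collapse = delim), delim)
    text_beg <- 58L
    text_end <- text_beg + nchar(text) - 1L
    data_beg <- text_end + 1L
    data_end <- data_beg + 4L * k * n_tot - 1L
    pad8 <- function(x) formatC(x, width = 8L, flag = " ")
    header <- paste0("FCS3.0    ", pad8(text_beg), pad8(text_end),
                     pad8(data_beg), pad8(data_end), pad8(0), pad8(0))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(header), con)
    writeBin(charToRaw(text), con)
    if (n_tot > 0)
        writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    invisible(path)
}

# --- brute-force alignment oracles -------------------------------------

# score one explicit alignment (equal-length padded strings): gap runs in
# either sequence cost open + len*ext ("open_plus_size") or
# open + (len-1)*ext; with free_end = TRUE, runs touching either end of
# the alignment are free
scoreAlignment <- function(pa, sa, submat, open, ext,
                           gapCost = "open_plus_size", free_end = FALSE) {
    A <- strsplit(pa, "")[[1]]
    B <- strsplit(sa, "")[[1]]
    n <- length(A)
    score <- 0
    runCost <- function(len) open + (len - (gapCost != "open_plus_size")) * ext
    for (seqsel in 1:2) {
        gaps <- (if (seqsel == 1) A else B) == "-"
        r <- rle(gaps)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (q in which(r$values)) {
            if (free_end && (starts[q] == 1 || ends[q] == n)) next
            score <- score - runCost(r$lengths[q])
        }
    }
    aligned <- A != "-" & B != "-"
    score + sum(submat[cbind(A[aligned], B[aligned])])
}

# all alignments (padded string pairs) of a vs b, no free ends
enumerateAlignments <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    rec <- function(i, j) {
        if (i == 0 && j == 0) return(list(c("", "")))
        out <- list()
        if (i > 0 && j > 0)
            out <- c(out, lapply(rec(i - 1, j - 1), function(p)
                c(paste0(p[1], ca[i]), paste0(p[2], cb[j]))))
        if (i > 0)
            out <- c(out, lapply(rec(i - 1, j), function(p)
                c(paste0(p[1], ca[i]), paste0(p[2], "-"))))
        if (j > 0)
            out <- c(out, lapply(rec(i, j - 1), function(p)
                c(paste0(p[1], "-"), paste0(p[2], cb[j]))))
        out
    }
    rec(length(ca), length(cb))
}

# optimal ends-free global score by enumeration (never negative: the
# sequences may slide past each other entirely)
bruteGlobalScore <- function(a, b, submat, open = 10, ext = 0.5,
                             gapCost = "open_plus_size") {
    al <- enumerateAlignments(a, b)
    max(0, vapply(al, function(p)
        scoreAlignment(p[1], p[2], submat, open, ext, gapCost,
                       free_end = TRUE), numeric(1)))
}

# optimal local score: best fully-charged alignment over all substring
# pairs, floored at 0
bruteLocalScore <- function(a, b, submat, open = 10, ext = 0.5,
                            gapCost = "open_plus_size") {
    best <- 0
    na <- nchar(a); nb <- nchar(b)
    for (i0 in 1:na) for (i1 in i0:na) for (j0 in 1:nb) for (j1 in j0:nb) {
        sa <- substr(a, i0, i1); sb <- substr(b, j0, j1)
        al <- enumerateAlignments(sa, sb)
        sc <- max(vapply(al, function(p)
            scoreAlignment(p[1], p[2], submat, open, ext, gapCost,
                           free_end = FALSE), numeric(1)))
        if (sc > best) best <- sc
    }
    best
}

# small symmetric test matrix over a 4-letter alphabet
testSubmat <- function() {
    m <- matrix(-2, 4, 4, dimnames = list(c("A", "C", "D", "E"),
                                          c("A", "C", "D", "E")))
    diag(m) <- c(4, 5, 3, 4)
    m["A", "C"] <- m["C", "A"] <- 1
    m["D", "E"] <- m["E", "D"] <- 2
    m
}

randomTestSeq <- function(len, alphabet = c("A", "C", "D", "E"))
    paste(sample(alphabet, len, replace = TRUE), collapse = "")

# --- Li threshold oracle ------------------------------------------------

# exhaustive scan over all candidate thresholds of an 8-bit image,
# minimizing the cross-entropy criterion directly
bruteLiThreshold <- function(x) {
    x <- as.numeric(x)
    cand <- seq(min(x), max(x) - 1)
    ce <- vapply(cand, function(t)
        flowAbVal:::liCrossEntropy(x, t), numeric(1))
    cand[which.min(ce)]
}

# two thresholds are equivalent when they induce the same background /
# foreground split; compare them by the largest intensity classified as
# background (thresholds inside the same histogram gap are identical)
partitionBoundary <- function(x, t) max(as.numeric(x)[as.numeric(x) <= t])

# --- shared synthetic defaults -----------------------------------------

smallStainPair <- function(ab_mean = 1100, iso_mean = 100, cv = 0.5,
                           n = 20000L, seed = 1L) {
    generateStainPair(
        syntheticSampleSpec(ab_mean, cv, n),
        syntheticSampleSpec(iso_mean, cv, n, condition = "isotype"),
        seed)
}
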