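# Pairwise affine-gap protein alignment (Smith-Waterman local and
# Needleman-Wunsch global with free end gaps), used to screen antibody
# epitopes against candidate cross-reactants such as tubulin chains.
#
# This is an original dynamic-programming (Gotoh three-state)
# implementation; reference-tool semantics are followed: BLOSUM62 with
# gap open 10 / extend 0.5 by default, identity computed over the full
# alignment length including gap columns, and a deterministic traceback
# with tie order diagonal > up > left.

AA_GAP <- "-"

alignmentParams <- function(submat = "BLOSUM62", gapOpen = 10,
                            gapExtend = 0.5,
                            gapCost = c("open_plus_size",
                                        "open_plus_size_minus_one")) {
    gapCost <- match.arg(gapCost)
    if (is.character(submat)) submat <- getSubstitutionMatrix(submat)
    if (!isSymmetric(unname(submat)))
        abort("substitution matrix must be symmetric", "input_error")
    if (!(gapOpen >= gapExtend && gapExtend >= 0))
        abort("need gapOpen >= gapExtend >= 0", "input_error")
    list(submat = submat, gapOpen = gapOpen, gapExtend = gapExtend,
         gapCost = gapCost,
         # penalty charged on the first residue of a gap; a gap of length
         # g then costs gapOpen + g*ext (open_plus_size, reference-tool
         # convention) or gapOpen + (g-1)*ext
         firstGap = gapOpen + (gapCost == "open_plus_size") * gapExtend)
}

getSubstitutionMatrix <- function(name) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
}

encodeSeq <- function(s, submat) {
    if (is(s, "AAString") || is(s, "AAStringSet")) s <- as.character(s)
    chars <- strsplit(toupper(s), "")[[1L]]
    if (!length(chars)) abort("sequences must be non-empty", "input_error")
    idx <- match(chars, rownames(submat))
    if (anyNA(idx))
        abort(paste0("invalid residue character(s): ",
                     paste(unique(chars[is.na(idx)]), collapse = ", ")),
              "input_error")
    structure(idx, chars = chars)
}

#' Pairwise affine-gap protein alignment
#'
#' Optimal local (Smith-Waterman) or global (Needleman-Wunsch, free end
#' gaps) alignment of two amino-acid sequences under an affine gap model.
#' \code{alignLocal} and \code{alignGlobal} are convenience wrappers.
#'
#' @param pattern,subject character strings or Biostrings AA objects over
#'   the 20-letter alphabet (plus B, Z, X, *).
#' @param mode \code{"local"} or \code{"global"}.
#' @param submat substitution matrix or its Biostrings data name
#'   (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend gap penalties (positive; defaults 10 and 0.5).
#' @param gapCost gap cost convention: \code{"open_plus_size"} (a gap of
#'   length g costs gapOpen + g * gapExtend, the reference-tool default)
#'   or \code{"open_plus_size_minus_one"}
#'   (gapOpen + (g - 1) * gapExtend). Recorded in the result metadata.
#' @param endGap penalize end gaps in global mode (default FALSE: free
#'   end gaps).
#' @return an \linkS4class{AlignmentResult}. Local alignments with no
#'   positive-scoring pair return an empty alignment with score 0.
#' @examples
#' alignLocal("HEAGAWGHEE", "PAWHEAE")
#' @export
alignPair <- function(pattern, subject, mode = c("global", "local"),
                      submat = "BLOSUM62", gapOpen = 10, gapExtend = 0.5,
                      gapCost = "open_plus_size", endGap = FALSE) {
    mode <- match.arg(mode)
    par <- alignmentParams(submat, gapOpen, gapExtend, gapCost)
    a <- encodeSeq(pattern, par$submat)
    b <- encodeSeq(subject, par$submat)
    ach <- attr(a, "chars"); bch <- attr(b, "chars")
    n <- length(a); m <- length(b)
    S <- par$submat
    gf <- par$firstGap; ge <- par$gapExtend
    NEG <- -1e18

    # state matrices (rows 0..n, cols 0..m): M = aligned pair,
    # X = gap in subject (up), Y = gap in pattern (left)
    M <- matrix(NEG, n + 1L, m + 1L)
    X <- matrix(NEG, n + 1L, m + 1L)
    Y <- matrix(NEG, n + 1L, m + 1L)
    # predecessor state per cell: 0 = fresh start, 1 = M, 2 = X, 3 = Y
    Mp <- matrix(0L, n + 1L, m + 1L)
    Xp <- matrix(0L, n + 1L, m + 1L)
    Yp <- matrix(0L, n + 1L, m + 1L)

    local <- mode == "local"
    free_end <- !local && !endGap
    if (!local && endGap) {
        # end gaps charged: classic global initialization
        M[1L, 1L] <- 0
        for (i in seq_len(n)) { X[i + 1L, 1L] <- -gf - (i - 1L) * ge
                                Xp[i + 1L, 1L] <- 2L }
        for (j in seq_len(m)) { Y[1L, j + 1L] <- -gf - (j - 1L) * ge
                                Yp[1L, j + 1L] <- 3L }
        Xp[2L, 1L] <- 0L; Yp[1L, 2L] <- 0L
    }

    for (i in seq_len(n)) {
        si <- S[a[i], ]
        for (j in seq_len(m)) {
            # diagonal predecessor (i-1, j-1)
            dM <- M[i, j]; dX <- X[i, j]; dY <- Y[i, j]
            best <- dM; ptr <- 1L
            if (dX > best) { best <- dX; ptr <- 2L }
            if (dY > best) { best <- dY; ptr <- 3L }
            start_ok <- local || (free_end && (i == 1L || j == 1L))
            if (!local && !free_end && i == 1L && j == 1L) {
                # handled by M[1,1] = 0 initialization
                if (0 >= best) { best <- 0; ptr <- 0L }
            }
            if (start_ok && 0 >= best) { best <- 0; ptr <- 0L }
            M[i + 1L, j + 1L] <- S[a[i], b[j]] + best
            Mp[i + 1L, j + 1L] <- ptr

            # X: consume pattern residue i against a gap (move up)
            vM <- M[i, j + 1L] - gf
            vX <- X[i, j + 1L] - ge
            vY <- Y[i, j + 1L] - gf
            bx <- vM; px <- 1L
            if (vX > bx) { bx <- vX; px <- 2L }
            if (vY > bx) { bx <- vY; px <- 3L }
            X[i + 1L, j + 1L] <- bx
            Xp[i + 1L, j + 1L] <- px

            # Y: consume subject residue j against a gap (move left)
            hM <- M[i + 1L, j] - gf
            hX <- X[i + 1L, j] - gf
            hY <- Y[i + 1L, j] - ge
            by <- hM; py <- 1L
            if (hX > by) { by <- hX; py <- 2L }
            if (hY > by) { by <- hY; py <- 3L }
            Y[i + 1L, j + 1L] <- by
            Yp[i + 1L, j + 1L] <- py
        }
    }

    params_rec <- list(submat = if (is.character(submat)) submat else
                           "custom",
                       gapOpen = gapOpen, gapExtend = gapExtend,
                       gapCost = gapCost, mode = mode, endGap = endGap)

    if (local) {
        # optimal local alignments end in an aligned pair
        score <- max(M[-1L, -1L], 0)
        if (score <= 0)
            return(newAlignmentResult("", "", 0, integer(0), integer(0),
                                      par$submat, params_rec))
        idx <- which(M == score, arr.ind = TRUE)
        # deterministic end cell: smallest pattern, then subject position
        idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
        ei <- idx[1L, 1L] - 1L; ej <- idx[1L, 2L] - 1L
        tb <- traceback3(Mp, Xp, Yp, ei, ej, 1L, ach, bch)
        return(newAlignmentResult(tb$pa, tb$sa, score,
                                  c(tb$i0 + 1L, ei), c(tb$j0 + 1L, ej),
                                  par$submat, params_rec))
    }

    # global: end anywhere on the bottom/right boundary for free end gaps,
    # at (n, m) otherwise
    if (free_end) {
        cand <- rbind(
            cbind(n + 1L, seq_len(m + 1L)[-1L]),
            cbind(seq_len(n + 1L)[-1L], m + 1L))
        vals <- pmax(M[cand], X[cand], Y[cand])
        best_k <- which.max(vals)
        ei <- cand[best_k, 1L] - 1L; ej <- cand[best_k, 2L] - 1L
        score <- vals[best_k]
        if (score < 0) {
            # no positive-scoring overlap: the sequences slide past each
            # other, leaving only free end gaps (score 0)
            pa <- paste0(paste(ach, collapse = ""), strrep(AA_GAP, m))
            sa <- paste0(strrep(AA_GAP, n), paste(bch, collapse = ""))
            return(newAlignmentResult(pa, sa, 0, c(1L, n), c(1L, m),
                                      par$submat, params_rec))
        }
    } else {
        ei <- n; ej <- m
        score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                     Y[n + 1L, m + 1L])
    }
    st <- c(M[ei + 1L, ej + 1L], X[ei + 1L, ej + 1L], Y[ei + 1L, ej + 1L])
    state <- which(st == score)[1L]
    tb <- traceback3(Mp, Xp, Yp, ei, ej, state, ach, bch)
    # free end gaps: pad the alignment with the unaligned sequence ends
    pa <- tb$pa; sa <- tb$sa
    if (tb$i0 > 0L) {
        pa <- paste0(paste(ach[seq_len(tb$i0)], collapse = ""), pa)
        sa <- paste0(strrep(AA_GAP, tb$i0), sa)
    }
    if (tb$j0 > 0L) {
        pa <- paste0(strrep(AA_GAP, tb$j0), pa)
        sa <- paste0(paste(bch[seq_len(tb$j0)], collapse = ""), sa)
    }
    if (ei < n) {
        pa <- paste0(pa, paste(ach[(ei + 1L):n], collapse = ""))
        sa <- paste0(sa, strrep(AA_GAP, n - ei))
    }
    if (ej < m) {
        pa <- paste0(pa, strrep(AA_GAP, m - ej))
        sa <- paste0(sa, paste(bch[(ej + 1L):m], collapse = ""))
    }
    newAlignmentResult(pa, sa, score, c(1L, n), c(1L, m),
                       par$submat, params_rec)
}

# follow predecessor pointers from (ei, ej, state) back to a fresh start;
# returns aligned strings for the traced core and its start offsets
traceback3 <- function(Mp, Xp, Yp, ei, ej, state, ach, bch) {
    pa <- character(0); sa <- character(0)
    i <- ei; j <- ej
    repeat {
        if (state == 1L) {
            pa <- c(ach[i], pa); sa <- c(bch[j], sa)
            prev <- Mp[i + 1L, j + 1L]
            i <- i - 1L; j <- j - 1L
        } else if (state == 2L) {
            pa <- c(ach[i], pa); sa <- c(AA_GAP, sa)
            prev <- Xp[i + 1L, j + 1L]
            i <- i - 1L
        } else {
            pa <- c(AA_GAP, pa); sa <- c(bch[j], sa)
            prev <- Yp[i + 1L, j + 1L]
            j <- j - 1L
        }
        if (prev == 0L) break
        state <- prev
    }
    list(pa = paste(pa, collapse = ""), sa = paste(sa, collapse = ""),
         i0 = i, j0 = j)
}

newAlignmentResult <- function(pa, sa, score, prange, srange, submat,
                               params) {
    stats <- alignmentStats(pa, sa, submat)
    new("AlignmentResult", pattern = pa, subject = sa, score = score,
        identity = stats[["identity"]], similarity = stats[["similarity"]],
        gaps = as.integer(stats[["gaps"]]),
        patternRange = as.integer(prange), subjectRange = as.integer(srange),
        params = params)
}

#' Identity, similarity and gap counts of an aligned pair
#'
#' Recomputed directly from the aligned strings: identity = identical
#' columns / alignment length x 100; similarity = columns whose
#' substitution score is positive / alignment length x 100; gaps = gap
#' columns. The denominator is the full alignment length including gap
#' columns (reference-tool convention).
#'
#' @param pa,sa aligned strings of equal length ('-' gaps).
#' @param submat substitution matrix or name.
#' @return named vector: \code{length}, \code{identity},
#'   \code{similarity}, \code{gaps}.
#' @export
alignmentStats <- function(pa, sa, submat = "BLOSUM62") {
    if (is.character(submat) && length(submat) == 1L && !is.matrix(submat))
        submat <- getSubstitutionMatrix(submat)
    A <- strsplit(pa, "")[[1L]]
    B <- strsplit(sa, "")[[1L]]
    stopifnot(length(A) == length(B))
    len <- length(A)
    if (!len)
        return(c(length = 0, identity = 0, similarity = 0, gaps = 0))
    gap <- A == AA_GAP | B == AA_GAP
    ident <- sum(!gap & A == B)
    pos <- sum(submat[cbind(A[!gap], B[!gap])] > 0)
    c(length = len, identity = 100 * ident / len,
      similarity = 100 * pos / len, gaps = sum(gap))
}

#' @rdname alignPair
#' @param ... passed on to \code{alignPair}.
#' @export
alignLocal <- function(pattern, subject, ...)
    alignPair(pattern, subject, mode = "local", ...)

#' @rdname alignPair
#' @export
alignGlobal <- function(pattern, subject, ...)
    alignPair(pattern, subject, mode = "global", ...)

#' Extract an epitope subsequence
#'
#' @param seq antigen sequence (character or Biostrings AA object).
#' @param start,end 1-based inclusive residue range on the antigen.
#' @param name epitope/antibody label.
#' @return named character vector of length 1: the epitope peptide.
#' @examples
#' extractEpitope("MDVFMKGLSK", 2, 5)  # "DVFM"
#' @export
extractEpitope <- function(seq, start, end, name = NULL) {
    s <- if (is(seq, "AAString") || is(seq, "AAStringSet"))
        as.character(seq)[[1L]] else as.character(seq)
    L <- nchar(s)
    if (!(start >= 1L && start <= end && end <= L))
        abort(sprintf("epitope range [%d, %d] out of bounds for length %d",
                      start, end, L), "input_error")
    setNames(substr(s, start, end),
             name %||% sprintf("epitope_%d_%d", start, end))
}

#' Identity of an epitope region within a larger alignment
#'
#' Restricts a pattern-vs-target alignment to the columns covering a
#' 1-based residue range on the pattern (e.g. an antibody epitope within
#' a full-antigen alignment) and reports the identity there. With
#' \code{denominator = "epitope"} the percentage is identical residues
#' over the epitope length (the convention behind per-epitope identity
#' figures quoted from full-chain alignments); with \code{"columns"} it
#' is over the restricted alignment columns including gaps.
#'
#' @param result an \linkS4class{AlignmentResult} whose pattern is the
#'   antigen.
#' @param start,end 1-based inclusive epitope range on the pattern.
#' @param denominator \code{"epitope"} or \code{"columns"}.
#' @return named vector: \code{columns}, \code{identical},
#'   \code{identity} (percent). \code{identical} is 0 when the epitope
#'   lies outside the aligned span.
#' @export
epitopeIdentity <- function(result, start, end,
                            denominator = c("epitope", "columns")) {
    denominator <- match.arg(denominator)
    stopifnot(is(result, "AlignmentResult"), start >= 1L, end >= start)
    A <- strsplit(result@pattern, "")[[1L]]
    B <- strsplit(result@subject, "")[[1L]]
    pos <- cumsum(A != AA_GAP) + result@patternRange[[1L]] - 1L
    keep <- which(A != AA_GAP & pos >= start & pos <= end)
    if (!length(keep))
        return(c(columns = 0, identical = 0,
                 identity = if (denominator == "epitope") 0 else NA_real_))
    cols <- seq(min(keep), max(keep))
    ident <- sum(A[cols] != AA_GAP & A[cols] == B[cols])
    denom <- if (denominator == "epitope") end - start + 1L else length(cols)
    c(columns = length(cols), identical = ident,
      identity = 100 * ident / denom)
}

#' Epitope cross-reactivity screening table
#'
#' For every (epitope, target) pair: the local and global alignment
#' identity, similarity, gaps and score. For the full antigen against
#' each target the best local alignment's antigen span is also reported,
#' to test whether the most tubulin-similar region of the antigen
#' overlaps an epitope.
#'
#' @param antigen full antigen sequence.
#' @param epitopes named list of \code{c(start, end)} ranges on the
#'   antigen.
#' @param targets named character vector (or AAStringSet) of target
#'   sequences.
#' @param ... alignment parameters passed to \code{\link{alignPair}}.
#' @return list with \code{epitope_table} (one row per epitope x target
#'   x mode) and \code{antigen_table} (full antigen vs target, local:
#'   columns include the aligned antigen span).
#' @export
epitopeCrossreactivityTable <- function(antigen, epitopes, targets, ...) {
    if (is(targets, "AAStringSet"))
        targets <- setNames(as.character(targets), names(targets))
    rows <- list()
    for (ep in names(epitopes)) {
        rng <- epitopes[[ep]]
        pep <- extractEpitope(antigen, rng[[1L]], rng[[2L]], ep)
        for (tg in names(targets)) for (mode in c("local", "global")) {
            r <- alignPair(pep, targets[[tg]], mode = mode, ...)
            rows[[length(rows) + 1L]] <- data.frame(
                epitope = ep, target = tg, mode = mode, score = r@score,
                identity = r@identity, similarity = r@similarity,
                gaps = r@gaps, stringsAsFactors = FALSE)
        }
    }
    arows <- lapply(names(targets), function(tg) {
        r <- alignLocal(antigen, targets[[tg]], ...)
        row <- data.frame(target = tg, score = r@score,
                          identity = r@identity,
                          similarity = r@similarity, gaps = r@gaps,
                          antigen_start = r@patternRange[[1L]],
                          antigen_end = r@patternRange[[2L]],
                          stringsAsFactors = FALSE)
        for (ep in names(epitopes)) {
            rng <- epitopes[[ep]]
            row[[paste0("identity_", ep)]] <-
                epitopeIdentity(r, rng[[1L]], rng[[2L]])[["identity"]]
        }
        row
    })
    list(epitope_table = if (length(rows)) do.call(rbind, rows) else
             data.frame(),
         antigen_table = if (length(arows)) do.call(rbind, arows) else
             data.frame())
}

# EMBOSS-like human-readable alignment block
formatAlignment <- function(r, width = 50L) {
    stopifnot(is(r, "AlignmentResult"))
    stats <- alignmentStats(r@pattern, r@subject,
        if (identical(r@params$submat, "custom")) "BLOSUM62" else
            r@params$submat)
    hdr <- sprintf(paste0(
        "# Mode: %s  Matrix: %s  Gap: %g/%g (%s)\n",
        "# Length: %d  Identity: %.1f%%  Similarity: %.1f%%  Gaps: %d\n",
        "# Score: %.1f\n"),
        r@params$mode, r@params$submat, r@params$gapOpen,
        r@params$gapExtend, r@params$gapCost, stats[["length"]],
        r@identity, r@similarity, r@gaps, r@score)
    A <- strsplit(r@pattern, "")[[1L]]
    B <- strsplit(r@subject, "")[[1L]]
    if (!length(A)) return(paste0(hdr, "# (empty alignment)\n"))
    submat <- getSubstitutionMatrix(
        if (identical(r@params$submat, "custom")) "BLOSUM62" else
            r@params$submat)
    mid <- vapply(seq_along(A), function(k) {
        if (A[k] == AA_GAP || B[k] == AA_GAP) " "
        else if (A[k] == B[k]) "|"
        else if (submat[A[k], B[k]] > 0) ":"
        else "."
    }, character(1L))
    out <- hdr
    for (s in seq(1L, length(A), by = width)) {
        e <- min(s + width - 1L, length(A))
        out <- paste0(out,
            paste(A[s:e], collapse = ""), "\n",
            paste(mid[s:e], collapse = ""), "\n",
            paste(B[s:e], collapse = ""), "\n\n")
    }
    out
}
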