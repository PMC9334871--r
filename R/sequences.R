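# Bundled reference sequences and epitope definitions for the
# alpha-synuclein / tubulin cross-reactivity screen.

#' Bundled antigen and tubulin reference sequences
#'
#' The five protein sequences used by the epitope similarity screen:
#' human alpha-synuclein (SYUA_HUMAN, the antigen), pig tubulin
#' alpha-1A and alpha-1B chains, pig tubulin beta chain, and human
#' neuron-specific beta-3 tubulin (TUBB3). Shipped as a FASTA fixture
#' pinned to one release; the copies bundled here were transcribed
#' without database access and verified against the published alignment
#' statistics of the aligned regions, so residues outside those regions
#' carry transcription risk (see the package vignette).
#'
#' @return a \code{Biostrings::AAStringSet} with names
#'   \code{SYUA_HUMAN}, \code{TBA1A_PIG}, \code{TBA1B_PIG},
#'   \code{TBB_PIG}, \code{TBB3_HUMAN}.
#' @export
referenceSequences <- function() {
    path <- system.file("extdata", "antigen_tubulin_sequences.fasta",
                        package = "flowAbVal", mustWork = TRUE)
    seqs <- Biostrings::readAAStringSet(path)
    names(seqs) <- sub(" .*$", "", names(seqs))
    seqs
}

#' Epitope ranges of the validated antibody clones
#'
#' 1-based inclusive residue ranges on alpha-synuclein: LB509 binds
#' residues 115-122, 2A7 binds 61-95 (the NAC region), MJFR1 binds
#' 118-123 (C-terminus).
#'
#' @return named list of \code{c(start, end)} integer vectors.
#' @export
antibodyEpitopes <- function() {
    list(`2A7` = c(61L, 95L),
         LB509 = c(115L, 122L),
         MJFR1 = c(118L, 123L))
}
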