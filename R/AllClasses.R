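CHANNEL_ROLES <- c("FSC-A", "FSC-H", "FSC-Width", "SSC-A",
                   "fluorescence", "viability")

# condition labels form a closed vocabulary; blocked conditions name the
# blocking protein after the colon
CONDITION_PATTERN <- "^(stained|isotype|no-stain|blocked:.+)$"

validCondition <- function(x) {
    is.null(x) || (is.character(x) && length(x) == 1L &&
                   grepl(CONDITION_PATTERN, x))
}

#' EventTable: per-event channel intensities plus sample metadata
#'
#' The unit of all cytometry computation: an n x k matrix of nonnegative
#' intensities (arbitrary units) with per-channel role annotations and
#' sample-level metadata. Negative values are admitted only after spillover
#' compensation (flagged in \code{meta$compensated}); raw tables must be
#' nonnegative.
#'
#' @slot exprs numeric matrix, events in rows, channels in columns; column
#'   names equal the channel names.
#' @slot channels data.frame with columns \code{name} (unique short label),
#'   \code{role} (one of FSC-A, FSC-H, FSC-Width, SSC-A, fluorescence,
#'   viability) and \code{detector}.
#' @slot meta named list: \code{sample_id}, \code{antibody}, \code{amount}
#'   (microgram per 50 microlitre staining), \code{condition} (one of
#'   stained, isotype, no-stain, blocked:<protein>), \code{cell_type},
#'   \code{compensated}, and a \code{qc} sub-list.
#' @aliases EventTable
#' @exportClass EventTable
setClass("EventTable",
    representation(exprs = "matrix", channels = "data.frame", meta = "list"))

setValidity("EventTable", function(object) {
    e <- object@exprs; ch <- object@channels; meta <- object@meta
    if (!is.numeric(e)) return("event matrix must be numeric")
    if (nrow(e) < 1L) return("at least one event required")
    if (ncol(e) < 1L) return("at least one channel required")
    if (!all(c("name", "role") %in% names(ch)))
        return("channels must have 'name' and 'role' columns")
    if (nrow(ch) != ncol(e))
        return("channel definitions must match event matrix columns")
    if (anyDuplicated(ch$name)) return("channel names must be unique")
    if (!identical(colnames(e), as.character(ch$name)))
        return("event matrix column names must equal channel names")
    if (!all(ch$role %in% CHANNEL_ROLES))
        return(paste0("channel roles must be in {",
                      paste(CHANNEL_ROLES, collapse = ", "), "}"))
    if (!isTRUE(meta$compensated) && any(e < 0, na.rm = TRUE))
        return("raw (uncompensated) intensities must be nonnegative")
    if (!validCondition(meta$condition))
        return("meta$condition must be stained|isotype|no-stain|blocked:<protein>")
    TRUE
})

#' Construct an EventTable
#'
#' @param exprs numeric matrix (or coercible), one row per event.
#' @param channels data.frame of channel definitions (\code{name},
#'   \code{role}, optional \code{detector}), or a character vector of roles
#'   named by channel.
#' @param meta named list of sample metadata (see \linkS4class{EventTable}).
#' @return an \linkS4class{EventTable}.
#' @examples
#' m <- cbind(`FSC-A` = c(100, 120), `FSC-H` = c(98, 119), FL1 = c(5, 7))
#' EventTable(m, c(`FSC-A` = "FSC-A", `FSC-H` = "FSC-H",
#'                 FL1 = "fluorescence"))
#' @export
EventTable <- function(exprs, channels, meta = list()) {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    if (is.character(channels))
        channels <- data.frame(name = names(channels),
                               role = unname(channels),
                               detector = names(channels),
                               stringsAsFactors = FALSE)
    if (is.null(channels$detector)) channels$detector <- channels$name
    colnames(exprs) <- channels$name
    if (is.null(meta$compensated)) meta$compensated <- FALSE
    if (is.null(meta$qc)) meta$qc <- list()
    new("EventTable", exprs = exprs, channels = channels, meta = meta)
}

#' @rdname eventMatrix
setMethod("eventMatrix", "EventTable", function(x) x@exprs)

#' @rdname channelDefs
setMethod("channelDefs", "EventTable", function(x) x@channels)

#' @rdname sampleMeta
setMethod("sampleMeta", "EventTable", function(x) x@meta)

#' @rdname nEvents
setMethod("nEvents", "EventTable", function(x) nrow(x@exprs))

setMethod("show", "EventTable", function(object) {
    m <- object@meta
    cat("EventTable:", nrow(object@exprs), "events x",
        ncol(object@exprs), "channels\n")
    cat("  channels:", paste0(object@channels$name, " [",
                              object@channels$role, "]", collapse = ", "),
        "\n")
    lab <- c(m$sample_id, m$antibody, m$condition, m$cell_type)
    if (length(lab)) cat("  sample:", paste(lab, collapse = " / "), "\n")
    if (isTRUE(m$compensated)) cat("  compensated\n")
    invisible(NULL)
})

# Channel name lookup by role; errors if absent and required.
channelByRole <- function(x, role, required = TRUE) {
    ch <- x@channels
    hit <- ch$name[ch$role == role]
    if (!length(hit) && required)
        abort(paste0("no channel with role '", role, "'"), "mapping_error")
    if (!length(hit)) return(NULL)
    hit[[1L]]
}

#' SpilloverMatrix: fluorescence spillover between detectors
#'
#' Square matrix over the fluorescence/viability channels with unit
#' diagonal and off-diagonal entries in [0, 1); must be invertible.
#' Entry (i, j) is the fraction of dye i's signal detected on channel j.
#'
#' @slot values numeric k x k matrix.
#' @slot channels character vector giving the channel order.
#' @aliases SpilloverMatrix
#' @exportClass SpilloverMatrix
setClass("SpilloverMatrix",
    representation(values = "matrix", channels = "character"))

setValidity("SpilloverMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("spillover matrix must be square")
    if (length(object@channels) != nrow(v))
        return("channel order must match matrix dimension")
    if (!isTRUE(all.equal(unname(diag(v)), rep(1, nrow(v)))))
        return("spillover matrix must have unit diagonal")
    off <- v[row(v) != col(v)]
    if (length(off) && (any(off < 0) || any(off >= 1)))
        return("off-diagonal spillover entries must lie in [0, 1)")
    if (!is.finite(kappa(v, exact = FALSE)) || kappa(v) > 1 / .Machine$double.eps)
        return("spillover matrix must be invertible")
    TRUE
})

#' Construct a SpilloverMatrix
#' @param values square numeric matrix with unit diagonal.
#' @param channels channel names, in matrix order; defaults to the matrix
#'   column names.
#' @return a \linkS4class{SpilloverMatrix}.
#' @export
SpilloverMatrix <- function(values, channels = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(channels))
        abort("spillover channel order is required", "mapping_error")
    dimnames(values) <- list(channels, channels)
    new("SpilloverMatrix", values = values, channels = channels)
}

setMethod("show", "SpilloverMatrix", function(object) {
    cat("SpilloverMatrix over", length(object@channels), "channels:",
        paste(object@channels, collapse = ", "), "\n")
    print(object@values)
    invisible(NULL)
})

#' GateSpec: a single gate region
#'
#' Data-independent gate specification. Supported kinds: \code{rectangle}
#' (closed box on two channels), \code{polygon} (even-odd rule, boundary
#' inclusive), \code{threshold} (keep events strictly below a cut on one
#' channel) and \code{ratio_band} (keep r_lo <= A/H <= r_hi on two
#' channels).
#'
#' @slot name gate label.
#' @slot kind one of rectangle, polygon, threshold, ratio_band.
#' @slot channels one or two channel names.
#' @slot params kind-specific parameter list: rectangle \code{xlim},
#'   \code{ylim}; polygon \code{vertices} (matrix with >= 3 non-collinear
#'   rows); threshold \code{value}; ratio_band \code{r_lo}, \code{r_hi},
#'   optional \code{normalize} (divide ratios by their median first).
#' @aliases GateSpec
#' @exportClass GateSpec
setClass("GateSpec",
    representation(name = "character", kind = "character",
                   channels = "character", params = "list"))

setValidity("GateSpec", function(object) {
    k <- object@kind
    p <- object@params
    if (!k %in% c("rectangle", "polygon", "threshold", "ratio_band"))
        return("kind must be rectangle|polygon|threshold|ratio_band")
    nch <- length(object@channels)
    if (k == "threshold" && nch != 1L) return("threshold gate needs 1 channel")
    if (k != "threshold" && nch != 2L) return(paste(k, "gate needs 2 channels"))
    if (k == "rectangle" && !(length(p$xlim) == 2L && length(p$ylim) == 2L))
        return("rectangle gate needs xlim and ylim of length 2")
    if (k == "polygon") {
        v <- p$vertices
        if (is.null(v) || nrow(v) < 3L)
            return("polygon gate needs >= 3 vertices")
        if (polygonArea(v) == 0)
            return("polygon vertices are collinear (zero area)")
    }
    if (k == "threshold" && length(p$value) != 1L)
        return("threshold gate needs a single 'value'")
    if (k == "ratio_band") {
        if (is.null(p$r_lo) || is.null(p$r_hi) ||
            !(p$r_lo > 0 && p$r_lo <= p$r_hi))
            return("ratio_band needs 0 < r_lo <= r_hi")
    }
    TRUE
})

polygonArea <- function(v) {
    x <- v[, 1L]; y <- v[, 2L]
    j <- c(seq_len(nrow(v))[-1L], 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Construct a GateSpec
#' @param name gate label.
#' @param kind gate kind; see \linkS4class{GateSpec}.
#' @param channels one or two channel names.
#' @param ... kind-specific parameters (\code{xlim}, \code{ylim},
#'   \code{vertices}, \code{value}, \code{r_lo}, \code{r_hi},
#'   \code{normalize}).
#' @return a \linkS4class{GateSpec}.
#' @examples
#' GateSpec("debris", "rectangle", c("FSC-H", "FSC-Width"),
#'          xlim = c(50, Inf), ylim = c(0, 100))
#' @export
GateSpec <- function(name, kind, channels, ...) {
    new("GateSpec", name = name, kind = kind, channels = channels,
        params = list(...))
}

setMethod("show", "GateSpec", function(object) {
    cat("GateSpec '", object@name, "' [", object@kind, "] on ",
        paste(object@channels, collapse = " x "), "\n", sep = "")
    invisible(NULL)
})

#' GateHierarchy: an ordered gating strategy
#'
#' Ordered gate list applied conjunctively: debris/dead exclusion, then
#' live-cell selection, then singlets. Two strategy labels mirror the two
#' branches of the workflow: \code{scatter_only} (debris and dead cells
#' excluded on an FSC-H x FSC-Width plot) and \code{viability_dye}
#' (dead cells excluded by a fixable viability stain).
#'
#' @slot gates list of \linkS4class{GateSpec}.
#' @slot strategy \code{"scatter_only"} or \code{"viability_dye"}.
#' @aliases GateHierarchy
#' @exportClass GateHierarchy
setClass("GateHierarchy",
    representation(gates = "list", strategy = "character"))

setValidity("GateHierarchy", function(object) {
    if (!object@strategy %in% c("scatter_only", "viability_dye"))
        return("strategy must be scatter_only or viability_dye")
    if (!all(vapply(object@gates, is, logical(1L), class2 = "GateSpec")))
        return("gates must all be GateSpec objects")
    TRUE
})

#' Construct a GateHierarchy
#' @param gates list of \linkS4class{GateSpec}, in application order
#'   (debris/dead, live, singlets).
#' @param strategy \code{"scatter_only"} or \code{"viability_dye"}.
#' @return a \linkS4class{GateHierarchy}.
#' @export
GateHierarchy <- function(gates, strategy = "scatter_only") {
    new("GateHierarchy", gates = gates, strategy = strategy)
}

#' GatedPopulation: result of applying a gate hierarchy
#'
#' @slot masks named list of per-level cumulative inclusion masks.
#' @slot counts named integer vector of per-level counts (non-increasing).
#' @slot finalMask logical vector, the conjunction of all levels.
#' @aliases GatedPopulation
#' @exportClass GatedPopulation
setClass("GatedPopulation",
    representation(masks = "list", counts = "integer", finalMask = "logical"))

setValidity("GatedPopulation", function(object) {
    if (length(object@counts) && any(diff(object@counts) > 0L))
        return("per-level counts must be non-increasing")
    TRUE
})

#' @rdname nEvents
setMethod("nEvents", "GatedPopulation", function(x) length(x@finalMask))

setMethod("show", "GatedPopulation", function(object) {
    cat("GatedPopulation:", length(object@finalMask), "events ->",
        sum(object@finalMask), "retained\n")
    for (nm in names(object@counts))
        cat(sprintf("  %-12s %d\n", nm, object@counts[[nm]]))
    invisible(NULL)
})

#' AlignmentResult: affine-gap pairwise alignment of two protein sequences
#'
#' @slot pattern,subject aligned strings of equal length with '-' gaps.
#' @slot score optimal alignment score.
#' @slot identity percent identical columns over the alignment length
#'   (gap columns included in the denominator).
#' @slot similarity percent columns with positive substitution score.
#' @slot gaps number of gap columns.
#' @slot patternRange,subjectRange 1-based inclusive aligned spans on the
#'   original sequences.
#' @slot params parameter record: matrix name, gap penalties, mode, gap
#'   cost convention.
#' @aliases AlignmentResult
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(pattern = "character", subject = "character",
                   score = "numeric", identity = "numeric",
                   similarity = "numeric", gaps = "integer",
                   patternRange = "integer", subjectRange = "integer",
                   params = "list"))

setValidity("AlignmentResult", function(object) {
    if (nchar(object@pattern) != nchar(object@subject))
        return("aligned strings must have equal length")
    if (object@identity > object@similarity + 1e-9 ||
        object@similarity > 100 + 1e-9)
        return("identity <= similarity <= 100 violated")
    TRUE
})

setMethod("show", "AlignmentResult", function(object) {
    cat(formatAlignment(object))
    invisible(NULL)
})

#' TwoChannelImage: paired marker/target intensity images
#'
#' A neuronal-marker channel (thresholded to define the measurement mask)
#' and a target channel (quantified inside the mask), as equal-shape
#' nonnegative matrices.
#'
#' @slot marker,target numeric matrices of identical dimension.
#' @slot bitDepth nominal pixel depth (bits), metadata only.
#' @aliases TwoChannelImage
#' @exportClass TwoChannelImage
setClass("TwoChannelImage",
    representation(marker = "matrix", target = "matrix",
                   bitDepth = "numeric"))

setValidity("TwoChannelImage", function(object) {
    if (!identical(dim(object@marker), dim(object@target)))
        return("marker and target channels must have identical shapes")
    if (any(!is.finite(object@marker)) || any(!is.finite(object@target)))
        return("image intensities must be finite")
    if (any(object@marker < 0) || any(object@target < 0))
        return("image intensities must be nonnegative")
    TRUE
})

#' Construct a TwoChannelImage
#' @param marker,target numeric matrices of identical dimension.
#' @param bitDepth nominal pixel depth in bits (default 8).
#' @return a \linkS4class{TwoChannelImage}.
#' @export
TwoChannelImage <- function(marker, target, bitDepth = 8) {
    new("TwoChannelImage", marker = as.matrix(marker),
        target = as.matrix(target), bitDepth = bitDepth)
}

setMethod("show", "TwoChannelImage", function(object) {
    cat("TwoChannelImage:", nrow(object@marker), "x", ncol(object@marker),
        "pixels,", object@bitDepth, "bit\n")
    invisible(NULL)
})
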