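# Two-branch gating strategy: debris exclusion, dead-cell exclusion
# (scatter-based or viability-dye-based), singlet selection, event-count QC.
#
# Gates are closed regions (boundary events are included) so that gating is
# deterministic and idempotent.

#' Apply a single gate to an event table
#'
#' @param table an \linkS4class{EventTable}.
#' @param gate a \linkS4class{GateSpec}. Semantics by kind:
#'   \describe{
#'     \item{rectangle}{keep events inside the closed box
#'       \code{xlim} x \code{ylim}.}
#'     \item{polygon}{even-odd rule, boundary inclusive.}
#'     \item{threshold}{keep events strictly below \code{value}
#'       (exclusion gates cut the high tail).}
#'     \item{ratio_band}{keep events with
#'       \code{r_lo <= channel1/channel2 <= r_hi}; with
#'       \code{normalize = TRUE} ratios are first divided by their median.
#'       Zero denominators are excluded, not an error.}
#'   }
#' @return logical mask, TRUE for events inside the region.
#' @export
applyGate <- function(table, gate) {
    stopifnot(is(table, "EventTable"), is(gate, "GateSpec"))
    defs <- channelDefs(table)
    missing_ch <- setdiff(gate@channels, defs$name)
    if (length(missing_ch))
        abort(paste0("gate channel(s) not in table: ",
                     paste(missing_ch, collapse = ", ")), "mapping_error")
    m <- eventMatrix(table)
    p <- gate@params
    switch(gate@kind,
        rectangle = {
            x <- m[, gate@channels[[1L]]]; y <- m[, gate@channels[[2L]]]
            x >= min(p$xlim) & x <= max(p$xlim) &
                y >= min(p$ylim) & y <= max(p$ylim)
        },
        polygon = pointInPolygon(m[, gate@channels[[1L]]],
                                 m[, gate@channels[[2L]]], p$vertices),
        threshold = m[, gate@channels[[1L]]] < p$value,
        ratio_band = {
            a <- m[, gate@channels[[1L]]]; h <- m[, gate@channels[[2L]]]
            r <- ifelse(h > 0, a / h, NA_real_)
            if (isTRUE(p$normalize)) r <- r / median(r, na.rm = TRUE)
            !is.na(r) & r >= p$r_lo & r <= p$r_hi
        })
}

# Even-odd point-in-polygon with inclusive boundary.
pointInPolygon <- function(x, y, vertices) {
    vx <- vertices[, 1L]; vy <- vertices[, 2L]
    n <- length(vx)
    inside <- rep(FALSE, length(x))
    on_edge <- rep(FALSE, length(x))
    j <- n
    for (i in seq_len(n)) {
        xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
        # boundary test: point on segment (i, j)
        cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
        within <- x >= pmin(xi, xj) & x <= pmax(xi, xj) &
                  y >= pmin(yi, yj) & y <= pmax(yi, yj)
        on_edge <- on_edge | (abs(cross) < 1e-12 * (1 + abs(cross)) & within)
        # even-odd crossing test
        crosses <- ((yi > y) != (yj > y)) &
                   (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- xor(inside, crosses)
        j <- i
    }
    inside | on_edge
}

#' Exclude dead cells by viability-dye intensity
#'
#' Events whose viability-channel intensity exceeds \code{threshold} are
#' marked dead and excluded (the fixable dye labels dead cells brightly).
#'
#' @param table an \linkS4class{EventTable}.
#' @param threshold dye intensity above which an event is dead.
#' @param channel viability channel name; defaults to the channel with
#'   role \code{"viability"}.
#' @return logical mask, TRUE for live (kept) events.
#' @export
gateViability <- function(table, threshold, channel = NULL) {
    if (is.null(channel)) {
        channel <- channelByRole(table, "viability", required = FALSE)
        if (is.null(channel))
            abort("no viability channel in table (strategy viability_dye)",
                  "configuration_error")
    }
    if (!channel %in% channelDefs(table)$name)
        abort(paste0("viability channel '", channel, "' not in table"),
              "configuration_error")
    eventMatrix(table)[, channel] <= threshold
}

#' Select singlets by pulse area-to-height ratio
#'
#' Doublets carry roughly twice the pulse area of a singlet at a given
#' height, so events are kept iff
#' \code{r_lo <= FSC-A/FSC-H <= r_hi}. With \code{normalize = TRUE}
#' (default) ratios are first divided by their median, centring the
#' singlet mode at 1 so the default band [0.8, 1.25] transfers across
#' instruments. Events with FSC-H = 0 are excluded and counted, not an
#' error.
#'
#' @param table an \linkS4class{EventTable} with FSC-A and FSC-H channels.
#' @param r_lo,r_hi band on the (normalized) area/height ratio.
#' @param normalize divide ratios by their median first (default TRUE).
#' @return logical mask with attribute \code{zero_height} (count of
#'   excluded FSC-H = 0 events).
#' @export
gateSinglets <- function(table, r_lo = 0.8, r_hi = 1.25, normalize = TRUE) {
    a_ch <- channelByRole(table, "FSC-A")
    h_ch <- channelByRole(table, "FSC-H")
    m <- eventMatrix(table)
    h <- m[, h_ch]
    r <- ifelse(h > 0, m[, a_ch] / h, NA_real_)
    if (normalize) r <- r / median(r, na.rm = TRUE)
    mask <- !is.na(r) & r >= r_lo & r <= r_hi
    attr(mask, "zero_height") <- sum(h <= 0)
    mask
}

#' Apply a gate hierarchy
#'
#' Gates are applied in order and combined conjunctively; per-level counts
#' are cumulative, hence non-increasing.
#'
#' @param table an \linkS4class{EventTable}.
#' @param hierarchy a \linkS4class{GateHierarchy}.
#' @return a \linkS4class{GatedPopulation}.
#' @export
applyHierarchy <- function(table, hierarchy) {
    stopifnot(is(table, "EventTable"), is(hierarchy, "GateHierarchy"))
    acc <- rep(TRUE, nEvents(table))
    masks <- list()
    counts <- integer(0)
    for (g in hierarchy@gates) {
        acc <- acc & applyGate(table, g)
        masks[[g@name]] <- acc
        counts[[g@name]] <- sum(acc)
    }
    new("GatedPopulation", masks = masks, counts = counts, finalMask = acc)
}

#' Subset an event table to a gated population
#' @param table an \linkS4class{EventTable}.
#' @param mask logical mask or \linkS4class{GatedPopulation}.
#' @return an \linkS4class{EventTable} with only the retained events.
#' @export
subsetEvents <- function(table, mask) {
    if (is(mask, "GatedPopulation")) mask <- mask@finalMask
    if (!sum(mask))
        abort("gated population is empty", "insufficient_data")
    meta <- sampleMeta(table)
    meta$qc$gated_from <- nEvents(table)
    EventTable(eventMatrix(table)[mask, , drop = FALSE],
               channelDefs(table), meta)
}

#' Event-count quality control
#'
#' A sample passes QC when at least \code{minimum} events were acquired
#' (default 20,000, the standard acquisition floor for these stainings).
#'
#' @param pop a \linkS4class{GatedPopulation} or \linkS4class{EventTable}.
#' @param minimum minimum total acquired events.
#' @return list with \code{pass}, \code{total}, \code{minimum} and the
#'   per-level \code{counts}.
#' @export
qcMinEvents <- function(pop, minimum = 20000L) {
    total <- nEvents(pop)
    counts <- if (is(pop, "GatedPopulation")) pop@counts else integer(0)
    list(pass = total >= minimum, total = total,
         minimum = as.integer(minimum), counts = counts)
}

#' Percentile-based debris-gate placement
#'
#' Optional helper (off by default in hierarchies): builds a rectangle on
#' FSC-H x FSC-Width excluding the lowest \code{q} percent of FSC-H and
#' the extreme upper \code{q} percent of FSC-Width, reproducing the visual
#' debris/dead-cell exclusion on the scatter plot.
#'
#' @param table an \linkS4class{EventTable}.
#' @param q percentile to trim (default 5).
#' @return a \linkS4class{GateSpec} rectangle.
#' @export
autoDebrisGate <- function(table, q = 5) {
    h_ch <- channelByRole(table, "FSC-H")
    w_ch <- channelByRole(table, "FSC-Width")
    m <- eventMatrix(table)
    GateSpec("debris_exclusion", "rectangle", c(h_ch, w_ch),
             xlim = c(quantile(m[, h_ch], q / 100, names = FALSE), Inf),
             ylim = c(0, quantile(m[, w_ch], 1 - q / 100, names = FALSE)))
}

#' Default gating hierarchies for the two strategies
#'
#' \code{scatter_only}: debris and dead cells excluded on an
#' FSC-H x FSC-Width rectangle, then singlet selection.
#' \code{viability_dye}: debris rectangle, dye-based dead-cell threshold,
#' then singlet selection. Geometry is configurable; defaults assume
#' event tables on the scale produced by \code{\link{generateSample}}.
#'
#' @param strategy \code{"scatter_only"} or \code{"viability_dye"}.
#' @param fsc_h_min lower FSC-H bound of the debris gate.
#' @param fsc_w_max upper FSC-Width bound of the debris/dead gate.
#' @param viability_threshold dye cut for the viability branch.
#' @param r_lo,r_hi singlet band on the median-normalized A/H ratio.
#' @return a \linkS4class{GateHierarchy}.
#' @export
defaultHierarchy <- function(strategy = c("scatter_only", "viability_dye"),
                             fsc_h_min = 50, fsc_w_max = 95,
                             viability_threshold = 300,
                             r_lo = 0.8, r_hi = 1.25) {
    strategy <- match.arg(strategy)
    debris <- GateSpec("debris_dead", "rectangle", c("FSC-H", "FSC-Width"),
                       xlim = c(fsc_h_min, Inf), ylim = c(0, fsc_w_max))
    singlets <- GateSpec("singlets", "ratio_band", c("FSC-A", "FSC-H"),
                         r_lo = r_lo, r_hi = r_hi, normalize = TRUE)
    gates <- if (strategy == "scatter_only") {
        list(debris, singlets)
    } else {
        live <- GateSpec("live", "threshold", "VIA",
                         value = viability_threshold)
        debris_only <- GateSpec("debris", "rectangle",
                                c("FSC-H", "FSC-Width"),
                                xlim = c(fsc_h_min, Inf), ylim = c(0, Inf))
        list(debris_only, live, singlets)
    }
    GateHierarchy(gates, strategy)
}
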