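# Decision layer: titration evaluation and optimal-amount selection,
# cross-reactivity panel aggregation, specificity/sensitivity
# classification, and antibody ranking.

#' Build a titration series
#'
#' @param antibody antibody name.
#' @param stats data.frame with one row per tested amount, columns
#'   \code{amount}, \code{mfi_ab}, \code{mfi_iso}, \code{sd_iso} (as
#'   produced by \code{\link{stainStatistics}}), or with a precomputed
#'   \code{si} column.
#' @param reference the manufacturer-recommended amount; must be one of
#'   the tested amounts unless reference MFIs are supplied separately.
#' @return a \code{titration_series} object (list with class attribute).
#' @export
titrationSeries <- function(antibody, stats, reference) {
    stats <- stats[order(stats$amount), , drop = FALSE]
    if (anyDuplicated(stats$amount))
        abort("amounts must be strictly increasing (no duplicates)",
              "spec_error")
    if (!reference %in% stats$amount)
        abort("reference amount is not among the tested amounts",
              "spec_error")
    structure(list(antibody = antibody, stats = stats,
                   reference = reference),
              class = "titration_series")
}

#' Evaluate a titration series
#'
#' For every tested amount: the stain index, and the ratio MFI of the
#' antibody and of the isotype control relative to the recommended
#' amount (fold change of specific signal vs. fold change of unspecific
#' background).
#'
#' @param series a \code{\link{titrationSeries}}.
#' @return data.frame with columns \code{amount}, \code{si},
#'   \code{ratio_mfi_ab}, \code{ratio_mfi_iso}.
#' @export
evaluateTitration <- function(series) {
    stopifnot(inherits(series, "titration_series"))
    s <- series$stats
    if (nrow(s) < 2L)
        abort("a titration needs at least 2 amounts", "insufficient_data")
    ref_row <- s[s$amount == series$reference, , drop = FALSE]
    si <- if (!is.null(s$si)) s$si else
        stainIndex(s$mfi_ab, s$mfi_iso, s$sd_iso)
    out <- data.frame(amount = s$amount, si = si)
    if (!is.null(s$mfi_ab)) {
        out$ratio_mfi_ab <- ratioMFI(s$mfi_ab, ref_row$mfi_ab)
        out$ratio_mfi_iso <- ratioMFI(s$mfi_iso, ref_row$mfi_iso)
    }
    out
}

#' Select the optimal antibody amount from a titration
#'
#' Policy: the smallest tested amount whose stain index reaches at least
#' \code{theta} times the maximum SI of the series (and, when configured,
#' whose isotype ratio MFI does not exceed \code{iso_ratio_cap}). This is
#' the simplest rule expressing "high signal at minimal antibody
#' consumption": with \code{theta = 1} it returns the max-SI amount, as
#' \code{theta} approaches 0 it returns the smallest tested amount.
#'
#' @param series a \code{\link{titrationSeries}} or a data.frame with
#'   columns \code{amount} and \code{si}.
#' @param theta fraction of the maximum SI required (0 < theta <= 1,
#'   default 0.75).
#' @param iso_ratio_cap maximum allowed isotype ratio MFI (default Inf).
#' @return the selected amount; if no amount satisfies the constraints,
#'   the max-SI amount with a warning.
#' @export
selectOptimalAmount <- function(series, theta = 0.75, iso_ratio_cap = Inf) {
    stopifnot(theta > 0, theta <= 1)
    tab <- if (inherits(series, "titration_series"))
        evaluateTitration(series) else series
    if (anyNA(tab$si))
        abort("every amount needs a stain index", "spec_error")
    ok <- tab$si >= theta * max(tab$si)
    if (is.finite(iso_ratio_cap) && !is.null(tab$ratio_mfi_iso))
        ok <- ok & tab$ratio_mfi_iso <= iso_ratio_cap
    if (!any(ok)) {
        warning("no amount satisfies the policy; returning the max-SI amount")
        return(tab$amount[which.max(tab$si)])
    }
    min(tab$amount[ok])
}

#' Summarize a blocking panel into a cross-reactivity profile
#'
#' @param measurements data.frame with one row per blocking measurement:
#'   \code{blocker}, \code{cell_type}, \code{condition},
#'   \code{replicate}, \code{efficiency}, optional \code{qc_flag}.
#' @param antibody antibody name.
#' @param self_blocker the blocker identical to the antigen (default
#'   \code{"aSyn_monomer"}).
#' @return a \code{crossreactivity_profile}: the measurement table plus a
#'   per-blocker summary (mean efficiency across replicates, SD, n).
#' @export
summarizeBlockingPanel <- function(measurements, antibody,
                                   self_blocker = "aSyn_monomer") {
    if (!nrow(measurements)) {
        return(structure(list(antibody = antibody, measurements = measurements,
                              summary = data.frame(), self_blocker = self_blocker),
                         class = "crossreactivity_profile"))
    }
    need <- c("blocker", "efficiency")
    if (!all(need %in% names(measurements)))
        abort("measurements need 'blocker' and 'efficiency' columns",
              "spec_error")
    for (col in c("cell_type", "condition", "replicate"))
        if (is.null(measurements[[col]])) measurements[[col]] <- 1L
    key <- interaction(measurements$blocker, measurements$cell_type,
                       measurements$condition, measurements$replicate,
                       drop = TRUE)
    if (anyDuplicated(key))
        abort("duplicate (blocker, cell type, condition, replicate) keys",
              "spec_error")
    agg <- do.call(rbind, lapply(split(measurements, measurements$blocker),
        function(d) data.frame(blocker = d$blocker[[1L]],
                               mean_efficiency = mean(d$efficiency),
                               sd_efficiency = if (nrow(d) > 1L)
                                   sd(d$efficiency) else NA_real_,
                               n = nrow(d), stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    structure(list(antibody = antibody, measurements = measurements,
                   summary = agg, self_blocker = self_blocker),
              class = "crossreactivity_profile")
}

#' Classify antibody specificity from a blocking panel
#'
#' An antibody is called specific when its mean self-blocking efficiency
#' (blocking by its own antigen) reaches \code{self_threshold}; every
#' non-self blocker whose mean efficiency reaches \code{cross_threshold}
#' is flagged as a cross-reactant.
#'
#' @param profile a \code{crossreactivity_profile} from
#'   \code{\link{summarizeBlockingPanel}}.
#' @param self_threshold minimum mean self-blocking efficiency for a
#'   specific call (default 0.85).
#' @param cross_threshold efficiency at which a non-self blocker is
#'   flagged cross-reactive (default 0.40).
#' @return list: \code{antibody}, \code{specific} (logical),
#'   \code{cross_reactive_with} (character), \code{self_efficiency},
#'   and the thresholds used.
#' @export
classifySpecificity <- function(profile, self_threshold = 0.85,
                                cross_threshold = 0.40) {
    stopifnot(inherits(profile, "crossreactivity_profile"))
    s <- profile$summary
    self <- s[s$blocker == profile$self_blocker, , drop = FALSE]
    if (!nrow(self))
        abort(paste0("no self-blocker ('", profile$self_blocker,
                     "') entry in the panel"), "spec_error")
    # mixtures contain the antigen itself and other antigen species
    # (e.g. aggregates) are the same protein: neither is evidence of
    # cross-reactivity
    antigen <- sub("_.*$", "", profile$self_blocker)
    others <- s[s$blocker != profile$self_blocker &
                !grepl("^mix", s$blocker) &
                !startsWith(s$blocker, paste0(antigen, "_")), , drop = FALSE]
    flagged <- others$blocker[others$mean_efficiency >= cross_threshold]
    list(antibody = profile$antibody,
         specific = self$mean_efficiency >= self_threshold,
         cross_reactive_with = as.character(flagged),
         self_efficiency = self$mean_efficiency,
         self_threshold = self_threshold,
         cross_threshold = cross_threshold)
}

#' Classify per-cell-type expression from stain indices
#'
#' Relative-plus-floor classes: \code{not_detected} when the SI is
#' missing or at most \code{floor}; \code{marginal} between \code{floor}
#' and \code{detect_threshold}; \code{detected} otherwise. Cell types are
#' also returned ordered by SI (descending), the antibody's relative
#' expression map.
#'
#' @param si named numeric vector of stain indices per cell type
#'   (NA = no measurable signal).
#' @param detect_threshold SI at or above which expression is
#'   \code{detected} (default 1.5).
#' @param floor SI at or below which expression is \code{not_detected}
#'   (default 0.5).
#' @return list with \code{classes} (named character) and
#'   \code{ordering} (cell types by SI descending, NA last).
#' @export
classifyExpression <- function(si, detect_threshold = 1.5, floor = 0.5) {
    stopifnot(detect_threshold > floor)
    cls <- ifelse(is.na(si) | si <= floor, "not_detected",
                  ifelse(si < detect_threshold, "marginal", "detected"))
    names(cls) <- names(si)
    ord <- names(si)[order(si, decreasing = TRUE, na.last = TRUE)]
    list(classes = cls, ordering = ord)
}

#' Rank antibodies by specificity
#'
#' Lexicographic, deterministic: (1) specific antibodies before
#' non-specific; (2) fewer cross-reactivity flags first; (3) higher mean
#' self-blocking efficiency first; remaining ties keep the input order
#' (stable).
#'
#' @param assessments list of specificity assessments from
#'   \code{\link{classifySpecificity}}.
#' @return data.frame ordered best-first: \code{antibody},
#'   \code{specific}, \code{n_cross_reactive}, \code{self_efficiency},
#'   \code{cross_reactive_with}.
#' @export
rankAntibodies <- function(assessments) {
    stopifnot(length(assessments) >= 1L)
    tab <- data.frame(
        antibody = vapply(assessments, `[[`, character(1L), "antibody"),
        specific = vapply(assessments, `[[`, logical(1L), "specific"),
        n_cross_reactive = vapply(assessments, function(a)
            length(a$cross_reactive_with), integer(1L)),
        self_efficiency = vapply(assessments, `[[`, numeric(1L),
                                 "self_efficiency"),
        cross_reactive_with = vapply(assessments, function(a)
            paste(a$cross_reactive_with, collapse = ","), character(1L)),
        stringsAsFactors = FALSE)
    ord <- order(!tab$specific, tab$n_cross_reactive, -tab$self_efficiency)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}
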