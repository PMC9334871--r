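# The workflow's defined statistics: MFI/SD, stain index, ratio MFI,
# normalized MFI, blocking efficiency, and the Western-blot normalization
# arithmetic.
#
# MFI is the arithmetic mean of the compensated intensities of a gated
# population (a median option exists for robustness studies but is never
# the default). The stain index uses the difference form
# (MFI_ab - MFI_iso) / (2 * SD_iso), the standard definition of the
# signal-to-background separation of a stained/isotype pair.

#' Mean and standard deviation of a gated population
#'
#' @param events an \linkS4class{EventTable} (already gated) or numeric
#'   vector of intensities.
#' @param channel channel name when \code{events} is an EventTable;
#'   defaults to the first fluorescence channel.
#' @param center \code{"mean"} (default, the MFI definition) or
#'   \code{"median"} for robustness studies.
#' @return named numeric vector \code{c(MFI, SD)}; SD uses the n - 1
#'   denominator.
#' @examples
#' populationStats(c(1, 2, 3))  # MFI 2, SD 1
#' @export
populationStats <- function(events, channel = NULL,
                            center = c("mean", "median")) {
    center <- match.arg(center)
    x <- intensityVector(events, channel)
    if (length(x) < 2L)
        abort("at least 2 events are required for MFI/SD",
              "insufficient_data")
    mfi <- if (center == "mean") mean(x) else median(x)
    c(MFI = mfi, SD = sd(x))
}

intensityVector <- function(events, channel = NULL) {
    if (is(events, "EventTable")) {
        if (is.null(channel))
            channel <- channelByRole(events, "fluorescence")
        eventMatrix(events)[, channel]
    } else {
        as.numeric(events)
    }
}

#' Stain index
#'
#' \deqn{SI = (MFI_{ab} - MFI_{iso}) / (2 \cdot SD_{iso})}
#'
#' The separation of the antibody-stained population from the isotype
#' control background, in units of twice the background SD. May be
#' negative; undefined (an error) when \code{SD_iso = 0}. SI is invariant
#' under any affine intensity transform \code{x -> a x + b} (a > 0)
#' applied to both samples.
#'
#' @param mfi_ab MFI of the antibody-stained sample.
#' @param mfi_iso MFI of the isotype-control-stained sample.
#' @param sd_iso SD of the isotype-control-stained sample (> 0).
#' @return the stain index (dimensionless).
#' @examples
#' stainIndex(1000, 100, 50)  # 9
#' @export
stainIndex <- function(mfi_ab, mfi_iso, sd_iso) {
    if (any(sd_iso <= 0))
        abort("stain index undefined: SD of isotype control must be > 0",
              "undefined_si")
    (mfi_ab - mfi_iso) / (2 * sd_iso)
}

#' Ratio MFI (fold change against the recommended amount)
#'
#' \code{ratioMFI(MFI_x, MFI_ref) = MFI_x / MFI_ref}, the fold-change of
#' the signal at some antibody amount over the signal at the
#' manufacturer-recommended amount.
#'
#' @param mfi_x MFI at the tested amount.
#' @param mfi_ref MFI at the reference (recommended) amount, > 0.
#' @return fold change.
#' @export
ratioMFI <- function(mfi_x, mfi_ref) {
    if (any(mfi_ref <= 0))
        abort("reference MFI must be > 0", "undefined_ratio")
    mfi_x / mfi_ref
}

#' Normalized MFI of a stained/isotype pair
#'
#' Two conventions are in use and both are supported; callers must pick
#' one, and the form is recorded in the result: \code{"ratio"} =
#' \code{MFI_ab / MFI_iso}, \code{"difference"} = \code{MFI_ab - MFI_iso}.
#'
#' @param mfi_ab,mfi_iso MFIs of the stained and isotype samples.
#' @param form \code{"ratio"} or \code{"difference"}.
#' @return numeric value with attribute \code{form}.
#' @export
normalizedMFI <- function(mfi_ab, mfi_iso, form = c("ratio", "difference")) {
    form <- match.arg(form)
    if (form == "ratio" && any(mfi_iso == 0))
        abort("ratio-form normalized MFI undefined for MFI_iso = 0",
              "undefined_ratio")
    out <- if (form == "ratio") mfi_ab / mfi_iso else mfi_ab - mfi_iso
    structure(out, form = form)
}

#' Blocking efficiency
#'
#' Fraction of the specific staining signal removed by pre-incubating the
#' antibody with excess blocking protein:
#' \deqn{E = (MFI_{stained} - MFI_{blocked}) /
#'           (MFI_{stained} - MFI_{nostain})}
#' Values below 0 or above 1 are reported as-is with a QC flag rather
#' than clipped. When \code{MFI_stained <= MFI_nostain} there is no
#' specific signal to block and the efficiency is undefined (the
#' "no detectable blocking" regime seen for low-sensitivity antibodies in
#' low-expressing cells).
#'
#' @param mfi_stained MFI of the directly stained sample.
#' @param mfi_blocked MFI after staining with the pre-blocked antibody.
#' @param mfi_nostain MFI of the unstained control.
#' @return efficiency (fraction) with attribute \code{qc_flag}
#'   (\code{"ok"} or \code{"out_of_range"}).
#' @examples
#' blockingEfficiency(1000, 500, 200)  # 0.625
#' @export
blockingEfficiency <- function(mfi_stained, mfi_blocked, mfi_nostain) {
    if (any(mfi_stained <= mfi_nostain))
        abort(paste0("blocking efficiency undefined: stained MFI does not ",
                     "exceed the no-stain control (no detectable blocking ",
                     "regime)"), "undefined_blocking")
    e <- (mfi_stained - mfi_blocked) / (mfi_stained - mfi_nostain)
    structure(e, qc_flag = ifelse(e < 0 | e > 1, "out_of_range", "ok"))
}

#' Western-blot normalized signal
#'
#' Band intensity of the target normalized to the beta-actin loading
#' control of the same lane, then to the untreated reference sample:
#' \code{(target / actin) / reference}.
#'
#' @param target target band intensity (>= 0).
#' @param actin beta-actin band intensity (> 0).
#' @param reference actin-normalized ratio of the untreated sample (> 0).
#' @return normalized signal (1 for the reference itself).
#' @export
wbNormalizedSignal <- function(target, actin, reference) {
    if (any(actin <= 0) || any(reference <= 0))
        abort("actin intensity and reference ratio must be > 0",
              "undefined_ratio")
    (target / actin) / reference
}

#' Stain statistics for a stained/isotype sample pair
#'
#' Bundles the per-pair metrics: MFI of both samples, SD of the isotype
#' control, stain index, and normalized MFI in the requested form.
#'
#' @param ab_events gated antibody-stained events
#'   (\linkS4class{EventTable} or numeric vector).
#' @param iso_events gated isotype-control events.
#' @param channel fluorescence channel name (EventTable input).
#' @param amount antibody amount (microgram per 50 microlitre staining).
#' @param form normalized-MFI form, \code{"ratio"} or \code{"difference"}.
#' @return one-row data.frame: \code{amount}, \code{mfi_ab},
#'   \code{mfi_iso}, \code{sd_iso}, \code{si}, \code{normalized_mfi},
#'   \code{norm_form}.
#' @export
stainStatistics <- function(ab_events, iso_events, channel = NULL,
                            amount = NA_real_,
                            form = c("ratio", "difference")) {
    form <- match.arg(form)
    ab <- populationStats(ab_events, channel)
    iso <- populationStats(iso_events, channel)
    data.frame(
        amount = amount,
        mfi_ab = ab[["MFI"]], mfi_iso = iso[["MFI"]],
        sd_iso = iso[["SD"]],
        si = stainIndex(ab[["MFI"]], iso[["MFI"]], iso[["SD"]]),
        normalized_mfi = as.numeric(normalizedMFI(ab[["MFI"]], iso[["MFI"]],
                                                  form)),
        norm_form = form,
        stringsAsFactors = FALSE)
}
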