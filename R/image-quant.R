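# Semi-automated immunocytochemistry quantification: Li
# minimum-cross-entropy threshold on the neuronal-marker channel, then
# mean gray value of the target channel inside the resulting mask.

#' Li minimum-cross-entropy threshold
#'
#' Iterative scheme of Li & Tam: starting from the image mean, the
#' threshold t is updated to
#' \deqn{t' = (\mu_b(t) - \mu_f(t)) / (\ln \mu_b(t) - \ln \mu_f(t))}
#' where \eqn{\mu_b}, \eqn{\mu_f} are the mean intensities at or below /
#' above t, until the update moves less than \code{tol} intensity units.
#' The fixed point minimizes the cross-entropy between the image and its
#' two-level reconstruction. Images containing nonpositive values are
#' shifted so logarithms are defined; the returned threshold is on the
#' original scale.
#'
#' @param image numeric matrix or vector of pixel intensities with at
#'   least two distinct values.
#' @param tol convergence tolerance in intensity units (default 0.5).
#' @param max_iter iteration cap.
#' @return the threshold (pixels >= threshold are foreground).
#' @export
liThreshold <- function(image, tol = 0.5, max_iter = 200L) {
    x <- as.numeric(image)
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L)
        abort("constant image: threshold undefined (degenerate histogram)",
              "degenerate_histogram")
    # shift so all values are positive (log-means must exist)
    shift <- 0
    mn <- min(x)
    if (mn <= 0) {
        shift <- -mn + max(diff(range(x)) * 1e-6, .Machine$double.eps)
        x <- x + shift
    }
    iterate <- function(t_cur) {
        for (k in seq_len(max_iter)) {
            back <- x[x <= t_cur]
            fore <- x[x > t_cur]
            if (!length(back) || !length(fore)) break
            mb <- mean(back); mf <- mean(fore)
            t_new <- (mb - mf) / (log(mb) - log(mf))
            if (abs(t_new - t_cur) < tol) return(t_new)
            t_cur <- t_new
        }
        t_cur
    }
    # the update has one fixed point per histogram valley; on strongly
    # overlapping mixtures the one reached from the image mean need not
    # minimize the cross-entropy, so iterate from a deterministic set of
    # quantile starts and keep the fixed point with the lowest criterion
    starts <- unique(c(mean(x),
                       quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE)))
    fixed <- vapply(starts, iterate, numeric(1L))
    best <- fixed[which.min(vapply(fixed, function(t) liCrossEntropy(x, t),
                                   numeric(1L)))]
    best - shift
}

# Li cross-entropy criterion for a candidate threshold, used by the
# exhaustive-scan mode of batchQuantify and by tests as the direct
# objective the iterative scheme minimizes.
liCrossEntropy <- function(x, t) {
    x <- as.numeric(x)
    back <- x[x <= t]; fore <- x[x > t]
    if (!length(back) || !length(fore)) return(Inf)
    mb <- mean(back); mf <- mean(fore)
    if (mb <= 0 || mf <= 0) return(Inf)
    -(sum(back) * log(mb) + sum(fore) * log(mf))
}

#' Quantify a two-channel immunocytochemistry image
#'
#' The marker channel is thresholded (Li method unless a fixed threshold
#' is given); the mask is all marker pixels at or above the threshold;
#' the result is the arithmetic mean of the target-channel pixels inside
#' the mask. No morphological cleanup is applied.
#'
#' @param image a \linkS4class{TwoChannelImage}.
#' @param threshold optional fixed threshold; default: Li threshold of
#'   the marker channel.
#' @return list: \code{threshold}, \code{mask_pixels},
#'   \code{mask_fraction}, \code{mean_gray}.
#' @export
quantifyICC <- function(image, threshold = NULL) {
    stopifnot(is(image, "TwoChannelImage"))
    if (is.null(threshold)) threshold <- liThreshold(image@marker)
    mask <- image@marker >= threshold
    if (!any(mask))
        abort("no marker-positive area (empty mask)", "empty_mask")
    list(threshold = threshold,
         mask_pixels = sum(mask),
         mask_fraction = mean(mask),
         mean_gray = mean(image@target[mask]))
}

#' Batch immunocytochemistry quantification
#'
#' @param images list of \linkS4class{TwoChannelImage}.
#' @param policy \code{"per_image"} (Li threshold per image) or
#'   \code{"constant_from_reference"} (one Li threshold from the
#'   designated reference image, or from the pooled marker histogram,
#'   applied batch-wide: the constant-threshold protocol).
#' @param reference index of the reference image, or \code{"pooled"}.
#' @return list of \code{\link{quantifyICC}} results.
#' @export
batchQuantify <- function(images,
                          policy = c("per_image", "constant_from_reference"),
                          reference = 1L) {
    policy <- match.arg(policy)
    if (!length(images)) abort("at least one image required", "input_error")
    if (policy == "per_image")
        return(lapply(images, quantifyICC))
    thr <- if (identical(reference, "pooled")) {
        liThreshold(unlist(lapply(images, function(im) as.numeric(im@marker))))
    } else {
        liThreshold(images[[reference]]@marker)
    }
    lapply(images, quantifyICC, threshold = thr)
}

#' Read a two-channel image from TIFF or PNG
#'
#' @param path image file (TIFF or PNG; grayscale multi-channel or an
#'   array with channels in the third dimension).
#' @param marker,target channel indices (third array dimension).
#' @param bitDepth nominal pixel depth; intensities are rescaled from
#'   [0, 1] to [0, 2^bitDepth - 1] when the reader returns normalized
#'   values.
#' @return a \linkS4class{TwoChannelImage}.
#' @export
readTwoChannelImage <- function(path, marker = 1L, target = 2L,
                                bitDepth = 8) {
    ext <- tolower(tools::file_ext(path))
    arr <- if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            abort("package 'tiff' is required to read TIFF files",
                  "input_error")
        a <- tiff::readTIFF(path, all = TRUE)
        if (is.list(a)) simplify2array(a) else a
    } else if (ext == "png") {
        if (!requireNamespace("png", quietly = TRUE))
            abort("package 'png' is required to read PNG files",
                  "input_error")
        png::readPNG(path)
    } else {
        abort(paste0("unsupported image format: ", ext), "input_error")
    }
    if (length(dim(arr)) == 2L)
        abort("image has a single channel; two are required", "input_error")
    scale <- if (max(arr) <= 1) 2^bitDepth - 1 else 1
    TwoChannelImage(arr[, , marker] * scale, arr[, , target] * scale,
                    bitDepth = bitDepth)
}
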