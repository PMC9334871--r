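# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that identical
# (spec, seed) pairs give identical output without touching global state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number", call. = FALSE)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(expr)
}

#' Arithmetic mean and SD of a lognormal given geometric mean and CV
#'
#' Fluorescence populations are parameterised by their geometric mean
#' \code{gm} and arithmetic coefficient of variation \code{cv}. For a
#' lognormal with \code{meanlog = log(gm)} and
#' \code{sdlog = sqrt(log(1 + cv^2))} this returns the arithmetic mean
#' \code{gm * sqrt(1 + cv^2)} and SD \code{mean * cv}, the moments that MFI
#' and SD estimators recover.
#'
#' @param gm geometric mean (> 0).
#' @param cv arithmetic coefficient of variation (>= 0).
#' @return named numeric vector with elements \code{mean}, \code{sd},
#'   \code{sdlog}.
#' @export
lognormalMoments <- function(gm, cv) {
    stopifnot(gm > 0, cv >= 0)
    sdlog <- sqrt(log1p(cv^2))
    m <- gm * exp(sdlog^2 / 2)
    c(mean = m, sd = m * cv, sdlog = sdlog)
}

# stop() with a classed condition so callers/tests can distinguish error
# families (format, mapping, numerical, spec, insufficient data, ...).
abort <- function(msg, class) {
    stop(structure(class = c(class, "flowAbVal_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}
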