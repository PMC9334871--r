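#' @import methods
#' @importFrom stats median quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils read.csv
NULL

#' Event matrix of an EventTable
#' @param x an \code{\link{EventTable}}.
#' @return numeric matrix, one row per event, one column per channel.
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' Channel definitions of an EventTable
#' @param x an \code{\link{EventTable}}.
#' @return data.frame with columns \code{name}, \code{role}, \code{detector}.
#' @export
setGeneric("channelDefs", function(x) standardGeneric("channelDefs"))

#' Sample metadata of an EventTable
#' @param x an \code{\link{EventTable}}.
#' @return named list of sample annotations.
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' Number of events
#' @param x an \code{\link{EventTable}} or \code{\link{GatedPopulation}}.
#' @return integer count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Apply fluorescence spillover compensation
#'
#' @param x an \code{\link{EventTable}} with raw intensities.
#' @param spillover a \code{\link{SpilloverMatrix}} over a subset of the
#'   table's fluorescence/viability channels.
#' @return a compensated \code{EventTable}; see
#'   \code{\link{compensate,EventTable,SpilloverMatrix-method}}.
#' @export
setGeneric("compensate", function(x, spillover) standardGeneric("compensate"))
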