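#' @import methods
#' @importFrom stats cor lm lm.fit pt coef p.adjust quantile rnorm rbinom
#'   sd var setNames complete.cases
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Subject identifier of an object
#'
#' @param x an object carrying a subject identifier
#'   ([RoiTimeSeries-class], [ConnectivityMatrix-class],
#'   [SegregationProfile-class]).
#' @return A length-one character vector.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Region identifiers of an object
#'
#' @param x an object carrying ordered region identifiers.
#' @return Character vector of region identifiers, in matrix order.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Fisher-z connectivity matrix of an object
#'
#' @param x a [ConnectivityMatrix-class].
#' @return A symmetric numeric matrix in Fisher-z units, with region
#'   identifiers as dimnames.
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' Has a connectivity matrix been prepared for segregation analysis?
#'
#' A prepared matrix has its diagonal and all formerly negative entries set
#' to zero.
#'
#' @param x a [ConnectivityMatrix-class].
#' @return Logical flag.
#' @export
setGeneric("isPrepared", function(x) standardGeneric("isPrepared"))

#' Network labels of a partition or profile
#'
#' @param x a [NetworkPartition-class] or [SegregationProfile-class].
#' @return Character vector of network labels in canonical order.
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' Region-to-network assignment of a partition
#'
#' @param x a [NetworkPartition-class].
#' @return Named character vector mapping region identifier to network
#'   label.
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))
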