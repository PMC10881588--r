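#' @include AllGenerics.R
NULL

.SYMMETRY_TOL <- 1e-10

#' RoiTimeSeries: one subject's ROI signal matrix
#'
#' Holds the mean BOLD (or other) signal of R regions of interest over T
#' timepoints for a single subject. Rows are timepoints, columns are
#' regions. This is the input to [computeFC()]; all upstream image
#' preprocessing is assumed done.
#'
#' @slot subjectId length-one character identifier.
#' @slot values numeric T x R matrix, no missing values.
#' @slot regionIds character vector of R unique region identifiers,
#'   matching the column order of `values`.
#'
#' @section Validity:
#' T >= 3, R >= 2, all values finite, region identifiers unique, and every
#' region has positive variance over time (a constant column has no defined
#' correlation and is rejected by name).
#'
#' @seealso [roiTimeSeries()] constructor, [computeFC()].
#' @export
setClass("RoiTimeSeries",
  representation(
    subjectId = "character",
    values = "matrix",
    regionIds = "character"
  )
)

setValidity("RoiTimeSeries", function(object) {
  v <- object@values
  ids <- object@regionIds
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId)) {
    msgs <- c(msgs, "subjectId must be a single non-missing string")
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) < 3L) msgs <- c(msgs, "need at least 3 timepoints")
  if (ncol(v) < 2L) msgs <- c(msgs, "need at least 2 regions")
  if (anyNA(v) || any(!is.finite(v))) {
    msgs <- c(msgs, "values contain missing or non-finite entries")
  }
  if (length(ids) != ncol(v)) {
    msgs <- c(msgs, "regionIds length must equal number of columns")
  }
  if (anyDuplicated(ids)) msgs <- c(msgs, "regionIds must be unique")
  if (length(msgs) == 0L) {
    vars <- apply(v, 2L, stats::var)
    if (any(vars <= 0)) {
      bad <- ids[vars <= 0]
      msgs <- c(msgs, paste0(
        "zero-variance region(s): ", paste(bad, collapse = ", ")
      ))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param subjectId subject identifier.
#' @param values numeric T x R matrix (timepoints x regions).
#' @param regionIds region identifiers; defaults to `colnames(values)`.
#' @return A validated [RoiTimeSeries-class] object.
#' @examples
#' ts <- roiTimeSeries("s1", cbind(a = rnorm(10), b = rnorm(10)))
#' regionIds(ts)
#' @export
roiTimeSeries <- function(subjectId, values, regionIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(regionIds)) {
    regionIds <- paste0("R", seq_len(ncol(values)))
  }
  colnames(values) <- regionIds
  new("RoiTimeSeries",
    subjectId = as.character(subjectId),
    values = values, regionIds = as.character(regionIds)
  )
}

#' ConnectivityMatrix: symmetric region x region Fisher-z matrix
#'
#' The working representation of one subject's functional connectivity:
#' Fisher r-to-z transformed Pearson correlations between all region pairs.
#' The `prepared` flag records whether the diagonal and all negative
#' entries have been set to zero ([prepareMatrix()]), the state required
#' by the segregation computations.
#'
#' @slot subjectId length-one character identifier.
#' @slot z numeric symmetric R x R matrix in Fisher-z units.
#' @slot regionIds character vector of R region identifiers.
#' @slot prepared logical flag.
#'
#' @section Validity:
#' `z` square and symmetric to within 1e-10; if `prepared`, the diagonal is
#' exactly zero and no entry is negative.
#'
#' @seealso [computeFC()], [prepareMatrix()], [profileSubject()].
#' @export
setClass("ConnectivityMatrix",
  representation(
    subjectId = "character",
    z = "matrix",
    regionIds = "character",
    prepared = "logical"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  z <- object@z
  msgs <- character()
  if (nrow(z) != ncol(z)) msgs <- c(msgs, "z must be square")
  if (length(object@regionIds) != nrow(z)) {
    msgs <- c(msgs, "regionIds length must equal matrix dimension")
  }
  if (anyDuplicated(object@regionIds)) {
    msgs <- c(msgs, "regionIds must be unique")
  }
  if (anyNA(z)) msgs <- c(msgs, "z contains missing values")
  if (length(msgs) == 0L && max(abs(z - t(z))) > .SYMMETRY_TOL) {
    msgs <- c(msgs, "z is not symmetric")
  }
  if (length(msgs) == 0L && isTRUE(object@prepared)) {
    if (any(diag(z) != 0)) msgs <- c(msgs, "prepared matrix must have zero diagonal")
    if (any(z < 0)) msgs <- c(msgs, "prepared matrix must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' Usually produced by [computeFC()]; the constructor is exposed for tests
#' and for reading matrices back from disk.
#'
#' @param subjectId subject identifier.
#' @param z symmetric numeric matrix in Fisher-z units.
#' @param regionIds region identifiers; defaults to `rownames(z)`.
#' @param prepared whether diagonal/negative zeroing has been applied.
#' @return A validated [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(subjectId, z, regionIds = rownames(z),
                               prepared = FALSE) {
  z <- as.matrix(z)
  if (is.null(regionIds)) regionIds <- paste0("R", seq_len(nrow(z)))
  dimnames(z) <- list(regionIds, regionIds)
  new("ConnectivityMatrix",
    subjectId = as.character(subjectId), z = z,
    regionIds = as.character(regionIds), prepared = isTRUE(prepared)
  )
}

#' NetworkPartition: region-to-network assignment
#'
#' Maps every region of a parcellation to exactly one functional network.
#' The reference configuration has 142 regions grouped into nine networks
#' (default, control, limbic, salience/ventral attention, dorsal
#' attention, somatomotor, visual, temporoparietal, subcortical); see
#' [defaultPartition()].
#'
#' @slot assignment named character vector: names are region identifiers,
#'   values are network labels.
#' @slot networks character vector giving the canonical network order.
#'
#' @section Validity:
#' Every region assigned exactly once; every listed network non-empty; no
#' assignment to an unlisted network. Network-level segregation
#' additionally requires >= 2 regions in the network, enforced at
#' computation time.
#'
#' @export
setClass("NetworkPartition",
  representation(
    assignment = "character",
    networks = "character"
  )
)

setValidity("NetworkPartition", function(object) {
  a <- object@assignment
  nets <- object@networks
  msgs <- character()
  if (is.null(names(a)) || any(names(a) == "")) {
    msgs <- c(msgs, "assignment must be named by region identifier")
  } else if (anyDuplicated(names(a))) {
    msgs <- c(msgs, "each region must be assigned exactly once")
  }
  if (anyDuplicated(nets)) msgs <- c(msgs, "network labels must be unique")
  unknown <- setdiff(unique(a), nets)
  if (length(unknown)) {
    msgs <- c(msgs, paste0(
      "assignment uses unlisted network(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  empty <- setdiff(nets, unique(a))
  if (length(empty)) {
    msgs <- c(msgs, paste0(
      "empty network(s): ", paste(empty, collapse = ", ")
    ))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a NetworkPartition
#'
#' @param assignment named character vector (region id -> network label),
#'   or a two-column data.frame with columns `region_id`, `network`.
#' @param networks canonical network order; defaults to order of first
#'   appearance in `assignment`.
#' @return A validated [NetworkPartition-class].
#' @examples
#' p <- networkPartition(c(r1 = "A", r2 = "A", r3 = "B", r4 = "B"))
#' networks(p)
#' @export
networkPartition <- function(assignment, networks = NULL) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(
      as.character(assignment[[2L]]),
      as.character(assignment[[1L]])
    )
  }
  if (is.null(networks)) networks <- unique(unname(assignment))
  new("NetworkPartition",
    assignment = assignment,
    networks = as.character(networks)
  )
}

#' SegregationProfile: per-subject segregation summary
#'
#' All system-segregation quantities for one subject computed from a
#' prepared connectivity matrix: global and per-network mean
#' within-network connectivity (Zw), mean between-network connectivity
#' (Zb), segregation (Zw - Zb)/Zw, intra-network mean connectivity
#' (identical to Zw by construction) and the matrix of pairwise
#' inter-network mean connectivity.
#'
#' @slot subjectId subject identifier.
#' @slot zwGlobal,zbGlobal,segGlobal global quantities (Fisher-z units;
#'   segregation dimensionless).
#' @slot zw,zb,seg,intra named numeric vectors over networks.
#' @slot inter numeric networks x networks symmetric matrix of mean
#'   between-pair connectivity; diagonal is NA.
#'
#' @seealso [profileSubject()], [profileTable()].
#' @export
setClass("SegregationProfile",
  representation(
    subjectId = "character",
    zwGlobal = "numeric",
    zbGlobal = "numeric",
    segGlobal = "numeric",
    zw = "numeric",
    zb = "numeric",
    seg = "numeric",
    intra = "numeric",
    inter = "matrix"
  )
)

#' MediationResult: single-mediator path model with bootstrap inference
#'
#' Output of [mediate()]. Paths are OLS coefficients on
#' covariate-residualized variables: `a` (predictor -> mediator), `b`
#' (mediator -> outcome given predictor), `c` (total effect), `cPrime`
#' (direct effect). The indirect effect is `a * b` and satisfies
#' c = c' + a*b exactly for OLS on one sample. Confidence bounds are
#' percentile bootstrap over subject resamples.
#'
#' @slot a,b,c,cPrime,indirect,proportionMediated path quantities.
#' @slot ciLower,ciUpper 95% percentile bootstrap bounds on the indirect
#'   effect.
#' @slot pBoot two-sided sign-crossing bootstrap p-value.
#' @slot nBoot,seed,n bootstrap bookkeeping.
#' @slot proportionStable FALSE when |c| is too small for the mediated
#'   proportion to be meaningful.
#' @export
setClass("MediationResult",
  representation(
    a = "numeric", b = "numeric", c = "numeric", cPrime = "numeric",
    indirect = "numeric", proportionMediated = "numeric",
    ciLower = "numeric", ciUpper = "numeric", pBoot = "numeric",
    nBoot = "integer", seed = "integer", n = "integer",
    proportionStable = "logical"
  )
)

## ---- accessors ----

#' @rdname subjectId
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)
#' @rdname subjectId
#' @export
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)
#' @rdname subjectId
#' @export
setMethod("subjectId", "SegregationProfile", function(x) x@subjectId)

#' @rdname regionIds
#' @export
setMethod("regionIds", "RoiTimeSeries", function(x) x@regionIds)
#' @rdname regionIds
#' @export
setMethod("regionIds", "ConnectivityMatrix", function(x) x@regionIds)
#' @rdname regionIds
#' @export
setMethod("regionIds", "NetworkPartition", function(x) names(x@assignment))

#' @rdname zMatrix
#' @export
setMethod("zMatrix", "ConnectivityMatrix", function(x) x@z)

#' @rdname isPrepared
#' @export
setMethod("isPrepared", "ConnectivityMatrix", function(x) x@prepared)

#' @rdname networks
#' @export
setMethod("networks", "NetworkPartition", function(x) x@networks)
#' @rdname networks
#' @export
setMethod("networks", "SegregationProfile", function(x) names(x@seg))

#' @rdname assignment
#' @export
setMethod("assignment", "NetworkPartition", function(x) x@assignment)

## ---- show methods ----

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries '", object@subjectId, "': ",
    nrow(object@values), " timepoints x ", ncol(object@values),
    " regions\n",
    sep = ""
  )
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix '", object@subjectId, "': ",
    nrow(object@z), " x ", ncol(object@z), " Fisher-z",
    if (object@prepared) ", prepared (diag/negatives zeroed)" else "",
    "\n",
    sep = ""
  )
})

setMethod("show", "NetworkPartition", function(object) {
  tab <- table(factor(object@assignment, levels = object@networks))
  cat("NetworkPartition: ", length(object@assignment), " regions, ",
    length(object@networks), " networks\n",
    sep = ""
  )
  print(tab)
})

setMethod("show", "SegregationProfile", function(object) {
  cat("SegregationProfile '", object@subjectId, "'\n",
    "  global: Zw = ", format(object@zwGlobal, digits = 4),
    ", Zb = ", format(object@zbGlobal, digits = 4),
    ", segregation = ", format(object@segGlobal, digits = 4), "\n",
    "  networks: ", paste(names(object@seg), collapse = ", "), "\n",
    sep = ""
  )
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (n = ", object@n, ", ", object@nBoot,
    " bootstrap resamples, seed ", object@seed, ")\n",
    "  a = ", format(object@a, digits = 4),
    ", b = ", format(object@b, digits = 4),
    ", c = ", format(object@c, digits = 4),
    ", c' = ", format(object@cPrime, digits = 4), "\n",
    "  indirect = ", format(object@indirect, digits = 4),
    " [", format(object@ciLower, digits = 4), ", ",
    format(object@ciUpper, digits = 4), "], p = ",
    format(object@pBoot, digits = 3), "\n",
    "  proportion mediated = ",
    if (object@proportionStable) {
      format(object@proportionMediated, digits = 4)
    } else {
      "unstable (|total effect| near zero)"
    }, "\n",
    sep = ""
  )
})
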