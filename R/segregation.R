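#' @include AllClasses.R
NULL

# Align a partition to a matrix's region order; errors on mismatch.
.alignPartition <- function(m, p) {
  ids <- m@regionIds
  miss <- setdiff(ids, names(p@assignment))
  extra <- setdiff(names(p@assignment), ids)
  if (length(miss) || length(extra)) {
    stop(
      "partition does not match matrix regions",
      if (length(miss)) {
        paste0("; unassigned: ", paste(utils::head(miss, 5L), collapse = ", "))
      } else "",
      if (length(extra)) {
        paste0("; absent from matrix: ", paste(utils::head(extra, 5L), collapse = ", "))
      } else ""
    )
  }
  p@assignment[ids]
}

.checkPrepared <- function(m) {
  stopifnot(is(m, "ConnectivityMatrix"))
  if (!isTRUE(m@prepared)) {
    stop("connectivity matrix must be prepared (see prepareMatrix())")
  }
}

#' Mean within- and between-network connectivity
#'
#' For a single network, `zw` is the mean Fisher-z value over all
#' unordered region pairs with both members in the network, and `zb` the
#' mean over pairs with exactly one member in the network (i.e. the
#' network's regions against all other regions of the brain). For
#' `scope = "global"`, `zw` pools all within-network pairs across all
#' networks and `zb` pools all between-network pairs; each unordered pair
#' is counted once, and edges that were zeroed during preparation
#' contribute 0 to the means rather than being excluded.
#'
#' @param m a prepared [ConnectivityMatrix-class].
#' @param p a [NetworkPartition-class] covering the matrix regions.
#' @param scope `"global"` or one network label.
#' @return Named numeric vector `c(zw = , zb = )`.
#' @export
withinBetweenMeans <- function(m, p, scope = "global") {
  .checkPrepared(m)
  stopifnot(is(p, "NetworkPartition"))
  a <- .alignPartition(m, p)
  z <- m@z
  ut <- upper.tri(z)
  if (identical(scope, "global")) {
    same <- outer(a, a, "==")
    zw <- mean(z[ut & same])
    zb <- mean(z[ut & !same])
  } else {
    if (!scope %in% p@networks) {
      stop("unknown network label: '", scope, "'")
    }
    inNet <- a == scope
    if (sum(inNet) < 2L) {
      stop(
        "network '", scope,
        "' has fewer than 2 regions; within-network mean undefined"
      )
    }
    both <- outer(inNet, inNet, "&")
    one <- outer(inNet, !inNet, "&") | outer(!inNet, inNet, "&")
    zw <- mean(z[ut & both])
    zb <- mean(z[ut & one])
  }
  c(zw = zw, zb = zb)
}

#' System segregation statistic
#'
#' Segregation = (Zw - Zb) / Zw: the relative excess of mean
#' within-network over mean between-network connectivity. 1 means no
#' between-network connectivity at all; 0 means within and between are
#' indistinguishable; negative values indicate stronger between- than
#' within-network coupling. Undefined when Zw = 0.
#'
#' @param zw mean within-network Fisher-z connectivity (> 0).
#' @param zb mean between-network Fisher-z connectivity.
#' @param scope label used in the error message when `zw` is 0.
#' @return `(zw - zb) / zw`.
#' @examples
#' segregationIndex(0.6, 0.2) # 2/3
#' @export
segregationIndex <- function(zw, zb, scope = "global") {
  if (any(zw == 0)) {
    stop("segregation undefined: mean within-network connectivity is 0 (",
      scope, ")")
  }
  (zw - zb) / zw
}

#' Fisher-z value of one region pair
#'
#' Symmetric lookup of a single edge in a prepared matrix; supports
#' edge-level association analyses.
#'
#' @param m a prepared [ConnectivityMatrix-class].
#' @param pair character vector of two region identifiers (or a
#'   one-row matrix as produced by [networkPairs()]).
#' @return The Fisher-z value at that pair.
#' @export
edgeFC <- function(m, pair) {
  .checkPrepared(m)
  pair <- as.character(pair)
  stopifnot(length(pair) == 2L)
  unknown <- setdiff(pair, m@regionIds)
  if (length(unknown)) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  }
  unname(m@z[pair[1L], pair[2L]])
}

#' Full segregation profile of one subject
#'
#' Computes every segregation quantity for one prepared matrix: global
#' and per-network mean within- (Zw) and between-network (Zb)
#' connectivity, segregation (Zw - Zb)/Zw, intra-network means
#' (equal to the per-network Zw) and all pairwise inter-network mean
#' connectivities.
#'
#' @param m a prepared [ConnectivityMatrix-class].
#' @param p a [NetworkPartition-class]; every network needs >= 2 regions.
#' @return A [SegregationProfile-class].
#' @examples
#' spec <- syntheticCohortSpec(nSubjects = 1, seed = 1)
#' m <- generateMatrices(spec)[[1]]
#' profileSubject(m, defaultPartition())
#' @export
profileSubject <- function(m, p) {
  .checkPrepared(m)
  a <- .alignPartition(m, p)
  nets <- p@networks
  z <- m@z
  ut <- upper.tri(z)
  inNet <- lapply(nets, function(nw) a == nw)
  names(inNet) <- nets

  zw <- zb <- setNames(numeric(length(nets)), nets)
  for (nw in nets) {
    wb <- withinBetweenMeans(m, p, scope = nw)
    zw[nw] <- wb[["zw"]]
    zb[nw] <- wb[["zb"]]
  }
  gl <- withinBetweenMeans(m, p, scope = "global")

  inter <- matrix(NA_real_, length(nets), length(nets),
    dimnames = list(nets, nets)
  )
  for (i in seq_along(nets)) {
    for (j in seq_along(nets)) {
      if (i < j) {
        mask <- outer(inNet[[i]], inNet[[j]], "&") |
          outer(inNet[[j]], inNet[[i]], "&")
        v <- mean(z[ut & mask])
        inter[i, j] <- inter[j, i] <- v
      }
    }
  }

  new("SegregationProfile",
    subjectId = m@subjectId,
    zwGlobal = unname(gl[["zw"]]),
    zbGlobal = unname(gl[["zb"]]),
    segGlobal = segregationIndex(gl[["zw"]], gl[["zb"]], scope = "global"),
    zw = zw, zb = zb,
    seg = segregationIndex(zw, zb, scope = "network-level"),
    intra = zw,
    inter = inter
  )
}

#' Segregation profiles of a cohort as a table
#'
#' Applies [profileSubject()] to each subject and assembles one wide
#' row per subject: `seg_global`, `seg.<network>`, `intra.<network>` and
#' `inter.<netA>.<netB>` columns (A < B in canonical network order),
#' ready to be merged with phenotypes for association analysis.
#'
#' @param matrices list of prepared [ConnectivityMatrix-class] objects.
#' @param p a [NetworkPartition-class].
#' @param edges optional two-column matrix of region pairs (as from
#'   [networkPairs()]); adds one `edge.<regA>.<regB>` column per pair.
#' @return A data.frame with one row per subject, first column
#'   `subject_id`.
#' @export
profileTable <- function(matrices, p, edges = NULL) {
  rows <- lapply(matrices, function(m) {
    pr <- profileSubject(m, p)
    nets <- names(pr@seg)
    vals <- c(
      seg_global = pr@segGlobal,
      zw_global = pr@zwGlobal,
      zb_global = pr@zbGlobal,
      setNames(pr@seg, paste0("seg.", nets)),
      setNames(pr@intra, paste0("intra.", nets))
    )
    for (i in seq_along(nets)) {
      for (j in seq_along(nets)) {
        if (i < j) {
          vals[paste0("inter.", nets[i], ".", nets[j])] <-
            pr@inter[i, j]
        }
      }
    }
    if (!is.null(edges)) {
      for (k in seq_len(nrow(edges))) {
        vals[paste0("edge.", edges[k, 1L], ".", edges[k, 2L])] <-
          edgeFC(m, edges[k, ])
      }
    }
    data.frame(
      subject_id = subjectId(m), t(vals),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Long-format export of one segregation profile
#'
#' @param pr a [SegregationProfile-class].
#' @return data.frame with columns `subject_id`, `measure`, `value`;
#'   measures named `seg_global`, `seg:<net>`, `intra:<net>`,
#'   `inter:<netA>:<netB>`.
#' @export
profileLong <- function(pr) {
  stopifnot(is(pr, "SegregationProfile"))
  nets <- names(pr@seg)
  measure <- c(
    "zw_global", "zb_global", "seg_global",
    paste0("seg:", nets), paste0("intra:", nets)
  )
  value <- c(pr@zwGlobal, pr@zbGlobal, pr@segGlobal, pr@seg, pr@intra)
  for (i in seq_along(nets)) {
    for (j in seq_along(nets)) {
      if (i < j) {
        measure <- c(measure, paste0("inter:", nets[i], ":", nets[j]))
        value <- c(value, pr@inter[i, j])
      }
    }
  }
  data.frame(
    subject_id = pr@subjectId, measure = measure, value = unname(value),
    stringsAsFactors = FALSE
  )
}
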