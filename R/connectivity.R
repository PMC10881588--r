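#' @include AllClasses.R
NULL

#' Compute a Fisher-z functional connectivity matrix
#'
#' Pearson-correlates every pair of region time courses and applies the
#' Fisher r-to-z transform `atanh(r)`. Correlations of magnitude 1 (which
#' arise between affinely dependent columns, common in synthetic data)
#' would map to infinity, so |r| is clipped to `clip` first and a warning
#' is emitted. The result is exactly symmetric (upper triangle computed,
#' then mirrored) with a zero diagonal, and carries `prepared = FALSE`:
#' negative edges are retained until [prepareMatrix()].
#'
#' @param ts a [RoiTimeSeries-class].
#' @param clip magnitude bound applied to correlations before `atanh`;
#'   default `1 - 1e-7` (z of about 8.4).
#' @return An unprepared [ConnectivityMatrix-class].
#' @examples
#' ts <- roiTimeSeries("s1", cbind(a = rnorm(20), b = rnorm(20)))
#' computeFC(ts)
#' @export
computeFC <- function(ts, clip = 1 - 1e-7) {
  stopifnot(is(ts, "RoiTimeSeries"))
  validObject(ts)
  r <- stats::cor(ts@values)
  off <- row(r) != col(r)
  nclip <- sum(abs(r[off]) > clip)
  if (nclip > 0L) {
    warning(
      "clipped ", nclip / 2L, " correlation(s) of magnitude > ",
      format(clip), " before Fisher transform (subject ",
      ts@subjectId, ")"
    )
    r[off] <- pmin(pmax(r[off], -clip), clip)
  }
  z <- atanh(r)
  diag(z) <- 0
  # mirror the upper triangle so the result is exactly symmetric
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  connectivityMatrix(ts@subjectId, z, ts@regionIds, prepared = FALSE)
}

#' Prepare a connectivity matrix for segregation analysis
#'
#' Sets all diagonal elements and all negative entries to zero, leaving
#' positive entries untouched. Zeroed edges remain in every subsequent
#' mean as values of 0 (they are not treated as missing). Idempotent.
#'
#' @param m a [ConnectivityMatrix-class].
#' @return The matrix with `prepared = TRUE`.
#' @export
prepareMatrix <- function(m) {
  stopifnot(is(m, "ConnectivityMatrix"))
  z <- m@z
  z[z < 0] <- 0
  diag(z) <- 0
  connectivityMatrix(m@subjectId, z, m@regionIds, prepared = TRUE)
}
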