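#' @include AllClasses.R
NULL

#' Canonical nine-network labels
#'
#' Network label set of the reference parcellation configuration, in
#' canonical order.
#'
#' @return Character vector of nine labels.
#' @export
networkLabels <- function() {
  c(
    "default", "control", "limbic", "salience_ventral_attention",
    "dorsal_attention", "somatomotor", "visual", "temporoparietal",
    "subcortical"
  )
}

# Region counts per network for the bundled reference partition.
# 112 cortical + 30 subcortical = 142 regions; the salience/ventral
# attention network has 22 regions, hence 22*21/2 = 231 region pairs.
.DEFAULT_SIZES <- c(
  default = 23L, control = 15L, limbic = 10L,
  salience_ventral_attention = 22L, dorsal_attention = 13L,
  somatomotor = 14L, visual = 12L, temporoparietal = 3L,
  subcortical = 30L
)

#' Reference 142-region, nine-network partition
#'
#' A synthetic stand-in for a 142-region whole-brain parcellation grouped
#' into nine functional networks (default, control, limbic,
#' salience/ventral attention, dorsal attention, somatomotor, visual,
#' temporoparietal, subcortical). Region identifiers are
#' `<network>_<index>`; the salience/ventral attention network has 22
#' regions (231 region pairs) and the subcortical network 30. Real
#' analyses supply their own partition via [networkPartition()] or
#' [readPartition()].
#'
#' @return A [NetworkPartition-class] with 142 regions.
#' @examples
#' p <- defaultPartition()
#' table(assignment(p))
#' @export
defaultPartition <- function() {
  labs <- rep(names(.DEFAULT_SIZES), .DEFAULT_SIZES)
  ids <- unlist(lapply(names(.DEFAULT_SIZES), function(nw) {
    sprintf("%s_%02d", nw, seq_len(.DEFAULT_SIZES[[nw]]))
  }))
  networkPartition(setNames(labs, ids), networks = names(.DEFAULT_SIZES))
}

#' Regions belonging to one network
#'
#' @param p a [NetworkPartition-class].
#' @param network a network label present in `networks(p)`.
#' @return Character vector of region identifiers, in assignment order.
#' @export
regionsOf <- function(p, network) {
  stopifnot(is(p, "NetworkPartition"))
  if (!network %in% p@networks) {
    stop("unknown network label: '", network, "'")
  }
  names(p@assignment)[p@assignment == network]
}

#' Enumerate the unordered region pairs of a network
#'
#' Returns every unordered pair of distinct regions in the network exactly
#' once, in deterministic lexicographic order by region identifier, so
#' that edge-level result tables are reproducible. An n-region network
#' yields n(n-1)/2 pairs.
#'
#' @param p a [NetworkPartition-class].
#' @param network a network label.
#' @return A two-column character matrix (`region_a`, `region_b`) with
#'   `region_a < region_b` lexicographically.
#' @examples
#' p <- defaultPartition()
#' nrow(networkPairs(p, "salience_ventral_attention")) # 231
#' @export
networkPairs <- function(p, network) {
  regions <- sort(regionsOf(p, network))
  n <- length(regions)
  if (n < 2L) {
    stop("network '", network, "' has fewer than 2 regions")
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- cbind(
    region_a = regions[idx[, "row"]],
    region_b = regions[idx[, "col"]]
  )
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}
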