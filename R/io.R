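#' @include AllClasses.R
NULL

.sepFor <- function(file) if (grepl("\\.csv$", file)) "," else "\t"

#' Read one subject's ROI time series from delimited text
#'
#' Expected layout: header row of region identifiers, one row per
#' timepoint, tab- (.tsv) or comma- (.csv) separated.
#'
#' @param file path to the file.
#' @param subjectId subject identifier; defaults to the file name minus
#'   its extension.
#' @return A [RoiTimeSeries-class].
#' @export
readTimeSeries <- function(file,
                           subjectId = sub("\\.[^.]*$", "", basename(file))) {
  d <- utils::read.delim(file, sep = .sepFor(file), check.names = FALSE)
  roiTimeSeries(subjectId, as.matrix(d), colnames(d))
}

#' Write one subject's ROI time series
#'
#' @param ts a [RoiTimeSeries-class].
#' @param file destination path (.tsv or .csv).
#' @export
writeTimeSeries <- function(ts, file) {
  stopifnot(is(ts, "RoiTimeSeries"))
  d <- as.data.frame(ts@values)
  colnames(d) <- ts@regionIds
  utils::write.table(d, file,
    sep = .sepFor(file), row.names = FALSE, quote = FALSE
  )
}

#' Write a connectivity matrix as delimited text
#'
#' Writes the R x R Fisher-z matrix with a header row and a leading
#' `region_id` index column. Values are formatted at 17 significant
#' digits so that write/read round-trips are bit-stable.
#'
#' @param m a [ConnectivityMatrix-class].
#' @param file destination path.
#' @export
writeConnectivityMatrix <- function(m, file) {
  stopifnot(is(m, "ConnectivityMatrix"))
  z <- m@z
  txt <- apply(z, 2L, function(col) formatC(col, digits = 17, format = "g"))
  d <- data.frame(region_id = m@regionIds, txt,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(d) <- c("region_id", m@regionIds)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a connectivity matrix written by [writeConnectivityMatrix()]
#'
#' @param file path to the file.
#' @param subjectId subject identifier; defaults to the file name minus
#'   its extension.
#' @param prepared whether the stored matrix had been prepared.
#' @return A [ConnectivityMatrix-class].
#' @export
readConnectivityMatrix <- function(file,
                                   subjectId = sub("\\.[^.]*$", "",
                                     basename(file)),
                                   prepared = FALSE) {
  d <- utils::read.delim(file, sep = "\t", check.names = FALSE)
  ids <- as.character(d[[1L]])
  z <- as.matrix(d[, -1L, drop = FALSE])
  dimnames(z) <- list(ids, ids)
  # symmetrize away decimal-text parsing asymmetries below tolerance
  z <- (z + t(z)) / 2
  connectivityMatrix(subjectId, z, ids, prepared = prepared)
}

#' Read a region-to-network partition from two-column TSV
#'
#' @param file TSV with columns `region_id` and `network`.
#' @param networks optional canonical network order; defaults to first
#'   appearance.
#' @return A [NetworkPartition-class].
#' @export
readPartition <- function(file, networks = NULL) {
  d <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  networkPartition(
    setNames(as.character(d[[2L]]), as.character(d[[1L]])),
    networks = networks
  )
}

#' Write a partition as two-column TSV
#'
#' @param p a [NetworkPartition-class].
#' @param file destination path.
#' @export
writePartition <- function(p, file) {
  stopifnot(is(p, "NetworkPartition"))
  utils::write.table(
    data.frame(
      region_id = names(p@assignment), network = unname(p@assignment)
    ),
    file, sep = "\t", row.names = FALSE, quote = FALSE
  )
}

#' Read a test-battery configuration from flat key-value text
#'
#' One line per test: `test: domain, higher` or `test: domain, lower`
#' (whether larger raw scores mean better performance). Blank lines and
#' `#` comments are ignored.
#'
#' @param file path to the battery file.
#' @return data.frame with columns `test`, `domain`, `higher_is_better`.
#' @export
readBattery <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[:,]")
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) != 3L || !p[3L] %in% c("higher", "lower")) {
      stop("malformed battery line: expected 'test: domain, higher|lower'")
    }
    data.frame(
      test = p[1L], domain = p[2L],
      higher_is_better = p[3L] == "higher",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a test-battery configuration
#'
#' @param battery data.frame as from [defaultBattery()].
#' @param file destination path.
#' @export
writeBattery <- function(battery, file) {
  writeLines(
    sprintf(
      "%s: %s, %s", battery$test, battery$domain,
      ifelse(battery$higher_is_better, "higher", "lower")
    ),
    file
  )
}
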