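#' @include AllClasses.R
NULL

#' Overall handgrip strength from repeated dynamometer trials
#'
#' Takes the best (maximum) reading of each hand, then averages the two
#' per-hand maxima. This is the standard scoring for repeated dynamometer
#' trials (typically two per hand, in kg).
#'
#' @param left,right numeric vectors of kg readings, at least one per
#'   hand, all positive.
#' @return Overall handgrip strength in kg.
#' @examples
#' handgripScore(c(20.0, 21.5), c(19.0, 22.0)) # 21.75
#' @export
handgripScore <- function(left, right) {
  for (h in list(left = left, right = right)) {
    if (length(h) < 1L || anyNA(h)) {
      stop("each hand needs at least one non-missing reading")
    }
    if (any(h <= 0)) stop("handgrip readings must be positive")
  }
  mean(c(max(left), max(right)))
}

#' T-score a raw test variable across a sample
#'
#' Z-transforms the scores with the sample mean and standard deviation,
#' then maps to T-scores (mean 50, SD 10). For tests where larger raw
#' values mean worse performance (e.g. completion times), set
#' `higherIsBetter = FALSE`: the z-score is sign-flipped before scaling
#' so that higher T always means better performance.
#'
#' @param raw numeric vector of raw scores across subjects (length >= 2).
#' @param higherIsBetter direction flag, default `TRUE`.
#' @param name test name used in error messages.
#' @return Numeric vector of T-scores with sample mean 50 and SD 10.
#' @examples
#' tScore(c(1, 2, 3))
#' @export
tScore <- function(raw, higherIsBetter = TRUE, name = "test") {
  if (length(raw) < 2L || anyNA(raw)) {
    stop("T-scoring '", name, "' needs >= 2 non-missing scores")
  }
  s <- stats::sd(raw)
  if (s == 0) {
    stop("T-scoring '", name, "' impossible: zero standard deviation")
  }
  z <- (raw - mean(raw)) / s
  if (!isTRUE(higherIsBetter)) z <- -z
  50 + 10 * z
}

#' The bundled cognitive test battery configuration
#'
#' Eight tests over three domains, with a direction flag per test. Timed
#' tests (trail-making A and B) have `higher_is_better = FALSE` so that
#' longer completion times lower the T-score; the flag is user-overridable
#' by supplying a different battery data.frame.
#'
#' @return data.frame with columns `test`, `domain`
#'   (attention / processing_speed / executive_function) and
#'   `higher_is_better`.
#' @export
defaultBattery <- function() {
  data.frame(
    test = c(
      "digit_span", "spatial_span",
      "symbol_digit", "symbol_search", "trail_making_a",
      "verbal_fluency", "design_fluency", "trail_making_b"
    ),
    domain = c(
      "attention", "attention",
      "processing_speed", "processing_speed", "processing_speed",
      "executive_function", "executive_function", "executive_function"
    ),
    higher_is_better = c(
      TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

#' Domain composites and global cognition from per-test T-scores
#'
#' Each domain composite is the arithmetic mean of its tests' T-scores;
#' global cognition is the mean of the three domain composites.
#'
#' @param tscores numeric matrix or data.frame, subjects x tests, columns
#'   named by test.
#' @param battery battery data.frame as from [defaultBattery()]; only
#'   `test` and `domain` are used here.
#' @return data.frame with one column per domain plus `global`.
#' @export
cognitiveComposites <- function(tscores, battery = defaultBattery()) {
  tscores <- as.matrix(tscores)
  domains <- unique(battery$domain)
  missing <- setdiff(battery$test, colnames(tscores))
  if (length(missing)) {
    stop("no T-scores for test(s): ", paste(missing, collapse = ", "))
  }
  comp <- as.data.frame(setNames(lapply(domains, function(d) {
    tests <- battery$test[battery$domain == d]
    if (length(tests) == 0L) stop("domain '", d, "' has no tests")
    rowMeans(tscores[, tests, drop = FALSE])
  }), domains))
  comp$global <- rowMeans(comp[, domains, drop = FALSE])
  comp
}

#' Score a raw phenotype table into cognitive T-scores and composites
#'
#' T-scores every battery test across the sample (respecting direction
#' flags), forms domain composites and global cognition, and carries the
#' SM-MMSE through untouched (it is analyzed on its raw scale, so its
#' regression coefficients are not comparable to the T-scored outcomes).
#'
#' @param phenotypes data.frame with one row per subject containing a
#'   `subject_id` column, raw columns named for every battery test, and
#'   optionally `smmse`.
#' @param battery battery data.frame as from [defaultBattery()].
#' @return data.frame: `subject_id`, per-test T-score columns
#'   (`t.<test>`), `attention`, `processing_speed`, `executive_function`,
#'   `global`, and `smmse` when present.
#' @export
scoreCognition <- function(phenotypes, battery = defaultBattery()) {
  stopifnot("subject_id" %in% names(phenotypes))
  missing <- setdiff(battery$test, names(phenotypes))
  if (length(missing)) {
    stop("phenotype table lacks test(s): ", paste(missing, collapse = ", "))
  }
  tmat <- sapply(seq_len(nrow(battery)), function(i) {
    tScore(phenotypes[[battery$test[i]]],
      higherIsBetter = battery$higher_is_better[i],
      name = battery$test[i]
    )
  })
  colnames(tmat) <- battery$test
  comp <- cognitiveComposites(tmat, battery)
  out <- data.frame(
    subject_id = phenotypes$subject_id,
    setNames(as.data.frame(tmat), paste0("t.", colnames(tmat))),
    comp,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if ("smmse" %in% names(phenotypes)) out$smmse <- phenotypes$smmse
  out
}
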