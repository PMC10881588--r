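#' @include AllClasses.R
NULL

#' SyntheticCohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a cohort with the statistical structure the analysis
#' pipeline assumes: subject-varying block-structured ROI correlation
#' (within-network correlation `w_i`, between-network `b_i`), a latent
#' per-subject segregation on the Fisher-z scale,
#' `s_i = 1 - atanh(b_i) / atanh(w_i)`, and linear couplings from
#' segregation to handgrip strength (slope `alpha1`) and from handgrip
#' (and optionally segregation directly, `beta2`) to a latent cognition
#' factor that drives all battery test scores. Defaults emulate a
#' community cohort of older adults: n = 148, 142 regions in nine
#' networks, 235 timepoints, handgrip 22.3 (SD 7.0) kg, age 72.8 (3.9)
#' years, education 7.28 (3.97) years, 83 female / 65 male.
#'
#' `alpha1` and `beta1` default to NA, which means "calibrate": the
#' constructor solves for the slope that yields the target
#' covariate-adjusted partial correlation (`targetPartialR` for
#' handgrip-segregation, default 0.27; `targetPartialRCog` for
#' handgrip-cognition, default 0.26) given the noise SDs, using
#' deterministic quadrature over the truncated-normal correlation
#' distributions — no randomness is involved in calibration.
#'
#' @seealso [syntheticCohortSpec()], [generateCohort()],
#'   [generateMatrices()].
#' @export
setClass("SyntheticCohortSpec",
  representation(
    nSubjects = "integer", timepoints = "integer",
    partition = "NetworkPartition",
    withinMean = "numeric", withinSd = "numeric", withinBounds = "numeric",
    betweenMean = "numeric", betweenSd = "numeric",
    betweenBounds = "numeric",
    alpha0 = "numeric", alpha1 = "numeric", targetPartialR = "numeric",
    beta1 = "numeric", beta2 = "numeric", targetPartialRCog = "numeric",
    noiseSdHandgrip = "numeric", noiseSdCognition = "numeric",
    testNoiseSd = "numeric",
    ageMean = "numeric", ageSd = "numeric", pMale = "numeric",
    eduMean = "numeric", eduSd = "numeric",
    ticvMean = "numeric", ticvSd = "numeric",
    sexLoadHandgrip = "numeric", ageLoadHandgrip = "numeric",
    eduLoadHandgrip = "numeric", ticvLoadHandgrip = "numeric",
    ageLoadCognition = "numeric", eduLoadCognition = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticCohortSpec", function(object) {
  msgs <- character()
  if (object@nSubjects < 2L) msgs <- c(msgs, "need >= 2 subjects")
  if (object@timepoints < 3L) msgs <- c(msgs, "need >= 3 timepoints")
  wb <- object@withinBounds
  bb <- object@betweenBounds
  if (!(0 < wb[1L] && wb[1L] < wb[2L] && wb[2L] < 1)) {
    msgs <- c(msgs, "within-correlation bounds must satisfy 0 < lo < hi < 1")
  }
  if (!(0 <= bb[1L] && bb[1L] < bb[2L])) {
    msgs <- c(msgs, "between-correlation bounds must satisfy 0 <= lo < hi")
  }
  if (bb[2L] >= wb[1L]) {
    msgs <- c(msgs, paste0(
      "between-correlation upper bound (", bb[2L],
      ") must stay below the within-correlation lower bound (", wb[1L],
      ") so every block matrix is positive definite"
    ))
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msgs <- c(msgs, "a seed is mandatory")
  }
  if (length(msgs)) msgs else TRUE
})

# nodes and weights of a truncated normal on [lo, hi] (midpoint rule on a
# fine grid; deterministic, used only for slope calibration)
.truncNormGrid <- function(mean, sd, lo, hi, n = 400L) {
  edges <- seq(lo, hi, length.out = n + 1L)
  x <- (edges[-1L] + edges[-(n + 1L)]) / 2
  w <- stats::dnorm(x, mean, sd) * diff(edges)
  list(x = x, w = w / sum(w))
}

# mean and sd of the latent segregation s = 1 - atanh(b)/atanh(w) under
# independent truncated-normal draws of w and b
.latentSegStats <- function(spec) {
  gw <- .truncNormGrid(
    spec@withinMean, spec@withinSd,
    spec@withinBounds[1L], spec@withinBounds[2L]
  )
  gb <- .truncNormGrid(
    spec@betweenMean, spec@betweenSd,
    spec@betweenBounds[1L], spec@betweenBounds[2L]
  )
  s <- outer(atanh(gw$x), atanh(gb$x), function(zw, zb) 1 - zb / zw)
  wts <- outer(gw$w, gb$w)
  m1 <- sum(s * wts)
  m2 <- sum(s^2 * wts)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Moments of the latent segregation distribution of a spec
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return Named vector `c(mean =, sd =)` of the latent per-subject
#'   segregation implied by the spec's correlation distributions
#'   (deterministic quadrature, no simulation).
#' @export
latentSegregationStats <- function(spec) .latentSegStats(spec)

# slope giving partial correlation r when the predictor's adjusted SD is
# sdX and the residual noise SD is sdNoise
.slopeForPartialR <- function(r, sdX, sdNoise) {
  if (r == 0) return(0)
  (r / sqrt(1 - r^2)) * sdNoise / sdX
}

#' Construct a synthetic cohort specification
#'
#' All arguments have defaults fixed at the emulated study conditions
#' (see [SyntheticCohortSpec-class]); only `seed` is mandatory.
#'
#' @param nSubjects cohort size (default 148).
#' @param timepoints timepoints per subject (default 235, an 8-minute
#'   2-second-TR scan minus 5 discarded volumes).
#' @param partition a [NetworkPartition-class]
#'   (default [defaultPartition()], 142 regions / 9 networks).
#' @param withinMean,withinSd,withinBounds truncated-normal distribution
#'   of the within-network Pearson correlation `w_i`
#'   (defaults 0.6, 0.08, \[0.35, 0.85\]).
#' @param betweenMean,betweenSd,betweenBounds distribution of the
#'   between-network correlation `b_i`
#'   (defaults 0.2, 0.05, \[0.02, 0.34\]); the upper bound must stay
#'   below the within lower bound so every block matrix is positive
#'   definite.
#' @param alpha0 expected handgrip (kg) at mean covariates and mean
#'   latent segregation (default 22.3).
#' @param alpha1 segregation-to-handgrip slope, kg per segregation unit;
#'   `NA` (default) calibrates it to `targetPartialR`.
#' @param targetPartialR target covariate-adjusted handgrip-segregation
#'   partial correlation used when `alpha1` is NA (default 0.27; 0
#'   disables the coupling).
#' @param beta1 handgrip-to-cognition slope (latent cognition units per
#'   kg); `NA` calibrates to `targetPartialRCog` (default 0.26).
#' @param beta2 direct segregation-to-cognition slope (default 0).
#' @param targetPartialRCog see `beta1`.
#' @param noiseSdHandgrip handgrip noise SD in kg (default 5.4, chosen so
#'   the total handgrip SD is about 7 kg given the covariate loadings).
#' @param noiseSdCognition latent-cognition noise SD (default 0.84).
#' @param testNoiseSd per-test unique noise SD on the latent scale
#'   (default 0.8).
#' @param ageMean,ageSd,pMale,eduMean,eduSd,ticvMean,ticvSd covariate
#'   generators: age (years), sex (Bernoulli male indicator), education
#'   (years), intracranial volume (mm^3).
#' @param sexLoadHandgrip,ageLoadHandgrip,eduLoadHandgrip,ticvLoadHandgrip
#'   covariate loadings on handgrip (kg per unit).
#' @param ageLoadCognition,eduLoadCognition covariate loadings on latent
#'   cognition.
#' @param seed mandatory integer RNG seed.
#' @return A validated [SyntheticCohortSpec-class].
#' @examples
#' spec <- syntheticCohortSpec(nSubjects = 20, seed = 1)
#' latentSegregationStats(spec)
#' @export
syntheticCohortSpec <- function(nSubjects = 148, timepoints = 235,
                                partition = defaultPartition(),
                                withinMean = 0.6, withinSd = 0.08,
                                withinBounds = c(0.35, 0.85),
                                betweenMean = 0.2, betweenSd = 0.05,
                                betweenBounds = c(0.02, 0.34),
                                alpha0 = 22.3, alpha1 = NA_real_,
                                targetPartialR = 0.27,
                                beta1 = NA_real_, beta2 = 0,
                                targetPartialRCog = 0.26,
                                noiseSdHandgrip = 5.4,
                                noiseSdCognition = 0.84,
                                testNoiseSd = 0.8,
                                ageMean = 72.8, ageSd = 3.9,
                                pMale = 65 / 148,
                                eduMean = 7.28, eduSd = 3.97,
                                ticvMean = 1.4e6, ticvSd = 1.3e5,
                                sexLoadHandgrip = 8,
                                ageLoadHandgrip = -0.25,
                                eduLoadHandgrip = 0.1,
                                ticvLoadHandgrip = 5e-6,
                                ageLoadCognition = -0.04,
                                eduLoadCognition = 0.05,
                                seed) {
  if (missing(seed)) stop("a seed is mandatory")
  spec <- new("SyntheticCohortSpec",
    nSubjects = as.integer(nSubjects),
    timepoints = as.integer(timepoints),
    partition = partition,
    withinMean = withinMean, withinSd = withinSd,
    withinBounds = withinBounds,
    betweenMean = betweenMean, betweenSd = betweenSd,
    betweenBounds = betweenBounds,
    alpha0 = alpha0, alpha1 = alpha1, targetPartialR = targetPartialR,
    beta1 = beta1, beta2 = beta2, targetPartialRCog = targetPartialRCog,
    noiseSdHandgrip = noiseSdHandgrip,
    noiseSdCognition = noiseSdCognition, testNoiseSd = testNoiseSd,
    ageMean = ageMean, ageSd = ageSd, pMale = pMale,
    eduMean = eduMean, eduSd = eduSd,
    ticvMean = ticvMean, ticvSd = ticvSd,
    sexLoadHandgrip = sexLoadHandgrip,
    ageLoadHandgrip = ageLoadHandgrip,
    eduLoadHandgrip = eduLoadHandgrip,
    ticvLoadHandgrip = ticvLoadHandgrip,
    ageLoadCognition = ageLoadCognition,
    eduLoadCognition = eduLoadCognition,
    seed = as.integer(seed)
  )
  validObject(spec)
  spec
}

#' Calibrated phenotype slopes of a spec
#'
#' Resolves the `alpha1` (segregation -> handgrip) and `beta1`
#' (handgrip -> cognition) slopes a spec will use: values given
#' explicitly are returned as is; NA values are replaced by the slope
#' that produces the spec's target partial correlation.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return Named numeric vector `c(alpha1 =, beta1 =)`.
#' @export
resolvedSlopes <- function(spec) {
  segStats <- .latentSegStats(spec)
  alpha1 <- spec@alpha1
  if (is.na(alpha1)) {
    alpha1 <- .slopeForPartialR(
      spec@targetPartialR, segStats[["sd"]], spec@noiseSdHandgrip
    )
  }
  beta1 <- spec@beta1
  if (is.na(beta1)) {
    # handgrip SD net of covariates: coupling signal + handgrip noise
    sdHgAdj <- sqrt(
      (alpha1 * segStats[["sd"]])^2 + spec@noiseSdHandgrip^2
    )
    beta1 <- .slopeForPartialR(
      spec@targetPartialRCog, sdHgAdj, spec@noiseSdCognition
    )
  }
  c(alpha1 = alpha1, beta1 = beta1)
}

# inverse-CDF truncated normal draws (fixed number of uniforms, so the
# RNG stream is identical across generator variants)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Latent draws + phenotype assembly shared by generateCohort() and
# generateMatrices(). Consumes a fixed-length RNG prefix so both
# generators agree on every latent and phenotype under the same seed.
.drawLatents <- function(spec) {
  n <- spec@nSubjects
  slopes <- resolvedSlopes(spec)
  segStats <- .latentSegStats(spec)

  set.seed(spec@seed)
  w <- .rtruncnorm(
    n, spec@withinMean, spec@withinSd,
    spec@withinBounds[1L], spec@withinBounds[2L]
  )
  b <- .rtruncnorm(
    n, spec@betweenMean, spec@betweenSd,
    spec@betweenBounds[1L], spec@betweenBounds[2L]
  )
  s <- 1 - atanh(b) / atanh(w)

  age <- stats::rnorm(n, spec@ageMean, spec@ageSd)
  sex <- stats::rbinom(n, 1L, spec@pMale) # 0 = female, 1 = male
  edu <- pmin(pmax(stats::rnorm(n, spec@eduMean, spec@eduSd), 0), 23)
  ticv <- stats::rnorm(n, spec@ticvMean, spec@ticvSd)
  gmv <- 0.4 * ticv + stats::rnorm(n, 0, 3e4)
  gds <- pmax(round(stats::rnorm(n, 2.33, 2.46)), 0)
  bmi <- stats::rnorm(n, 23.0, 3.4)
  whr <- stats::rnorm(n, 0.917, 0.068)
  scanInterval <- round(stats::rnorm(n, 276.6, 156.6))

  handgrip <- spec@alpha0 +
    slopes[["alpha1"]] * (s - segStats[["mean"]]) +
    spec@sexLoadHandgrip * (sex - spec@pMale) +
    spec@ageLoadHandgrip * (age - spec@ageMean) +
    spec@eduLoadHandgrip * (edu - spec@eduMean) +
    spec@ticvLoadHandgrip * (ticv - spec@ticvMean) +
    stats::rnorm(n, 0, spec@noiseSdHandgrip)
  handgrip <- pmax(handgrip, 1) # dynamometer readings are positive

  # dynamometer trials: two per hand; the per-hand maximum and the
  # left/right average reconstruct the scored handgrip value
  handGap <- abs(stats::rnorm(n, 0, 0.8))
  trialDropL <- stats::runif(n, 0.2, 1.5)
  trialDropR <- stats::runif(n, 0.2, 1.5)
  leftBest <- pmax(handgrip - handGap, 0.5)
  rightBest <- pmax(handgrip + handGap, 0.5)
  handgrip <- (leftBest + rightBest) / 2

  g <- slopes[["beta1"]] * (handgrip - spec@alpha0) +
    spec@beta2 * (s - segStats[["mean"]]) +
    spec@ageLoadCognition * (age - spec@ageMean) +
    spec@eduLoadCognition * (edu - spec@eduMean) +
    stats::rnorm(n, 0, spec@noiseSdCognition)

  battery <- defaultBattery()
  # raw-score anchors per test: center, scale (latent units -> raw units)
  anchors <- list(
    digit_span = c(16, 3), spatial_span = c(14, 3),
    symbol_digit = c(35, 8), symbol_search = c(20, 5),
    trail_making_a = c(60, 15), verbal_fluency = c(35, 8),
    design_fluency = c(18, 5), trail_making_b = c(150, 40)
  )
  tests <- lapply(seq_len(nrow(battery)), function(i) {
    a <- anchors[[battery$test[i]]]
    signal <- g + stats::rnorm(n, 0, spec@testNoiseSd)
    if (battery$higher_is_better[i]) {
      a[1L] + a[2L] * signal
    } else {
      a[1L] - a[2L] * signal # timed tests: better cognition, shorter time
    }
  })
  names(tests) <- battery$test
  smmse <- pmin(pmax(round(26.4 + 1.5 * g), 0), 30)

  # zero-padded to the cohort's width so lexicographic order equals
  # numeric order in file listings and merges
  ids <- sprintf(paste0("sub%0", max(3L, nchar(n)), "d"), seq_len(n))
  phenotypes <- data.frame(
    subject_id = ids,
    grip_left_1 = pmax(leftBest - trialDropL, 0.1),
    grip_left_2 = leftBest,
    grip_right_1 = pmax(rightBest - trialDropR, 0.1),
    grip_right_2 = rightBest,
    handgrip = handgrip,
    age = age, sex = sex, education = edu, ticv = ticv, gmv = gmv,
    gds = gds, bmi = bmi, whr = whr, scan_interval = scanInterval,
    smmse = smmse,
    as.data.frame(tests),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    subject_id = ids, within_r = w, between_r = b,
    seg_latent = s, cognition_latent = g,
    alpha1 = slopes[["alpha1"]], beta1 = slopes[["beta1"]],
    beta2 = spec@beta2,
    stringsAsFactors = FALSE
  )
  list(phenotypes = phenotypes, truth = truth, w = w, b = b, ids = ids)
}

# block correlation matrix: within-network off-diagonals w, between b
.blockCorrelation <- function(w, b, membership) {
  sameNet <- outer(membership, membership, "==")
  C <- ifelse(sameNet, w, b)
  diag(C) <- 1
  C
}

#' Generate only the phenotype table and latent truth of a cohort
#'
#' The latent and phenotype component shared by [generateCohort()] and
#' [generateMatrices()]: per-subject correlation pair, latent
#' segregation, covariates, handgrip trials and raw test scores, without
#' constructing matrices or time series. Identical draws to the other
#' two generators under the same seed; intended for replicate simulation
#' studies where the connectivity stage has been validated separately
#' (the exact-matrix segregation profile equals `seg_latent` by
#' construction).
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return List with `phenotypes` and `truth` as in [generateCohort()].
#' @export
generatePhenotypes <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  lat <- .drawLatents(spec)
  list(phenotypes = lat$phenotypes, truth = lat$truth)
}

#' Generate a full synthetic cohort
#'
#' Draws, per subject, a within/between correlation pair `(w_i, b_i)`,
#' builds the block-structured ROI correlation matrix, samples `T`
#' multivariate-normal timepoints, and assembles a phenotype table whose
#' handgrip and cognitive scores are linearly coupled to the latent
#' segregation `s_i = 1 - atanh(b_i)/atanh(w_i)` per the spec's slopes.
#' Fully reproducible: the same spec (including seed) gives
#' byte-identical output, and the latent/phenotype draws are shared with
#' [generateMatrices()] under the same seed.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return List with `timeSeries` (list of [RoiTimeSeries-class]),
#'   `phenotypes` (data.frame, one row per subject: dynamometer trials,
#'   scored handgrip, covariates, raw test scores, SM-MMSE) and `truth`
#'   (data.frame of latent values and resolved slopes).
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  lat <- .drawLatents(spec)
  membership <- spec@partition@assignment
  ids <- names(membership)
  tsList <- vector("list", spec@nSubjects)
  for (i in seq_len(spec@nSubjects)) {
    C <- .blockCorrelation(lat$w[i], lat$b[i], membership)
    U <- tryCatch(chol(C), error = function(e) {
      stop(
        "correlation matrix not positive definite for subject ",
        lat$ids[i], " (w = ", format(lat$w[i]), ", b = ",
        format(lat$b[i]), ")"
      )
    })
    X <- matrix(
      stats::rnorm(spec@timepoints * length(ids)),
      spec@timepoints, length(ids)
    ) %*% U
    colnames(X) <- ids
    tsList[[i]] <- roiTimeSeries(lat$ids[i], X, ids)
  }
  names(tsList) <- lat$ids
  list(timeSeries = tsList, phenotypes = lat$phenotypes, truth = lat$truth)
}

#' Generate exact (noise-free) connectivity matrices
#'
#' Shortcut that skips time-series sampling and emits, per subject, the
#' prepared Fisher-z matrix implied directly by `(w_i, b_i)`: within-
#' network edges `atanh(w_i)`, between-network edges `atanh(b_i)`, zero
#' diagonal. The subject's segregation profile on this matrix equals the
#' latent closed form exactly, which makes these matrices the fast,
#' deterministic route for calibration and simulation studies. Latents
#' and phenotypes are drawn identically to [generateCohort()] under the
#' same seed.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return List with `matrices` (list of prepared
#'   [ConnectivityMatrix-class]), `phenotypes` and `truth` as in
#'   [generateCohort()].
#' @examples
#' spec <- syntheticCohortSpec(nSubjects = 3, seed = 42)
#' out <- generateMatrices(spec)
#' profileSubject(out$matrices[[1]], defaultPartition())
#' @export
generateMatrices <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  lat <- .drawLatents(spec)
  membership <- spec@partition@assignment
  ids <- names(membership)
  sameNet <- outer(membership, membership, "==")
  mats <- vector("list", spec@nSubjects)
  for (i in seq_len(spec@nSubjects)) {
    z <- ifelse(sameNet, atanh(lat$w[i]), atanh(lat$b[i]))
    diag(z) <- 0
    dimnames(z) <- list(ids, ids)
    mats[[i]] <- connectivityMatrix(lat$ids[i], z, ids, prepared = TRUE)
  }
  names(mats) <- lat$ids
  list(matrices = mats, phenotypes = lat$phenotypes, truth = lat$truth)
}
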