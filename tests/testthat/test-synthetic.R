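test_that("identical spec and seed give byte-identical cohorts", {
  p <- small_partition()
  spec <- syntheticCohortSpec(
    nSubjects = 5, timepoints = 30, partition = p, seed = 77
  )
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth, c2$truth)
  expect_identical(
    lapply(c1$timeSeries, function(t) t@values),
    lapply(c2$timeSeries, function(t) t@values)
  )
  # and a different seed changes the draws
  c3 <- generateCohort(syntheticCohortSpec(
    nSubjects = 5, timepoints = 30, partition = p, seed = 78
  ))
  expect_false(identical(c1$phenotypes$handgrip, c3$phenotypes$handgrip))
})

test_that("matrix shortcut and full cohort share latents under one seed", {
  p <- small_partition()
  spec <- syntheticCohortSpec(
    nSubjects = 6, timepoints = 25, partition = p, seed = 11
  )
  co <- generateCohort(spec)
  mx <- generateMatrices(spec)
  ph <- generatePhenotypes(spec)
  expect_identical(co$phenotypes, mx$phenotypes)
  expect_identical(co$truth, mx$truth)
  expect_identical(co$phenotypes, ph$phenotypes)
})

test_that("exact matrices realize the latent segregation in closed form", {
  p <- small_partition()
  spec <- syntheticCohortSpec(nSubjects = 8, partition = p, seed = 21)
  out <- generateMatrices(spec)
  profs <- profileTable(out$matrices, p)
  expect_equal(profs$seg_global, out$truth$seg_latent, tolerance = 1e-12)
  # uniform blocks: every network-level segregation equals the global one
  for (nw in networkLabels()) {
    expect_equal(profs[[paste0("seg.", nw)]], profs$seg_global,
      tolerance = 1e-12
    )
  }
  # closed form: seg = 1 - atanh(b)/atanh(w)
  expect_equal(
    profs$seg_global,
    1 - atanh(out$truth$between_r) / atanh(out$truth$within_r),
    tolerance = 1e-12
  )
})

test_that("permuting region labels leaves the profile unchanged", {
  p <- small_partition()
  spec <- syntheticCohortSpec(nSubjects = 2, partition = p, seed = 31)
  m <- generateMatrices(spec)$matrices[[1]]
  perm <- sample(length(regionIds(m)))
  m2 <- connectivityMatrix(
    subjectId(m), zMatrix(m)[perm, perm],
    regionIds(m)[perm], prepared = TRUE
  )
  pr1 <- profileSubject(m, p)
  pr2 <- profileSubject(m2, p)
  expect_equal(pr1@seg, pr2@seg, tolerance = 1e-14)
  expect_equal(pr1@inter, pr2@inter, tolerance = 1e-14)
})

test_that("random specs agree with the pair-enumeration oracle", {
  set.seed(601)
  p <- two_block_partition(c(A = 4, B = 5))
  for (rep in 1:5) {
    spec <- syntheticCohortSpec(
      nSubjects = 2, partition = p, seed = 600 + rep,
      withinMean = runif(1, 0.5, 0.7), betweenMean = runif(1, 0.1, 0.3)
    )
    m <- generateMatrices(spec)$matrices[[1]]
    pr <- profileSubject(m, p)
    orc <- oracle_profile(zMatrix(m), assignment(p), networks(p))
    expect_equal(pr@segGlobal, orc$segGlobal, tolerance = 1e-12)
    expect_equal(pr@seg, orc$seg, tolerance = 1e-12)
  }
})

test_that("vanishing between-network correlation drives segregation to 1", {
  p <- two_block_partition(c(A = 4, B = 4))
  gap <- function(T) {
    spec <- syntheticCohortSpec(
      nSubjects = 4, timepoints = T, partition = p,
      betweenMean = 0, betweenSd = 1e-7, betweenBounds = c(0, 1e-6),
      seed = 41
    )
    co <- generateCohort(spec)
    segs <- vapply(co$timeSeries, function(ts) {
      profileSubject(
        prepareMatrix(computeFC(ts)), p
      )@segGlobal
    }, numeric(1))
    mean(abs(segs - 1))
  }
  gSmall <- gap(60)
  gLarge <- gap(1500)
  expect_lt(gLarge, gSmall) # gap shrinks as T grows
  expect_lt(gLarge, 0.05)
})

test_that("slope calibration hits the requested partial correlation", {
  p <- small_partition()
  spec <- syntheticCohortSpec(
    nSubjects = 5000, partition = p, targetPartialR = 0.27, seed = 51
  )
  out <- generatePhenotypes(spec)
  d <- cbind(out$phenotypes, seg = out$truth$seg_latent)
  res <- fitOLS(
    d, "handgrip", "seg", c("age", "sex", "education", "ticv")
  )
  # recovered slope close to the programmed one
  alpha1 <- out$truth$alpha1[1]
  expect_gt(alpha1, 0)
  expect_lt(abs(res$coefficient - alpha1) / alpha1, 0.15)
  # realized partial correlation near the 0.27 target
  rPartial <- res$t / sqrt(res$t^2 + res$df)
  expect_equal(rPartial, 0.27, tolerance = 0.035)
})

test_that("null couplings produce no handgrip-segregation association", {
  p <- small_partition()
  spec <- syntheticCohortSpec(
    nSubjects = 5000, partition = p,
    targetPartialR = 0, targetPartialRCog = 0, seed = 61
  )
  out <- generatePhenotypes(spec)
  expect_identical(out$truth$alpha1[1], 0)
  d <- cbind(out$phenotypes, seg = out$truth$seg_latent)
  res <- fitOLS(d, "handgrip", "seg", c("age", "sex", "education", "ticv"))
  rPartial <- res$t / sqrt(res$t^2 + res$df)
  expect_lt(abs(rPartial), 0.05)
})

test_that("default-strength signal is detected after FDR in most cohorts", {
  # one cohort profiled through the full connectivity path, equal to the
  # latent closed form (checked above); replicates then use the fast
  # latent route
  reps <- 200
  hits <- logical(reps)
  segCols <- paste0("seg.", networkLabels())
  p <- small_partition()
  for (r in seq_len(reps)) {
    spec <- syntheticCohortSpec(
      nSubjects = 148, partition = p, seed = 7000 + r
    )
    out <- generatePhenotypes(spec)
    d <- out$phenotypes
    for (sc in segCols) d[[sc]] <- out$truth$seg_latent
    fam <- runFamily(
      d, segCols, "handgrip", c("age", "sex", "education", "ticv"),
      family = "segregation"
    )
    hits[r] <- fam$significant[
      fam$outcome == "seg.salience_ventral_attention"
    ]
  }
  expect_gte(mean(hits), 0.8)
})

test_that("invalid correlation configurations are rejected", {
  expect_error(
    syntheticCohortSpec(
      seed = 1, withinBounds = c(0.3, 0.6), betweenBounds = c(0.1, 0.5)
    ),
    "positive definite"
  )
  expect_error(
    syntheticCohortSpec(seed = 1, withinBounds = c(0.9, 0.4)),
    "lo < hi"
  )
  expect_error(syntheticCohortSpec(nSubjects = 5), "seed")
})
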