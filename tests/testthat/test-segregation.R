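test_that("constant two-block matrix gives the block means everywhere", {
  p <- two_block_partition(c(A = 2, B = 2))
  m <- block_matrix(p, zw = 0.6, zb = 0.2)
  for (scope in c("global", "A", "B")) {
    wb <- withinBetweenMeans(m, p, scope)
    expect_equal(unname(wb), c(0.6, 0.2))
  }
  pr <- profileSubject(m, p)
  expect_equal(pr@segGlobal, 2 / 3)
  expect_equal(unname(pr@seg), c(2 / 3, 2 / 3))
})

test_that("six-region two-network means match exhaustive enumeration", {
  p <- two_block_partition(c(A = 3, B = 3))
  ids <- regionIds(p)
  set.seed(201)
  z <- matrix(runif(36, 0, 1), 6, 6)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(ids, ids)
  m <- connectivityMatrix("s1", z, ids, prepared = TRUE)
  orc <- oracle_profile(z, assignment(p), networks(p))
  wbA <- withinBetweenMeans(m, p, "A")
  expect_equal(wbA[["zw"]], orc$zw[["A"]], tolerance = 1e-14)
  expect_equal(wbA[["zb"]], orc$zb[["A"]], tolerance = 1e-14)
  gl <- withinBetweenMeans(m, p, "global")
  expect_equal(gl[["zw"]], orc$zwGlobal, tolerance = 1e-14)
  expect_equal(gl[["zb"]], orc$zbGlobal, tolerance = 1e-14)
})

test_that("a zeroed negative edge contributes 0, not missing", {
  p <- two_block_partition(c(A = 3, B = 3))
  m <- block_matrix(p, zw = 0.6, zb = 0.2)
  z <- zMatrix(m)
  z["A1", "A2"] <- z["A2", "A1"] <- -0.4
  m2 <- prepareMatrix(connectivityMatrix("s1", z))
  wb <- withinBetweenMeans(m2, p, "A")
  # 3 within pairs: 0, 0.6, 0.6 -> mean 0.4 (the zeroed edge stays in)
  expect_equal(wb[["zw"]], 0.4)
})

test_that("segregation index handles its limit cases", {
  expect_equal(segregationIndex(0.5, 0), 1)
  expect_equal(segregationIndex(0.4, 0.4), 0)
  expect_equal(segregationIndex(0.6, 0.2), 2 / 3)
  expect_error(segregationIndex(0, 0.1, scope = "visual"), "visual")
})

test_that("an all-zero prepared matrix has undefined segregation", {
  p <- two_block_partition(c(A = 2, B = 2))
  m <- block_matrix(p, zw = 0, zb = 0)
  expect_error(profileSubject(m, p), "undefined")
})

test_that("networkPairs enumerates each unordered pair exactly once", {
  p <- defaultPartition()
  expect_identical(nrow(networkPairs(p, "salience_ventral_attention")), 231L)
  expect_identical(nrow(networkPairs(p, "temporoparietal")), 3L)

  p2 <- two_block_partition(c(A = 5, B = 2))
  pairs <- networkPairs(p2, "A")
  expect_identical(nrow(pairs), 10L)
  # double-loop oracle
  regs <- sort(regionsOf(p2, "A"))
  expected <- NULL
  for (i in seq_along(regs)) {
    for (j in seq_along(regs)) {
      if (i < j) expected <- rbind(expected, c(regs[i], regs[j]))
    }
  }
  expect_identical(unname(pairs), unname(expected))
  expect_true(all(pairs[, 1] < pairs[, 2])) # lexicographic within pair
  expect_identical(nrow(networkPairs(p2, "B")), 1L)
  expect_error(networkPairs(p2, "nope"), "unknown network")
})

test_that("edgeFC is a symmetric lookup honouring preparation", {
  p <- two_block_partition(c(A = 2, B = 2))
  z <- zMatrix(block_matrix(p, 0.3, 0.1))
  z["A1", "B1"] <- z["B1", "A1"] <- -0.2
  m <- prepareMatrix(connectivityMatrix("s1", z))
  expect_equal(edgeFC(m, c("A1", "A2")), 0.3)
  expect_equal(edgeFC(m, c("A1", "B1")), 0) # zeroed negative
  expect_equal(edgeFC(m, c("B1", "A1")), edgeFC(m, c("A1", "B1")))
  expect_error(edgeFC(m, c("A1", "Q9")), "unknown region")
})

test_that("profiles match the enumeration oracle on random matrices", {
  set.seed(202)
  for (rep in 1:40) {
    R <- sample(6:12, 1)
    k <- sample(2:3, 1)
    labs <- paste0("r", seq_len(R))
    p <- rand_partition(labs, k)
    m <- rand_prepared(R, labs)
    pr <- profileSubject(m, p)
    orc <- oracle_profile(zMatrix(m), assignment(p), networks(p))
    expect_equal(pr@zwGlobal, orc$zwGlobal, tolerance = 1e-10)
    expect_equal(pr@zbGlobal, orc$zbGlobal, tolerance = 1e-10)
    expect_equal(pr@segGlobal, orc$segGlobal, tolerance = 1e-10)
    expect_equal(pr@zw, orc$zw, tolerance = 1e-10)
    expect_equal(pr@zb, orc$zb, tolerance = 1e-10)
    expect_equal(pr@seg, orc$seg, tolerance = 1e-10)
    expect_equal(pr@intra, orc$zw, tolerance = 1e-10)
    expect_equal(pr@inter, orc$inter, tolerance = 1e-10)
  }
})

test_that("segregation is scale invariant; means scale linearly", {
  set.seed(203)
  labs <- paste0("r", 1:9)
  p <- rand_partition(labs, 3)
  m <- rand_prepared(9, labs)
  pr1 <- profileSubject(m, p)
  c0 <- 3.25
  m2 <- connectivityMatrix("sx", c0 * zMatrix(m), labs, prepared = TRUE)
  pr2 <- profileSubject(m2, p)
  expect_equal(pr2@segGlobal, pr1@segGlobal, tolerance = 1e-12)
  expect_equal(pr2@seg, pr1@seg, tolerance = 1e-12)
  expect_equal(pr2@zwGlobal, c0 * pr1@zwGlobal, tolerance = 1e-12)
  expect_equal(pr2@intra, c0 * pr1@intra, tolerance = 1e-12)
  expect_equal(pr2@inter, c0 * pr1@inter, tolerance = 1e-12)
})

test_that("profiles are invariant to region-order permutation", {
  set.seed(204)
  labs <- paste0("r", 1:10)
  p <- rand_partition(labs, 3)
  m <- rand_prepared(10, labs)
  perm <- sample(10)
  z2 <- zMatrix(m)[perm, perm]
  m2 <- connectivityMatrix("sx", z2, labs[perm], prepared = TRUE)
  pr1 <- profileSubject(m, p)
  pr2 <- profileSubject(m2, p)
  expect_equal(pr1@segGlobal, pr2@segGlobal, tolerance = 1e-12)
  expect_equal(pr1@seg, pr2@seg, tolerance = 1e-12)
  expect_equal(pr1@inter, pr2@inter, tolerance = 1e-12)
})

test_that("global means are the pair-count-weighted means of the parts", {
  set.seed(205)
  labs <- paste0("r", 1:11)
  p <- rand_partition(labs, 3)
  m <- rand_prepared(11, labs)
  pr <- profileSubject(m, p)
  sizes <- table(factor(assignment(p), levels = networks(p)))
  wPairs <- sizes * (sizes - 1) / 2
  expect_equal(
    pr@zwGlobal,
    sum(pr@intra * wPairs) / sum(wPairs),
    tolerance = 1e-12
  )
  nets <- networks(p)
  bSum <- bCnt <- 0
  for (i in seq_along(nets)) {
    for (j in seq_along(nets)) {
      if (i < j) {
        cnt <- sizes[[i]] * sizes[[j]]
        bSum <- bSum + pr@inter[i, j] * cnt
        bCnt <- bCnt + cnt
      }
    }
  }
  expect_equal(pr@zbGlobal, bSum / bCnt, tolerance = 1e-12)
  # bounds: seg <= 1 always; sign tied to zw >= zb
  expect_lte(pr@segGlobal, 1)
  expect_identical(pr@segGlobal >= 0, pr@zwGlobal >= pr@zbGlobal)
})

test_that("singleton networks in scope are rejected", {
  p <- networkPartition(
    c(a1 = "A", a2 = "A", b1 = "B"),
    networks = c("A", "B")
  )
  ids <- regionIds(p)
  z <- matrix(0.3, 3, 3, dimnames = list(ids, ids))
  diag(z) <- 0
  m <- connectivityMatrix("s1", z, ids, prepared = TRUE)
  expect_error(withinBetweenMeans(m, p, "B"), "fewer than 2")
})

test_that("unprepared matrices are refused by segregation operations", {
  p <- two_block_partition(c(A = 2, B = 2))
  ids <- regionIds(p)
  z <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  diag(z) <- 0
  m <- connectivityMatrix("s1", z, ids, prepared = FALSE)
  expect_error(withinBetweenMeans(m, p), "prepared")
  expect_error(profileSubject(m, p), "prepared")
})

test_that("long-format export lists every measure once", {
  p <- two_block_partition(c(A = 2, B = 2))
  m <- block_matrix(p, 0.6, 0.2)
  long <- profileLong(profileSubject(m, p))
  expect_identical(anyDuplicated(long$measure), 0L)
  expect_true(all(c(
    "seg_global", "seg:A", "intra:B", "inter:A:B"
  ) %in% long$measure))
  expect_equal(
    long$value[long$measure == "inter:A:B"], 0.2
  )
})
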