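test_that("fitOLS equals the normal-equations oracle on a fixture", {
  set.seed(401)
  n <- 20
  d <- data.frame(
    y = rnorm(n), x = rnorm(n), age = rnorm(n, 70, 4),
    sex = rbinom(n, 1, 0.5)
  )
  res <- fitOLS(d, "y", "x", c("age", "sex"))
  X <- cbind(1, d$x, d$age, d$sex)
  orc <- oracle_ols(X, d$y)
  expect_equal(res$coefficient, unname(orc$beta[2]), tolerance = 1e-10)
  expect_equal(res$se, unname(orc$se[2]), tolerance = 1e-10)
  expect_equal(res$t, unname(orc$t[2]), tolerance = 1e-10)
  expect_equal(res$p_uncorrected, unname(orc$p[2]), tolerance = 1e-10)
  expect_identical(res$df, 16L)
  expect_equal(res$t, res$coefficient / res$se)
})

test_that("an exactly orthogonal predictor has coefficient ~ 0", {
  n <- 12
  x <- rep(c(1, -1), n / 2) # mean 0
  cov1 <- rep(c(1, 1, -1, -1), n / 4) # orthogonal to x
  y <- cov1 + rep(c(0.5, 0.5, -0.5, 0.3, -0.8, 0), 2)
  y <- y - x * sum(x * y) / sum(x * x) # project x out of y
  d <- data.frame(y = y, x = x, cov1 = cov1)
  res <- fitOLS(d, "y", "x", "cov1")
  expect_lt(abs(res$coefficient), 1e-10)
})

test_that("t and p are invariant to affine covariate rescaling", {
  set.seed(402)
  d <- data.frame(
    y = rnorm(50), x = rnorm(50), a = rnorm(50, 1e6, 1e5), b = rnorm(50)
  )
  r1 <- fitOLS(d, "y", "x", c("a", "b"))
  d2 <- transform(d, a = (a - 1e6) / 1e5, b = 100 * b + 3)
  r2 <- fitOLS(d2, "y", "x", c("a", "b"))
  expect_equal(r1$t, r2$t, tolerance = 1e-8)
  expect_equal(r1$p_uncorrected, r2$p_uncorrected, tolerance = 1e-8)
  expect_equal(r1$coefficient, r2$coefficient, tolerance = 1e-8)
})

test_that("rank deficiency and bad specs are rejected informatively", {
  set.seed(403)
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$dup <- 2 * d$x + 1
  expect_error(fitOLS(d, "y", "x", "dup"), "rank deficient.*dup")
  expect_error(fitOLS(d, "y", "x", "x"), "must not appear")
  expect_error(fitOLS(d[1:3, ], "y", "x"), "too few")
  d$y <- d$x * 3 + 1 # zero residual variance
  expect_error(fitOLS(d, "y", "x"), "zero residual variance")
})

test_that("rows with missing model variables are dropped with a log", {
  set.seed(404)
  d <- data.frame(y = rnorm(30), x = rnorm(30), c1 = rnorm(30))
  d$c1[c(3, 11)] <- NA
  expect_message(res <- fitOLS(d, "y", "x", "c1"), "dropped 2 row")
  expect_identical(res$n, 28L)
})

test_that("BH adjustment matches the min-over-suffix definition", {
  expect_equal(bhAdjust(0.03), 0.03) # m = 1 unchanged
  set.seed(405)
  for (rep in 1:10) {
    p <- runif(50)^2
    expect_equal(bhAdjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  # ties share a value through the stable sort
  p <- c(0.01, 0.01, 0.5)
  expect_equal(bhAdjust(p), oracle_bh(p))
  # monotone: ordering of adjusted follows ordering of raw
  p <- runif(30)
  adj <- bhAdjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bhAdjust(numeric(0)), "empty")
  expect_error(bhAdjust(c(0.1, 0)), "0, 1")
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("residualize projects out covariates exactly", {
  set.seed(406)
  n <- 40
  C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n)
  r <- residualize(y, C)
  expect_equal(r, oracle_residualize(y, C), tolerance = 1e-10)
  for (j in 1:3) expect_lt(abs(sum(r * C[, j])), 1e-8)
  expect_lt(abs(mean(r)), 1e-10)
  # exact linear combination -> all-zero residuals
  y2 <- 2 * C[, 1] - C[, 3] + 5
  expect_equal(residualize(y2, C), rep(0, n), tolerance = 1e-9)
  # already orthogonal and centered -> unchanged
  y3 <- residualize(rnorm(n), C)
  expect_equal(residualize(y3, C), y3, tolerance = 1e-10)
})

test_that("runFamily corrects within the declared family only", {
  set.seed(407)
  n <- 60
  d <- data.frame(
    x = rnorm(n), age = rnorm(n),
    o1 = rnorm(n), o2 = rnorm(n), o3 = rnorm(n), g0 = rnorm(n)
  )
  res <- runFamily(d, c("g0", "o1", "o2", "o3"), "x", "age",
    family = "f", correct = c("o1", "o2", "o3")
  )
  expect_true(is.na(res$p_fdr[res$outcome == "g0"]))
  inFam <- res$outcome != "g0"
  expect_equal(
    res$p_fdr[inFam], oracle_bh(res$p_uncorrected[inFam])
  )
  expect_true(all(res$p_fdr[inFam] >= res$p_uncorrected[inFam]))
  # single-member family: adjusted equals raw
  r1 <- runFamily(d, "o1", "x", "age")
  expect_equal(r1$p_fdr, r1$p_uncorrected)
})

test_that("BH keeps the familywise null rejection rate near alpha", {
  set.seed(408)
  n <- 30
  reps <- 1000
  anySig <- logical(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(
      x = rnorm(n), o1 = rnorm(n), o2 = rnorm(n), o3 = rnorm(n),
      o4 = rnorm(n), o5 = rnorm(n)
    )
    res <- runFamily(d, paste0("o", 1:5), "x", family = "null")
    anySig[r] <- any(res$p_fdr < 0.05)
  }
  # under the global null with independent outcomes, P(any BH
  # discovery) = alpha; Monte-Carlo SE ~ 0.007 at 1000 replicates
  expect_gt(mean(anySig), 0.025)
  expect_lt(mean(anySig), 0.075)
})
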