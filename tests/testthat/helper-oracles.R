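# Independent brute-force oracles used to validate the implementation.
# These deliberately use direct formulas and explicit double loops,
# never the package's own code paths.

# Pearson correlation + Fisher z by the textbook formula, pairwise loops
oracle_fisher_z <- function(X, clip = 1 - 1e-7) {
  R <- ncol(X)
  z <- matrix(0, R, R, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (i == j) next
      xi <- X[, i] - mean(X[, i])
      xj <- X[, j] - mean(X[, j])
      r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      r <- min(max(r, -clip), clip)
      z[i, j] <- atanh(r)
    }
  }
  z
}

# all segregation-profile quantities by exhaustive enumeration of
# unordered region pairs
oracle_profile <- function(z, assign, nets) {
  ids <- rownames(z)
  a <- assign[ids]
  n <- length(ids)
  wSum <- wCnt <- 0
  bSum <- bCnt <- 0
  zwN <- zbN <- setNames(numeric(length(nets)), nets)
  cwN <- cbN <- setNames(numeric(length(nets)), nets)
  interS <- interC <- matrix(0, length(nets), length(nets),
    dimnames = list(nets, nets)
  )
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- z[i, j]
      if (a[i] == a[j]) {
        wSum <- wSum + v
        wCnt <- wCnt + 1
        zwN[a[i]] <- zwN[a[i]] + v
        cwN[a[i]] <- cwN[a[i]] + 1
      } else {
        bSum <- bSum + v
        bCnt <- bCnt + 1
        for (nw in c(a[i], a[j])) {
          zbN[nw] <- zbN[nw] + v
          cbN[nw] <- cbN[nw] + 1
        }
        interS[a[i], a[j]] <- interS[a[i], a[j]] + v
        interS[a[j], a[i]] <- interS[a[j], a[i]] + v
        interC[a[i], a[j]] <- interC[a[i], a[j]] + 1
        interC[a[j], a[i]] <- interC[a[j], a[i]] + 1
      }
    }
  }
  inter <- interS / interC
  diag(inter) <- NA_real_
  list(
    zwGlobal = wSum / wCnt, zbGlobal = bSum / bCnt,
    segGlobal = (wSum / wCnt - bSum / bCnt) / (wSum / wCnt),
    zw = zwN / cwN, zb = zbN / cbN,
    seg = (zwN / cwN - zbN / cbN) / (zwN / cwN),
    inter = inter
  )
}

# Benjamini-Hochberg by the min-over-suffix definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    suffix <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    adj[ord[i]] <- min(1, min(suffix))
  }
  adj
}

# OLS coefficient table from the normal equations with classical SEs
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta[, 1] / se
  list(
    beta = beta[, 1], se = se, t = tval, df = df,
    p = 2 * pt(abs(tval), df, lower.tail = FALSE)
  )
}

# projection residuals via the explicit hat matrix
oracle_residualize <- function(y, C) {
  X <- cbind(1, as.matrix(C))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  as.numeric(y - H %*% y)
}

# ---- fixture builders ----

# random symmetric prepared matrix with named regions; entries strictly
# positive off-diagonal so every segregation scope is well defined
rand_prepared <- function(R, labels = paste0("r", seq_len(R))) {
  z <- matrix(stats::runif(R * R, 0.02, 1), R, R)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(labels, labels)
  connectivityMatrix("sx", z, labels, prepared = TRUE)
}

# random partition of R labelled regions into k networks (each >= 2)
rand_partition <- function(labels, k) {
  R <- length(labels)
  stopifnot(R >= 2 * k)
  nets <- paste0("net", seq_len(k))
  # guarantee two regions per network, assign the rest at random
  a <- c(rep(nets, each = 2), sample(nets, R - 2 * k, replace = TRUE))
  a <- sample(a)
  networkPartition(setNames(a, labels), networks = nets)
}

# small two-block partition used across segregation tests
two_block_partition <- function(sizes = c(A = 2, B = 2)) {
  labs <- rep(names(sizes), sizes)
  ids <- sprintf("%s%d", labs, unlist(lapply(sizes, seq_len)))
  networkPartition(setNames(labs, ids), networks = names(sizes))
}

# constant-block prepared matrix: within edges zw, between edges zb
block_matrix <- function(p, zw, zb, subject = "s1") {
  a <- assignment(p)
  ids <- names(a)
  z <- ifelse(outer(a, a, "=="), zw, zb)
  diag(z) <- 0
  dimnames(z) <- list(ids, ids)
  connectivityMatrix(subject, z, ids, prepared = TRUE)
}

# compact 18-region partition (2 regions per canonical network) for
# fast simulation studies
small_partition <- function() {
  labs <- rep(networkLabels(), each = 2)
  ids <- sprintf("%s_%d", labs, rep(1:2, length(networkLabels())))
  networkPartition(setNames(labs, ids), networks = networkLabels())
}
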