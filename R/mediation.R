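#' @include AllClasses.R
NULL

# OLS paths for a single-mediator model on residualized data, from
# cross-products (fast enough to call 5000+ times in the bootstrap).
.medPaths <- function(x, m, y) {
  vx <- sum(x * x) - sum(x)^2 / length(x)
  vm <- sum(m * m) - sum(m)^2 / length(m)
  cxm <- sum(x * m) - sum(x) * sum(m) / length(x)
  cxy <- sum(x * y) - sum(x) * sum(y) / length(x)
  cmy <- sum(m * y) - sum(m) * sum(y) / length(m)
  det <- vx * vm - cxm^2
  a <- cxm / vx
  b <- (vx * cmy - cxm * cxy) / det
  cPrime <- (vm * cxy - cxm * cmy) / det
  cTot <- cxy / vx
  c(a = a, b = b, cPrime = cPrime, c = cTot)
}

#' Residualized single-mediator analysis with bootstrap inference
#'
#' Tests whether a mediator variable `m` carries part of the association
#' between a predictor `x` and an outcome `y`. Covariates are first
#' regressed out of all three variables; the path model is then fit by
#' OLS on the residuals: `a` (x -> m), `b` and `c'` from `y ~ x + m`, and
#' the total effect `c` from `y ~ x`. The indirect effect is `a * b`
#' (which equals `c - c'` exactly for OLS on one sample) and the
#' proportion mediated is `a * b / c`. Inference on the indirect effect
#' uses a nonparametric bootstrap: subjects are resampled with
#' replacement (residuals treated as data, mirroring the
#' regress-out-first design), the indirect effect recomputed per
#' resample, and a 95% percentile (or BCa) interval reported together
#' with a two-sided sign-crossing p-value
#' `2 * min(P(boot <= 0), P(boot >= 0))`.
#'
#' @param x,m,y numeric vectors of equal length (predictor, mediator,
#'   outcome), or column names when `data` is given.
#' @param covariates covariate matrix/data.frame or column names; `NULL`
#'   to analyze the variables as they are.
#' @param data optional data.frame to resolve names against.
#' @param nBoot number of bootstrap resamples (>= 100), default 5000.
#' @param seed integer RNG seed; mandatory so runs are reproducible.
#' @param conf confidence level of the interval, default 0.95.
#' @param ciType `"percentile"` (default) or `"bca"`
#'   (bias-corrected and accelerated).
#' @param cTol the proportion mediated is flagged unstable (returned NA)
#'   when `|c|` falls below `cTol * sd(y-residuals) / sd(x-residuals)`;
#'   default 1e-6.
#' @return A [MediationResult-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' m <- 0.5 * x + rnorm(200)
#' y <- 0.5 * m + 0.25 * x + rnorm(200)
#' mediate(x, m, y, nBoot = 500, seed = 7)
#' @export
mediate <- function(x, m, y, covariates = NULL, data = NULL,
                    nBoot = 5000, seed, conf = 0.95,
                    ciType = c("percentile", "bca"), cTol = 1e-6) {
  ciType <- match.arg(ciType)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  if (!is.null(data)) {
    x <- data[[x]]
    m <- data[[m]]
    y <- data[[y]]
    if (!is.null(covariates) && is.character(covariates)) {
      covariates <- data[, covariates, drop = FALSE]
    }
  }
  n <- length(x)
  if (length(m) != n || length(y) != n) {
    stop("x, m and y must have equal length")
  }
  if (nBoot < 100) stop("nBoot must be >= 100")
  if (!is.null(covariates)) {
    x <- residualize(x, covariates)
    m <- residualize(m, covariates)
    y <- residualize(y, covariates)
  }
  paths <- .medPaths(x, m, y)
  if (!all(is.finite(paths))) {
    stop("collinear mediation inputs: path coefficients undefined")
  }
  indirect <- paths[["a"]] * paths[["b"]]

  set.seed(as.integer(seed))
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- .medPaths(x[idx], m[idx], y[idx])
    p[["a"]] * p[["b"]]
  }, numeric(1))
  boot <- boot[is.finite(boot)]

  alpha <- 1 - conf
  if (ciType == "percentile") {
    ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    z0 <- stats::qnorm(mean(boot < indirect))
    jack <- vapply(seq_len(n), function(i) {
      p <- .medPaths(x[-i], m[-i], y[-i])
      p[["a"]] * p[["b"]]
    }, numeric(1))
    jm <- mean(jack)
    acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    ci <- stats::quantile(boot, adj, names = FALSE)
  }
  pBoot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))

  unstable <- abs(paths[["c"]]) <
    cTol * stats::sd(y) / max(stats::sd(x), .Machine$double.eps)
  prop <- if (unstable) NA_real_ else indirect / paths[["c"]]

  new("MediationResult",
    a = unname(paths[["a"]]), b = unname(paths[["b"]]),
    c = unname(paths[["c"]]), cPrime = unname(paths[["cPrime"]]),
    indirect = unname(indirect), proportionMediated = prop,
    ciLower = ci[1L], ciUpper = ci[2L], pBoot = pBoot,
    nBoot = as.integer(nBoot), seed = as.integer(seed),
    n = as.integer(n), proportionStable = !unstable
  )
}

#' Flatten a MediationResult to a one-row data.frame
#'
#' @param res a [MediationResult-class].
#' @return One-row data.frame with all paths, interval bounds, p-value
#'   and bootstrap bookkeeping.
#' @export
mediationTable <- function(res) {
  stopifnot(is(res, "MediationResult"))
  data.frame(
    a = res@a, b = res@b, c = res@c, c_prime = res@cPrime,
    indirect = res@indirect,
    proportion_mediated = res@proportionMediated,
    ci_lower = res@ciLower, ci_upper = res@ciUpper,
    p_boot = res@pBoot, n = res@n, n_boot = res@nBoot, seed = res@seed,
    stringsAsFactors = FALSE
  )
}
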