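#' @include AllClasses.R
NULL

.checkFullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(
      "design matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    )
  }
  invisible(TRUE)
}

.modelFrame <- function(data, vars) {
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  nDropped <- sum(!keep)
  if (nDropped > 0L) {
    message(
      "dropped ", nDropped, " row(s) with missing values among: ",
      paste(vars, collapse = ", ")
    )
  }
  data[keep, vars, drop = FALSE]
}

#' Covariate-adjusted ordinary least squares for one outcome
#'
#' Fits `outcome ~ predictor + covariates` with an intercept by ordinary
#' least squares and reports the predictor's coefficient, classical
#' standard error, t statistic (coefficient/SE) and two-sided p-value
#' from the t distribution with residual degrees of freedom. Rows with a
#' missing value in any model variable are dropped listwise for that
#' model, with a logged count.
#'
#' @param data data.frame holding all model variables.
#' @param outcome,predictor,covariates column names; `predictor` must not
#'   appear among `covariates`.
#' @param family optional family identifier carried into the result for
#'   FDR bookkeeping.
#' @return One-row data.frame: `family`, `outcome`, `predictor`, `n`,
#'   `df`, `coefficient`, `se`, `t`, `p_uncorrected`, `p_fdr` (NA until
#'   [runFamily()] fills it).
#' @examples
#' d <- data.frame(y = rnorm(30), x = rnorm(30), age = rnorm(30))
#' fitOLS(d, "y", "x", "age")
#' @export
fitOLS <- function(data, outcome, predictor, covariates = character(),
                   family = NA_character_) {
  if (predictor %in% covariates) {
    stop("predictor '", predictor, "' must not appear among covariates")
  }
  vars <- c(outcome, predictor, covariates)
  mf <- .modelFrame(data, vars)
  X <- cbind(
    `(Intercept)` = 1,
    as.matrix(mf[, c(predictor, covariates), drop = FALSE])
  )
  n <- nrow(mf)
  if (n <= ncol(X) + 1L) {
    stop("too few complete rows (", n, ") for ", ncol(X), " coefficients")
  }
  .checkFullRank(X)
  fit <- stats::lm.fit(X, mf[[outcome]])
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  tss <- sum((mf[[outcome]] - mean(mf[[outcome]]))^2)
  if (rss <= 1e-12 * max(tss, .Machine$double.eps)) {
    stop("zero residual variance for outcome '", outcome, "'")
  }
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  b <- fit$coefficients[predictor]
  seB <- se[match(predictor, colnames(X))]
  tval <- b / seB
  data.frame(
    family = family, outcome = outcome, predictor = predictor,
    n = n, df = df,
    coefficient = unname(b), se = unname(seB), t = unname(tval),
    p_uncorrected = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    p_fdr = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for one declared family of m tests:
#' after ascending sort, adjusted p at rank i is
#' `min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to input
#' order. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of uncorrected p-values in (0, 1].
#' @return Adjusted p-values, same order and length as the input.
#' @examples
#' bhAdjust(c(0.0012, 0.0024, 0.0172, 0.0412, 0.2196))
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Residualize a variable on covariates
#'
#' Removes the OLS projection of `y` onto an intercept plus the
#' covariates, returning residuals orthogonal to every covariate (and
#' mean zero). Used for partial-association scatter data and as the first
#' step of the mediation analysis.
#'
#' @param y numeric vector, or a column name when `data` is supplied.
#' @param covariates numeric matrix/data.frame of covariates, or column
#'   names when `data` is supplied.
#' @param data optional data.frame to resolve names against.
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariates, data = NULL) {
  if (!is.null(data)) {
    y <- data[[y]]
    covariates <- data[, covariates, drop = FALSE]
  }
  C <- as.matrix(covariates)
  X <- cbind(`(Intercept)` = 1, C)
  if (anyNA(y) || anyNA(X)) stop("missing values in residualization inputs")
  .checkFullRank(X)
  stats::lm.fit(X, y)$residuals
}

#' Fit an association family and correct it for multiple comparisons
#'
#' Fits one OLS model per outcome (shared predictor and covariates) and
#' applies Benjamini-Hochberg FDR across exactly the members listed in
#' `correct`, which defaults to all of them. Members excluded from
#' correction (e.g. a global summary reported alongside a corrected
#' network-level family) keep `p_fdr = NA`.
#'
#' @param data data.frame with all model variables.
#' @param outcomes character vector of outcome column names (the family
#'   members).
#' @param predictor shared predictor column name.
#' @param covariates shared covariate column names.
#' @param family family identifier string.
#' @param correct outcomes to include in the FDR correction.
#' @param alpha significance level applied to `p_fdr`, default 0.05.
#' @return data.frame with one row per outcome, columns as in
#'   [fitOLS()] plus `significant`.
#' @export
runFamily <- function(data, outcomes, predictor, covariates = character(),
                      family = "family", correct = outcomes,
                      alpha = 0.05) {
  rows <- lapply(outcomes, function(o) {
    fitOLS(data, o, predictor, covariates, family = family)
  })
  res <- do.call(rbind, rows)
  inFam <- res$outcome %in% correct
  if (any(inFam)) {
    res$p_fdr[inFam] <- bhAdjust(res$p_uncorrected[inFam])
  }
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res
}
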