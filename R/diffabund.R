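## MaAsLin-style differential abundance: prevalence filtering, optional
## total-sum scaling, log2 transform with pseudo-counts, per-feature
## covariate-adjusted linear models, BH correction over the feature
## family, and mutual adjustment of selected features.

#' Prevalence filter
#'
#' Keeps features detected (non-zero) in at least `min_prev` of samples.
#' The boundary is inclusive: a feature present in exactly
#' `min_prev * n` samples is retained.
#'
#' @param mat samples x features matrix.
#' @param min_prev minimal prevalence fraction in (0, 1].
#' @return filtered matrix; dropped feature names in attribute "dropped",
#'   per-feature prevalence of the retained features in attribute
#'   "prevalence".
#' @export
prevalence_filter <- function(mat, min_prev = 0.1) {
  if (!(min_prev > 0 && min_prev <= 1)) stop_config("min_prev must lie in (0, 1]")
  prev <- colMeans(mat > 0)
  keep <- prev >= min_prev
  if (!any(keep)) warning("no features pass the prevalence filter")
  out <- mat[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(mat)[!keep]
  attr(out, "prevalence") <- prev[keep]
  out
}

#' Normalise and log2-transform abundances
#'
#' Optional total-sum scaling (per-sample division by the sample total,
#' used for pathway tables) followed by `log2(x + pseudo)`. The default
#' pseudo-count is half the smallest non-zero value of the
#' (post-normalisation) matrix.
#'
#' @param mat non-negative samples x features matrix.
#' @param normalization `"none"` (species relative abundances) or `"tss"`.
#' @param pseudo positive pseudo-count; `NULL` for the default.
#' @return transformed matrix; the pseudo-count used in attribute "pseudo".
#' @export
transform_abundance <- function(mat, normalization = c("none", "tss"), pseudo = NULL) {
  normalization <- match.arg(normalization)
  if (any(mat < 0)) stop_domain("abundances must be non-negative")
  if (normalization == "tss") {
    tot <- rowSums(mat)
    if (any(tot <= 0)) stop_domain("cannot TSS-normalise a zero-total sample")
    mat <- mat / tot
  }
  if (is.null(pseudo)) {
    nz <- mat[mat > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 0.5
  }
  if (!is.numeric(pseudo) || length(pseudo) != 1L || pseudo <= 0)
    stop_config("pseudo must be a positive scalar")
  out <- log2(mat + pseudo)
  attr(out, "pseudo") <- pseudo
  if (!is.null(attr(mat, "prevalence"))) attr(out, "prevalence") <- attr(mat, "prevalence")
  out
}

## Multi-response OLS of Y (n x m) on design X; returns per-feature
## estimates/se/p for the requested coefficient columns.
ols_features <- function(Y, X, which_cols) {
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop_usage("design matrix is rank deficient")
  B <- qr.coef(qx, Y)                       # p x m
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qx))
  lapply(which_cols, function(j) {
    se <- sqrt(sigma2 * XtXinv[j, j])
    est <- B[j, ]
    tt <- est / se
    list(estimate = est, se = se,
         p = 2 * stats::pt(-abs(tt), df = n - p))
  })
}

#' Per-feature differential abundance models
#'
#' Fits, for every feature, an ordinary least squares model of the
#' transformed abundance on the exposure plus covariates (the analysis
#' covariate set includes sequencing depth), and applies Benjamini-
#' Hochberg correction across the feature family separately for each
#' exposure coefficient. Constant features are skipped and logged.
#'
#' @param transformed samples x features matrix (from
#'   [transform_abundance()], log2 scale so coefficients are log2 fold
#'   changes per exposure unit).
#' @param exposure numeric vector or factor.
#' @param covariates optional data.frame.
#' @param level confidence level for the Wald intervals.
#' @return data.frame with feature, term, log2fc, ci_low, ci_high, p, q,
#'   direction, prevalence (one row per feature x exposure coefficient);
#'   skipped features in attribute "skipped".
#' @export
fit_features <- function(transformed, exposure, covariates = NULL, level = 0.95) {
  Y <- as.matrix(transformed)
  keep <- apply(Y, 2, function(v) stats::var(v) > 0)
  skipped <- colnames(Y)[!keep]
  Y <- Y[, keep, drop = FALSE]
  if (ncol(Y) == 0L) stop_usage("no non-constant features to test")
  df <- data.frame(.expo = exposure)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  X <- build_design(df)
  expo_cols <- grep("^\\.expo", colnames(X))
  fits <- ols_features(Y, X, expo_cols)
  z <- qnorm(1 - (1 - level) / 2)
  ## detection prevalence: carried from prevalence_filter when available,
  ## otherwise inferred from the transformed floor (zeros map to the
  ## common value log2(pseudo))
  prev <- attr(transformed, "prevalence")
  if (is.null(prev) || length(prev) != ncol(as.matrix(transformed))) {
    tm <- as.matrix(transformed)
    prev <- colMeans(tm > min(tm) + 1e-12)
  }
  prev <- prev[keep]
  rows <- lapply(seq_along(expo_cols), function(i) {
    f <- fits[[i]]
    data.frame(feature = colnames(Y),
               term = sub("^\\.expo", "exposure", colnames(X)[expo_cols[i]]),
               log2fc = f$estimate,
               ci_low = f$estimate - z * f$se,
               ci_high = f$estimate + z * f$se,
               p = f$p,
               q = bh_adjust(f$p),
               direction = ifelse(f$estimate >= 0, "positive", "negative"),
               prevalence = prev,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Mutual adjustment of selected features
#'
#' Refits each selected feature's exposure association with the other
#' selected features' transformed abundances added as covariates, and
#' reports which associations retain p < `alpha`. A collinear feature set
#' triggers a ridge-stabilised fit with a warning rather than a failure.
#'
#' @param transformed samples x features matrix (log2 scale).
#' @param selected character vector (>= 2) of feature names.
#' @param exposure numeric exposure vector.
#' @param covariates optional data.frame.
#' @param alpha retention threshold.
#' @return data.frame with feature, log2fc, p, retained.
#' @export
mutual_adjustment <- function(transformed, selected, exposure, covariates = NULL,
                              alpha = 0.05) {
  if (length(selected) < 2L) stop_usage("mutual adjustment needs >= 2 selected features")
  miss <- setdiff(selected, colnames(transformed))
  if (length(miss)) stop_schema("unknown features: ", paste(miss, collapse = ", "))
  rows <- lapply(selected, function(feat) {
    others <- setdiff(selected, feat)
    df <- data.frame(.expo = exposure)
    if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
    X <- cbind(build_design(df), transformed[, others, drop = FALSE])
    y <- transformed[, feat]
    n <- nrow(X); p <- ncol(X)
    XtX <- crossprod(X)
    ridge <- 0
    if (qr(X)$rank < p) {
      warning("collinear feature set; ridge-stabilised fit for ", feat)
      ridge <- 1e-6 * mean(diag(XtX))
    }
    A <- solve(XtX + diag(ridge, p))
    b <- A %*% crossprod(X, y)
    res <- y - X %*% b
    sigma2 <- sum(res^2) / (n - qr(X)$rank)
    j <- which(colnames(X) == ".expo")[1]
    se <- sqrt(sigma2 * A[j, j])
    pval <- 2 * stats::pt(-abs(b[j] / se), df = n - qr(X)$rank)
    data.frame(feature = feat, log2fc = b[j], p = pval,
               retained = pval < alpha, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
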