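## Multinomial logistic regression for the three screening diagnostic
## groups (controls as reference), fitted by direct Newton-Raphson
## maximisation of the multinomial log-likelihood with analytic gradient
## and observed information. Wald inference throughout.

#' Fit a multinomial logistic regression
#'
#' Fits the K-category baseline-logit model with the first factor level of
#' the outcome as reference (for screening data: controls). Estimation is
#' Newton-type on the full multinomial log-likelihood with analytic
#' gradient; the observed information is ridge-stabilised (1e-8) when
#' singular. Wald covariance is the inverse observed information.
#'
#' @param data data.frame holding the predictor columns.
#' @param outcome factor (>= 2 levels, each non-empty) or the name of a
#'   column of `data`; first level is the reference.
#' @param terms character vector of predictor column names; factors are
#'   dummy-coded via `model.matrix`.
#' @param tol convergence tolerance on the max absolute score.
#' @param max_iter iteration cap; non-convergence is flagged, not silent.
#' @return object of class `multinom_fit` with elements `coefficients`
#'   ((K-1) x p matrix, rows the non-reference outcomes), `vcov` (over
#'   `vec` of the coefficient rows), `loglik`, `n`, `converged`,
#'   `reference`, `outcome_levels`, `term_names`.
#' @export
fit_multinomial <- function(data, outcome, terms, tol = 1e-8, max_iter = 100L) {
  if (is.character(outcome) && length(outcome) == 1L) outcome <- data[[outcome]]
  y <- if (is.factor(outcome)) outcome else factor(outcome)  # keep declared levels
  if (nlevels(y) < 2L) stop_usage("outcome needs at least 2 levels")
  if (any(table(y) == 0L)) stop_domain("empty outcome category: ", paste(levels(y)[table(y) == 0L], collapse = ", "))
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop_schema("missing predictor columns: ", paste(miss, collapse = ", "))
  X <- build_design(data[, terms, drop = FALSE])
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (any(table(y) == 0L))
    stop_domain("empty outcome category after removing incomplete rows")
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  if (qr(X)$rank < p) stop_usage("design matrix is rank deficient after encoding")
  Ymat <- matrix(0, n, K - 1L)
  yi <- as.integer(y)
  for (k in 2:K) Ymat[, k - 1L] <- as.numeric(yi == k)

  B <- matrix(0, K - 1L, p)
  loglik <- function(B) {
    eta <- X %*% t(B)
    lse <- log1p(rowSums(exp(eta)))
    sum(eta * Ymat) - sum(lse)
  }
  ll <- loglik(B)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- X %*% t(B)
    expeta <- exp(eta)
    denom <- 1 + rowSums(expeta)
    P <- expeta / denom                       # n x (K-1)
    G <- t(X) %*% (Ymat - P)                  # p x (K-1), score per contrast
    g <- as.vector(G)
    ## observed information, (K-1)p x (K-1)p in contrast-major blocks
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (k in seq_len(K - 1L)) for (l in k:(K - 1L)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(X, X * w)
      ik <- (k - 1L) * p + seq_len(p); il <- (l - 1L) * p + seq_len(p)
      H[ik, il] <- blk
      if (k != l) H[il, ik] <- blk
    }
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) solve(H + diag(1e-8, nrow(H)), g))
    ## step-halving safeguard
    lam <- 1
    repeat {
      ## step is vec over contrasts: reshape contrast-major
      Bnew <- B
      for (k in seq_len(K - 1L)) Bnew[k, ] <- B[k, ] + lam * step[(k - 1L) * p + seq_len(p)]
      llnew <- loglik(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) { B <- Bnew; ll <- llnew; break }
      lam <- lam / 2
      if (lam < 1e-10) break
    }
  }
  V <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-8, nrow(H))))
  cn <- colnames(X)
  rn <- levels(y)[-1]
  dimnames(B) <- list(rn, cn)
  vn <- unlist(lapply(rn, function(r) paste(r, cn, sep = ":")))
  dimnames(V) <- list(vn, vn)
  structure(list(coefficients = B, vcov = V, loglik = ll, n = n,
                 converged = converged, reference = levels(y)[1],
                 outcome_levels = levels(y), term_names = cn,
                 X = X, y = y),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("Multinomial logistic fit (reference:", x$reference, ")\n")
  cat("n =", x$n, " log-likelihood =", format(x$loglik),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

coef_se <- function(fit, outcome, term) {
  nm <- paste(outcome, term, sep = ":")
  b <- fit$coefficients[outcome, term]
  se <- sqrt(fit$vcov[nm, nm])
  c(b = b, se = se)
}

#' Odds ratios with Wald confidence intervals
#'
#' @param fit a `multinom_fit`.
#' @param terms coefficient names to report (default all non-intercept).
#' @param level confidence level.
#' @param coding optional label describing the exposure coding.
#' @return data.frame with term, outcome, OR, CI bounds and Wald p.
#' @export
association_table <- function(fit, terms = NULL, level = 0.95, coding = NA_character_) {
  if (is.null(terms)) terms <- setdiff(fit$term_names, "(Intercept)")
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (oc in rownames(fit$coefficients)) for (tm in terms) {
    bs <- coef_se(fit, oc, tm)
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, outcome = oc,
      or_ = exp(bs["b"]), ci_low = exp(bs["b"] - z * bs["se"]),
      ci_high = exp(bs["b"] + z * bs["se"]),
      p = 2 * pnorm(-abs(bs["b"] / bs["se"])),
      coding = coding, stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Wald trend test over ordinal exposure levels
#'
#' The exposure must enter the model as a single ordinal numeric score
#' (0, 1, 2, 3 for the four consumption levels); the returned p-values are
#' Wald tests of that term, one per outcome contrast.
#'
#' @param fit a `multinom_fit`.
#' @param term name of the ordinal score column in the fit.
#' @return named numeric vector of p-values (one per non-reference outcome).
#' @export
trend_test <- function(fit, term) {
  if (!term %in% fit$term_names)
    stop_usage("term '", term, "' not in the fitted model; code the exposure as one ordinal numeric score")
  sapply(rownames(fit$coefficients), function(oc) {
    bs <- coef_se(fit, oc, term)
    unname(2 * pnorm(-abs(bs[["b"]] / bs[["se"]])))
  })
}

#' Wald tests for interaction (product) terms
#'
#' Per-term Wald p-values for each product term and outcome contrast, plus
#' an optional joint chi-squared test across the listed terms within each
#' contrast.
#'
#' @param fit a `multinom_fit`.
#' @param terms character vector of product-term coefficient names (e.g.
#'   from dummy-coded `sex x level` columns).
#' @param joint also compute the joint Wald test per outcome contrast.
#' @return data.frame with outcome, term, estimate, se, p; joint rows have
#'   term `"(joint)"` and the chi-squared statistic in `estimate`.
#' @export
interaction_wald <- function(fit, terms, joint = FALSE) {
  miss <- setdiff(terms, fit$term_names)
  if (length(miss)) stop_usage("model has no product terms: ", paste(miss, collapse = ", "))
  out <- list()
  for (oc in rownames(fit$coefficients)) {
    nms <- paste(oc, terms, sep = ":")
    V <- fit$vcov[nms, nms, drop = FALSE]
    if (any(!is.finite(V)) || any(diag(V) <= 0))
      stop_usage("aliased product term among: ", paste(terms, collapse = ", "))
    for (tm in terms) {
      bs <- coef_se(fit, oc, tm)
      out[[length(out) + 1L]] <- data.frame(
        outcome = oc, term = tm, estimate = bs["b"], se = bs["se"],
        p = 2 * pnorm(-abs(bs["b"] / bs["se"])), row.names = NULL)
    }
    if (joint) {
      b <- fit$coefficients[oc, terms]
      stat <- tryCatch(drop(t(b) %*% solve(V, b)),
                       error = function(e) stop_usage("aliased product terms: ", paste(terms, collapse = ", ")))
      out[[length(out) + 1L]] <- data.frame(
        outcome = oc, term = "(joint)", estimate = stat, se = NA_real_,
        p = pchisq(stat, df = length(terms), lower.tail = FALSE), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
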