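## Counterfactual mediation decomposition: the effect of a twofold
## increase in alcohol intake (one unit on the log2 scale) on advanced
## colorectal lesions, split into the average direct effect (ADE) and the
## average causal mediation effect (ACME) acting through the microbial
## score, on the risk-difference scale, with nonparametric percentile
## bootstrap confidence intervals.

#' Linear model for the mediator
#'
#' OLS of the microbial score on the exposure plus covariates (the
#' adjustment set includes the cross-validation partition identity). The
#' residual SD is retained for drawing counterfactual mediator values.
#'
#' @param data data.frame with all columns.
#' @param mediator,exposure column names (exposure on the log2 scale).
#' @param covariates character vector of covariate column names.
#' @return list of class `mediator_fit`: `coef`, `sigma`, `exposure_coef`,
#'   plus the design information needed for counterfactual prediction.
#' @export
fit_mediator_model <- function(data, mediator, exposure, covariates = character()) {
  m <- data[[mediator]]
  if (is.null(m)) stop_schema("mediator column '", mediator, "' not found")
  if (var(m) == 0) stop_domain("zero-variance mediator")
  df <- data[, c(exposure, covariates), drop = FALSE]
  X <- build_design(df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_usage("rank-deficient mediator design; aliased: ", paste(aliased, collapse = ", "))
  }
  b <- qr.coef(qx, m)
  res <- m - X %*% b
  sigma <- sqrt(sum(res^2) / (nrow(X) - ncol(X)))
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv)) * sigma
  structure(list(coef = b, se = setNames(se, names(b)), sigma = sigma,
                 exposure = exposure, exposure_coef = b[[exposure]],
                 fitted = drop(X %*% b), X = X, n = nrow(X)),
            class = "mediator_fit")
}

#' Logistic model for the outcome
#'
#' Maximum-likelihood logistic regression of the advanced-lesion indicator
#' on exposure, mediator and covariates (non-advanced adenomas having been
#' grouped with colonoscopy-negative controls upstream). Quasi-separation
#' is flagged via `converged = FALSE`, never silent.
#'
#' @param data data.frame.
#' @param outcome binary (0/1 or logical) column name.
#' @param exposure,mediator column names.
#' @param covariates character vector of covariate column names.
#' @return list of class `outcome_fit` with `coef`, `vcov`, `converged`.
#' @export
fit_outcome_model <- function(data, outcome, exposure, mediator, covariates = character()) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop_usage("outcome must be binary 0/1 (group non-advanced findings with controls first)")
  df <- data[, c(exposure, mediator, covariates), drop = FALSE]
  X <- build_design(df)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  conv <- fit$converged && all(abs(fit$coefficients) < 20)
  b <- fit$coefficients
  w <- fit$weights
  V <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  structure(list(coef = setNames(b, colnames(X)), vcov = V,
                 converged = conv, exposure = exposure, mediator = mediator,
                 X = X, y = y, n = nrow(X)),
            class = "outcome_fit")
}

#' Counterfactual decomposition (ACME / ADE / total effect)
#'
#' For each participant, counterfactual mediator values `M(a)` are drawn
#' from the fitted normal linear mediator model at the observed exposure
#' `a0` and at `a1 = a0 + delta` (default one log2 unit, i.e. a twofold
#' intake increase), pushed through the logistic outcome model to obtain
#' potential-outcome probabilities `Y(a, M(a'))`, and averaged:
#' ACME = E\[Y(a1, M(a1)) - Y(a1, M(a0))\],
#' ADE  = E\[Y(a1, M(a0)) - Y(a0, M(a0))\] (both treated- and
#' control-referenced variants are computed and averaged), total = ACME +
#' ADE exactly, proportion mediated = ACME / total. All effects are on the
#' risk-difference (probability) scale.
#'
#' The integral over the mediator distribution is computed either by Monte
#' Carlo (`method = "simulate"`, `n_sim` draws) or by Gauss-Hermite
#' quadrature (`method = "quadrature"`, deterministic; used inside the
#' bootstrap for speed).
#'
#' @param med_fit a [fit_mediator_model()] fit.
#' @param out_fit a [fit_outcome_model()] fit.
#' @param exposure_values observed exposure vector (log2 scale) aligned
#'   with the fits.
#' @param delta exposure contrast (default 1 = twofold).
#' @param n_sim Monte Carlo draws for `method = "simulate"`.
#' @param method `"simulate"` or `"quadrature"`.
#' @param quad_k quadrature nodes.
#' @param seed RNG seed for the Monte Carlo draws.
#' @return list of class `mediation_point`: `acme`, `ade`, `total_effect`,
#'   `prop_mediated` (NA with `pm_undefined = TRUE` when the total effect
#'   is numerically zero), the treated/control-referenced components, and
#'   the contrast.
#' @export
decompose <- function(med_fit, out_fit, exposure_values, delta = 1,
                      n_sim = 1000L, method = c("simulate", "quadrature"),
                      quad_k = 21L, seed = NULL) {
  method <- match.arg(method)
  if (!out_fit$converged) warning("outcome model flagged as not converged")
  n <- length(exposure_values)
  if (n != med_fit$n || n != out_fit$n) stop_usage("misaligned fits and exposure vector")
  bexp_m <- med_fit$exposure_coef
  mu0 <- med_fit$fitted                  # E[M | a0, C]
  mu1 <- mu0 + bexp_m * delta            # linear mediator model
  sig <- med_fit$sigma
  bo <- out_fit$coef
  gamma <- bo[[out_fit$mediator]]
  beta_a <- bo[[out_fit$exposure]]
  ## linear predictor with exposure and mediator contributions removed
  base <- drop(out_fit$X %*% bo) -
    beta_a * out_fit$X[, out_fit$exposure] - gamma * out_fit$X[, out_fit$mediator]
  a0 <- exposure_values
  a1 <- a0 + delta
  pbar <- function(a, mu) {
    ## E over M ~ N(mu, sig) of plogis(base + beta_a a + gamma M)
    lp0 <- base + beta_a * a + gamma * mu
    if (method == "quadrature") {
      gh <- gauss_hermite_normal(quad_k)
      out <- numeric(n)
      for (j in seq_along(gh$nodes))
        out <- out + gh$weights[j] * plogis(lp0 + gamma * sig * gh$nodes[j])
      mean(out)
    } else {
      z <- matrix(rnorm(n * n_sim), n, n_sim)
      mean(plogis(lp0 + gamma * sig * z))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  y11 <- pbar(a1, mu1)   # Y(a1, M(a1))
  y10 <- pbar(a1, mu0)   # Y(a1, M(a0))
  y00 <- pbar(a0, mu0)   # Y(a0, M(a0))
  y01 <- pbar(a0, mu1)   # Y(a0, M(a1))
  acme1 <- y11 - y10; acme0 <- y01 - y00
  ade0 <- y10 - y00; ade1 <- y11 - y01
  acme <- (acme1 + acme0) / 2
  ade <- (ade1 + ade0) / 2
  total <- acme + ade
  pm_undef <- abs(total) < 1e-12
  structure(list(acme = acme, ade = ade, total_effect = total,
                 prop_mediated = if (pm_undef) NA_real_ else acme / total,
                 pm_undefined = pm_undef,
                 acme_treated = acme1, acme_control = acme0,
                 ade_treated = ade1, ade_control = ade0,
                 contrast = c(a0 = NA_real_, delta = delta)),
            class = "mediation_point")
}

#' Full mediation analysis with bootstrap confidence intervals
#'
#' Fits the mediator and outcome models, computes the counterfactual
#' decomposition, and attaches nonparametric percentile bootstrap 95%
#' confidence intervals: participants are resampled with replacement,
#' both models refitted and the decomposition recomputed per replicate.
#' A quasi-Bayesian alternative (parameter draws from the asymptotic
#' normal distribution of both fits) is available for cross-checking.
#'
#' @param data data.frame with all columns.
#' @param outcome,exposure,mediator column names; exposure on the log2
#'   scale, outcome binary.
#' @param covariates character vector of covariate columns.
#' @param delta exposure contrast (default 1 log2 unit = twofold).
#' @param n_boot bootstrap replicates (>= 100 for CI output).
#' @param n_sim Monte Carlo draws for the point estimate.
#' @param seed RNG seed (required; governs draws and resampling).
#' @param ci_method `"bootstrap"` (percentile, default) or
#'   `"quasi-bayes"`.
#' @param level confidence level.
#' @param boot_method integration method inside replicates (default
#'   `"quadrature"` for speed and determinism).
#' @return object of class `mediation_result`: point estimates, percentile
#'   CIs (`ci_total`, `ci_ade`, `ci_acme`, `ci_prop`), `n_boot`, `seed`,
#'   `contrast`, and both model fits.
#' @export
mediate <- function(data, outcome, exposure, mediator, covariates = character(),
                    delta = 1, n_boot = 1000L, n_sim = 1000L, seed = 1L,
                    ci_method = c("bootstrap", "quasi-bayes"), level = 0.95,
                    boot_method = "quadrature") {
  ci_method <- match.arg(ci_method)
  if (n_boot < 100L) stop_usage("n_boot must be >= 100 for CI output")
  med <- fit_mediator_model(data, mediator, exposure, covariates)
  out <- fit_outcome_model(data, outcome, exposure, mediator, covariates)
  a <- data[[exposure]]
  pt <- decompose(med, out, a, delta = delta, n_sim = n_sim,
                  method = "simulate", seed = child_seed(seed, 1L))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draw <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("total", "ade", "acme", "pm")))
  set.seed(child_seed(seed, 2L))
  n <- nrow(data)
  fail <- 0L
  if (ci_method == "bootstrap") {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- data[idx, , drop = FALSE]
      res <- tryCatch({
        mb <- fit_mediator_model(db, mediator, exposure, covariates)
        ob <- fit_outcome_model(db, outcome, exposure, mediator, covariates)
        decompose(mb, ob, db[[exposure]], delta = delta, method = boot_method)
      }, error = function(e) NULL)
      if (is.null(res)) { fail <- fail + 1L; next }
      draw[b, ] <- c(res$total_effect, res$ade, res$acme, res$prop_mediated)
    }
  } else {
    if (is.null(out$vcov)) stop_usage("outcome covariance unavailable for quasi-Bayes draws")
    Lm <- chol(chol2inv(qr.R(qr(med$X))) * med$sigma^2)
    Lo <- chol(out$vcov)
    for (b in seq_len(n_boot)) {
      mb <- med
      mb$coef <- med$coef + drop(t(Lm) %*% rnorm(length(med$coef)))
      mb$exposure_coef <- mb$coef[[exposure]]
      mb$fitted <- drop(med$X %*% mb$coef)
      ob <- out
      ob$coef <- out$coef + drop(t(Lo) %*% rnorm(length(out$coef)))
      res <- decompose(mb, ob, a, delta = delta, method = boot_method)
      draw[b, ] <- c(res$total_effect, res$ade, res$acme, res$prop_mediated)
    }
  }
  if (fail > 0.1 * n_boot)
    stop_domain("more than 10% of bootstrap replicates failed to fit (", fail, "/", n_boot, ")")
  ci <- function(col) unname(quantile(draw[, col], qs, na.rm = TRUE))
  structure(list(total_effect = pt$total_effect, ade = pt$ade, acme = pt$acme,
                 prop_mediated = pt$prop_mediated, pm_undefined = pt$pm_undefined,
                 ci_total = ci("total"), ci_ade = ci("ade"),
                 ci_acme = ci("acme"), ci_prop = ci("pm"),
                 n_boot = as.integer(n_boot), n_failed = fail,
                 contrast = c(delta = delta), seed = as.integer(seed),
                 ci_method = ci_method, draws = draw,
                 mediator_fit = med, outcome_fit = out),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%+.5f  [%+.5f, %+.5f]", v, ci[1], ci[2])
  cat("Causal mediation decomposition (risk-difference scale,",
      sprintf("twofold contrast x %g)\n", x$contrast[["delta"]]))
  cat("  Total effect:", fmt(x$total_effect, x$ci_total), "\n")
  cat("  ADE:         ", fmt(x$ade, x$ci_ade), "\n")
  cat("  ACME:        ", fmt(x$acme, x$ci_acme), "\n")
  if (isTRUE(x$pm_undefined)) {
    cat("  Proportion mediated: undefined (total effect ~ 0)\n")
  } else {
    cat(sprintf("  Proportion mediated: %.1f%%  [%.1f%%, %.1f%%]\n",
                100 * x$prop_mediated, 100 * x$ci_prop[1], 100 * x$ci_prop[2]))
  }
  cat("  ", x$ci_method, "CIs,", x$n_boot, "replicates, seed", x$seed, "\n")
  invisible(x)
}
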