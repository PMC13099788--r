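#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases glm.fit lm median model.matrix
#'   pnorm plogis pchisq pt qlogis qnorm quantile rbinom rgamma
#'   rlnorm rnorm runif sd setNames uniroot var binomial dist
#' @importFrom utils read.delim write.table
NULL

stop_domain <- function(...) stop(errorCondition(paste0(...), class = c("alcomediome_domain_error", "error")))
stop_schema <- function(...) stop(errorCondition(paste0(...), class = c("alcomediome_schema_error", "error")))
stop_usage  <- function(...) stop(errorCondition(paste0(...), class = c("alcomediome_usage_error", "error")))
stop_config <- function(...) stop(errorCondition(paste0(...), class = c("alcomediome_config_error", "error")))

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over a family of p-values.
#' Implemented directly (running minimum of `p * m / rank` from the largest
#' rank down) so that it can be checked against a brute-force oracle.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` allowed and returned
#'   as `NA`.
#' @return vector of adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_usage("p must be numeric")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  if (any(pp < 0 | pp > 1)) stop_domain("p-values must lie in [0, 1]")
  m <- length(pp)
  if (m == 0L) return(q)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  ## ratio-first grouping keeps q >= p exactly in floating point
  qq <- pmin(1, cummin(pp[o] * (m / (m:1))))[ro]
  q[ok] <- qq
  q
}

## Build a model matrix from a data.frame of covariates (may be NULL/empty),
## always including an intercept. Character columns become factors.
build_design <- function(data, intercept = TRUE) {
  if (is.null(data) || ncol(as.data.frame(data)) == 0L) {
    n <- if (is.null(data)) 0L else nrow(data)
    X <- matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  f <- if (intercept) ~ . else ~ . - 1
  model.matrix(f, data = df)
}

## Per-twofold exposure coding: log2(g/day + 1). The pseudo-count of one
## gram keeps zero consumers in the model; drop_zero = TRUE instead returns
## NA for them so callers can subset.
#' Per-twofold alcohol coding
#'
#' Codes intake in grams/day as `log2(g + 1)` so that a one-unit increase is
#' a doubling. The +1 pseudo-count keeps zero consumers; with
#' `drop_zero = TRUE` zero consumers are returned as `NA` instead.
#'
#' @param grams_per_day non-negative numeric vector.
#' @param drop_zero return `NA` for zero consumers instead of 0.
#' @return numeric vector on the log2 scale.
#' @export
log2_alcohol <- function(grams_per_day, drop_zero = FALSE) {
  if (any(grams_per_day < 0, na.rm = TRUE)) stop_domain("alcohol intake must be non-negative")
  out <- log2(grams_per_day + 1)
  if (drop_zero) out[grams_per_day == 0] <- NA_real_
  out
}

## Gauss-Hermite nodes/weights for integrating against a standard normal,
## via the Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite_normal <- function(k = 21L) {
  if (k == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(k - 1L) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  J[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ## physicists' nodes x -> probabilists' z = sqrt(2) x; weights sum to 1
  list(nodes = sqrt(2) * e$values, weights = e$vectors[1, ]^2)
}

## Deterministic child seed for a named sub-stream, kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L + as.integer(offset) * 7919L) %% 2000000000L
}
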