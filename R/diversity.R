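## Alpha- and beta-diversity analytics: Shannon and inverse Simpson with
## covariate-adjusted log-linear regression, Bray-Curtis dissimilarity,
## principal coordinates, PERMANOVA with partial omega-squared effect
## sizes, and group dispersion.

#' Alpha diversity of one or more samples
#'
#' Shannon entropy H = -sum p_i log p_i (natural log by default), inverse
#' Simpson D = 1 / sum p_i^2 (effective species number), and richness
#' (count of features with non-zero abundance). Vectors are renormalised to
#' proportions internally, so the indices are invariant to rescaling a
#' sample by a positive constant.
#'
#' @param x non-negative abundance vector, or samples x features matrix.
#' @param base logarithm base for Shannon (default `exp(1)`, i.e. nats).
#' @return for a vector, a one-row data.frame with `shannon`,
#'   `inv_simpson`, `richness`; for a matrix, one row per sample.
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  if (is.matrix(x)) {
    out <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) alpha_diversity(x[i, ], base = base)))
    rownames(out) <- rownames(x)
    return(out)
  }
  if (any(x < 0)) stop_domain("abundances must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop_domain("all-zero abundance vector")
  p <- x[x > 0] / tot
  data.frame(shannon = -sum(p * log(p, base = base)),
             inv_simpson = 1 / sum(p^2),
             richness = sum(x > 0))
}

#' Covariate-adjusted regression of log alpha diversity
#'
#' Ordinary least squares with the natural log of the diversity index as
#' response. Exposure coefficients are reported as percent differences,
#' 100 x (exp(beta) - 1), with Wald confidence intervals on the same scale
#' (the scale used for reporting diversity shifts between consumption
#' groups).
#'
#' @param alpha positive numeric vector of index values.
#' @param exposure exposure vector (numeric or factor).
#' @param covariates optional data.frame of adjustment covariates (the
#'   analysis set typically includes sequencing depth).
#' @param level confidence level.
#' @return data.frame with one row per exposure coefficient: `term`,
#'   `pct_diff`, `ci_low`, `ci_high`, `p`; the `lm` fit as attribute "fit".
#' @export
alpha_regression <- function(alpha, exposure, covariates = NULL, level = 0.95) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop_domain("alpha indices must be positive to take logs")
  df <- data.frame(.expo = exposure)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  X <- build_design(df)
  fit <- lm(log(alpha) ~ X - 1)
  cf <- summary(fit)$coefficients
  rownames(cf) <- colnames(X)
  expo_terms <- grep("^\\.expo", colnames(X), value = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    term = sub("^\\.expo", "exposure", expo_terms),
    pct_diff = 100 * (exp(cf[expo_terms, 1]) - 1),
    ci_low = 100 * (exp(cf[expo_terms, 1] - z * cf[expo_terms, 2]) - 1),
    ci_high = 100 * (exp(cf[expo_terms, 1] + z * cf[expo_terms, 2]) - 1),
    p = cf[expo_terms, 4], row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i,j) = sum |x_i - x_j| / sum (x_i + x_j) over features; 0 for
#' identical samples, 1 for disjoint supports.
#'
#' @param mat non-negative samples x features matrix.
#' @return symmetric n x n matrix with zero diagonal and the sample IDs as
#'   dimnames.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop_domain("abundances must be non-negative")
  tot <- rowSums(mat)
  if (any(tot <= 0)) {
    bad <- rownames(mat)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stop_domain("sample(s) with zero total abundance: ", paste(bad, collapse = ", "))
  }
  man <- as.matrix(stats::dist(mat, method = "manhattan"))
  d <- man / outer(tot, tot, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

## Gower-centered matrix G = -(1/2) J D^2 J used by PCoA and PERMANOVA.
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  rm <- rowMeans(A); gm <- mean(A)
  A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower-centered squared-distance matrix.
#' Negative eigenvalues (possible for semi-metric dissimilarities such as
#' Bray-Curtis) are reported as-is, and only axes with positive eigenvalues
#' yield real coordinates.
#'
#' @param d distance/dissimilarity matrix.
#' @param k number of axes to return (<= n - 1).
#' @return list with `coordinates` (n x k, scaled by sqrt eigenvalue) and
#'   `eigenvalues` (all n, descending).
#' @export
pcoa <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n - 1L) stop_usage("k must be at most n - 1")
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  pos <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = e$values)
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA with partial omega-squared
#'
#' Distance-based permutational multivariate ANOVA for a single term of
#' interest, adjusted for covariates. Sums of squares are marginal: the
#' term's SS is the drop in explained (Gower-trace) variation when it is
#' removed from the full model. Significance uses permutation of residuals
#' under the reduced model (Freedman-Lane): the reduced-model residual
#' Gower matrix is permuted while the design is held fixed. Effect size is
#' the partial omega-squared
#' (SS_term - df_term * MS_resid) / (SS_total + MS_resid).
#'
#' @param d distance matrix (square symmetric, e.g. from [bray_curtis()]).
#' @param data data.frame aligned with the rows of `d`.
#' @param term name of the column tested.
#' @param covariates character vector of adjustment columns (may be empty).
#' @param n_perm number of permutations (default 999).
#' @param seed required RNG seed for the permutations (logged in output).
#' @return data.frame of class `permanova_result`: term, ss, df, pseudo_f,
#'   omega_sq, p_perm, n_perm, seed.
#' @export
permanova <- function(d, data, term, covariates = character(), n_perm = 999L, seed) {
  if (missing(seed)) stop_usage("a permutation seed is required")
  d <- as.matrix(d)
  n <- nrow(d)
  if (nrow(data) != n) stop_schema("design rows do not match the distance matrix")
  Xr <- build_design(data[, covariates, drop = FALSE])
  Xf <- build_design(data[, c(covariates, term), drop = FALSE])
  rk_f <- qr(Xf)$rank; rk_r <- qr(Xr)$rank
  df_term <- rk_f - rk_r
  if (df_term < 1L) stop_usage("term '", term, "' is aliased with the covariates")
  Hf <- hat_matrix(Xf); Hr <- hat_matrix(Xr)
  G <- gower_center(d)
  Hdiff <- Hf - Hr
  Rf <- diag(n) - Hf
  ss_term <- sum(Hdiff * G)
  ss_resid <- sum(Rf * G)
  df_resid <- n - rk_f
  ss_total <- sum(diag(G))
  ms_resid <- ss_resid / df_resid
  pseudo_f <- (ss_term / df_term) / ms_resid
  omega_sq <- (ss_term - df_term * ms_resid) / (ss_total + ms_resid)

  Rr <- diag(n) - Hr
  Gr <- Rr %*% G %*% Rr   # reduced-model residual variation
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- Gr[p, p]
    f_p <- (sum(Hdiff * Gp) / df_term) / (sum(Rf * Gp) / df_resid)
    if (f_p >= pseudo_f - 1e-12) exceed <- exceed + 1L
  }
  p_perm <- (1 + exceed) / (n_perm + 1)
  structure(data.frame(term = term, ss = ss_term, df = df_term,
                       pseudo_f = pseudo_f, omega_sq = omega_sq,
                       p_perm = p_perm, n_perm = as.integer(n_perm),
                       seed = as.integer(seed), stringsAsFactors = FALSE),
            class = c("permanova_result", "data.frame"))
}

#' Group dispersion around centroids
#'
#' Distances of each sample to its own group centroid in principal
#' coordinate space (negative eigenvalue axes handled with the usual
#' imaginary-part correction, as in multivariate dispersion analysis).
#' Groups are summarised by the median distance; the permutation test
#' shuffles group labels of the distances and compares the sum of absolute
#' deviations of group medians from the overall median.
#'
#' @param d distance matrix.
#' @param groups factor of group labels (>= 2 groups, each with >= 2
#'   members).
#' @param n_perm label permutations for the test.
#' @param seed RNG seed.
#' @return list with `distances` (per sample), `medians` (per group) and
#'   `p_perm`.
#' @export
dispersion <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_usage("need at least two groups")
  if (any(table(g) < 2L)) stop_usage("singleton group: ", paste(names(which(table(g) < 2L)), collapse = ", "))
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  C <- V %*% diag(sqrt(abs(lam)), length(lam))  # real & imaginary axes
  pos <- lam > 0
  dist2 <- numeric(nrow(d))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    cen <- colMeans(C[idx, , drop = FALSE])
    dif <- sweep(C[idx, , drop = FALSE], 2, cen)
    dist2[idx] <- dif[, pos, drop = FALSE]^2 %*% rep(1, sum(pos)) -
      (if (any(!pos)) dif[, !pos, drop = FALSE]^2 %*% rep(1, sum(!pos)) else 0)
  }
  dists <- sqrt(pmax(dist2, 0))
  med_stat <- function(x, grp) {
    m <- tapply(x, grp, median)
    sum(abs(m - median(x)))
  }
  obs <- med_stat(dists, g)
  set.seed(seed)
  perm <- replicate(n_perm, med_stat(dists, sample(g)))
  list(distances = setNames(dists, rownames(d)),
       medians = tapply(dists, g, median),
       statistic = obs,
       p_perm = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1))
}
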