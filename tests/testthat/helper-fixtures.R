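# Shared fixture builders. Everything is generated in code; no files.

# Small compositional matrix with no exposure structure (null world).
null_abundance <- function(n, m, seed = 1) {
  set.seed(seed)
  mu <- rnorm(m, 0, 1.5)
  mat <- matrix(rlnorm(n * m, rep(mu, each = n), 1), n, m)
  mat <- 100 * mat / rowSums(mat)
  dimnames(mat) <- list(paste0("s", seq_len(n)), paste0("sp", seq_len(m)))
  mat
}

# Zero-inflated right-skewed intake like the emulated cohort.
null_exposure <- function(n, seed = 1) {
  set.seed(seed)
  log2(ifelse(runif(n) < 0.13, 0, rlnorm(n, log(9), 1.3)) + 1)
}

# Brute-force BH step-up oracle: q_(i) = min_{j >= i} min(1, p_(j) m / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) min(1, p[o[j]] * (m / j)), numeric(1)))
  }
  q
}

# Brute-force Bray-Curtis over an explicit double loop.
bray_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(mat))) {
      num <- num + abs(mat[i, k] - mat[j, k])
      den <- den + mat[i, k] + mat[j, k]
    }
    d[i, j] <- num / den
  }
  d
}

# One-factor PERMANOVA pseudo-F from the classic between/within
# decomposition of squared distances (no Gower matrix involved).
permanova_oracle_f <- function(d, g) {
  n <- nrow(d); g <- factor(g)
  d2 <- d^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (nlevels(g) - 1)) / (ss_w / (n - nlevels(g)))
}

# Draw a 3-category multinomial outcome with known contrast log-odds.
draw_multinomial <- function(n, x, w, b2, b3, seed = 1) {
  set.seed(seed)
  lp2 <- b2[1] + b2[2] * x + b2[3] * w
  lp3 <- b3[1] + b3[2] * x + b3[3] * w
  den <- 1 + exp(lp2) + exp(lp3)
  u <- runif(n)
  p3 <- exp(lp3) / den; p2 <- exp(lp2) / den
  factor(ifelse(u < p3, "advanced", ifelse(u < p3 + p2, "adenoma", "control")),
         levels = c("control", "adenoma", "advanced"))
}
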