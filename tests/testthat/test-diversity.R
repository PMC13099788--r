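test_that("alpha diversity matches closed forms", {
  u <- rep(1, 10)
  a <- alpha_diversity(u)
  expect_equal(a$shannon, log(10), tolerance = 1e-12)
  expect_equal(a$inv_simpson, 10, tolerance = 1e-12)
  expect_equal(a$richness, 10)

  s <- c(5, 0, 0)
  a1 <- alpha_diversity(s)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$inv_simpson, 1)

  p <- c(0.5, 0.25, 0.25)
  a2 <- alpha_diversity(p)
  expect_equal(a2$shannon, 1.5 * log(2), tolerance = 1e-12)
  expect_equal(a2$inv_simpson, 1 / 0.375, tolerance = 1e-12)

  # invariant to rescaling by a positive constant
  expect_equal(alpha_diversity(p * 731), a2)
  # log base flag
  expect_equal(alpha_diversity(u, base = 2)$shannon, log2(10))
  expect_error(alpha_diversity(c(0, 0)), class = "alcomediome_domain_error")
})

test_that("alpha regression recovers a known percent shift and calibrates", {
  set.seed(21)
  n <- 2000
  grp <- rbinom(n, 1, 0.6)
  idx <- exp(log(3) + log(1.027) * grp + rnorm(n, 0, 0.2))
  res <- alpha_regression(idx, grp)
  expect_lt(res$ci_low, 2.7)
  expect_gt(res$ci_high, 2.7)
  expect_lt(abs(res$pct_diff - 2.7), 2)

  # null calibration
  rej <- 0L
  for (s in 1:200) {
    set.seed(3000 + s)
    g <- rbinom(200, 1, 0.5)
    y <- exp(rnorm(200))
    rej <- rej + (alpha_regression(y, g)$p < 0.05)
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)
  expect_error(alpha_regression(c(1, 0, 2), rnorm(3)),
               class = "alcomediome_domain_error")
})

test_that("orthogonal exposure leaves residual variance unchanged", {
  set.seed(22)
  n <- 400
  z <- rnorm(n)
  # exposure exactly orthogonal to the intercept and to z
  x <- unname(resid(lm(rep(c(-1, 1), n / 2) ~ z)))
  y <- exp(0.3 * z + rnorm(n, 0, 0.1))
  full <- attr(alpha_regression(y, x, data.frame(z = z)), "fit")
  covonly <- lm(log(y) ~ z)
  # orthogonality: adding x cannot change z's coefficient
  expect_equal(unname(coef(full)[grep("z", names(coef(full)))]),
               unname(coef(covonly)["z"]), tolerance = 1e-10)
})

test_that("Bray-Curtis matches hand values and the double-loop oracle", {
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 3)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))["a", "b"], 1 / 3,
               tolerance = 1e-15)
  set.seed(23)
  for (i in 1:5) {
    m <- matrix(rexp(100), 10, 10)
    expect_equal(unname(bray_curtis(m)), bray_oracle(m), tolerance = 1e-12)
  }
  m2 <- rbind(a = c(1, 1), b = c(0, 0))
  expect_error(bray_curtis(m2), "b")
})

test_that("PCoA recovers Euclidean configurations and spectral identities", {
  set.seed(24)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts))
  pc <- pcoa(d, k = 2)
  # distances among recovered coordinates equal the originals (rotation-proof)
  expect_equal(as.matrix(dist(pc$coordinates)), d,
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalue sum equals the trace of the centered Gower matrix
  G <- alcomediome:::gower_center(d)
  expect_equal(sum(pc$eigenvalues), sum(diag(G)), tolerance = 1e-8)
  # identical samples embed identically
  m <- null_abundance(6, 10, seed = 25)
  m[2, ] <- m[1, ]
  pc2 <- pcoa(bray_curtis(m), k = 2)
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ], tolerance = 1e-10)
  expect_error(pcoa(d, k = 12), class = "alcomediome_usage_error")
})

test_that("PERMANOVA pseudo-F equals the decomposition oracle and p respects bounds", {
  set.seed(26)
  m <- null_abundance(24, 15, seed = 26)
  g <- factor(rep(1:3, each = 8))
  d <- bray_curtis(m)
  res <- permanova(d, data.frame(g = g), "g", n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f, permanova_oracle_f(d, g), tolerance = 1e-10)
  expect_gte(res$p_perm, 1 / 100)
  expect_lte(res$p_perm, 1)
  # strong group structure is detected
  m2 <- m; m2[g == 1, 1:5] <- m2[g == 1, 1:5] + 40
  m2 <- 100 * m2 / rowSums(m2)
  res2 <- permanova(bray_curtis(m2), data.frame(g = g), "g", n_perm = 999, seed = 2)
  expect_lte(res2$p_perm, 0.01)
  expect_gt(res2$omega_sq, 0.05)
  # aliased term
  expect_error(permanova(d, data.frame(g = g, g2 = g), "g2",
                         covariates = "g", n_perm = 9, seed = 1),
               class = "alcomediome_usage_error")
})

test_that("PERMANOVA permutation seed is logged and reproducible", {
  m <- null_abundance(20, 10, seed = 27)
  g <- factor(rep(1:2, each = 10))
  d <- bray_curtis(m)
  r1 <- permanova(d, data.frame(g = g), "g", n_perm = 199, seed = 7)
  r2 <- permanova(d, data.frame(g = g), "g", n_perm = 199, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$seed, 7L)
  expect_error(permanova(d, data.frame(g = g), "g"),
               class = "alcomediome_usage_error")
})

test_that("null omega-squared is centered near zero", {
  set.seed(28)
  om <- numeric(40)
  for (s in 1:40) {
    m <- null_abundance(150, 30, seed = 400 + s)
    g <- factor(rep(1:2, each = 75))
    om[s] <- permanova(bray_curtis(m), data.frame(g = g), "g",
                       n_perm = 19, seed = s)$omega_sq
  }
  expect_lt(mean(abs(om)), 0.005)
})

test_that("dispersion summarises distance-to-centroid structure", {
  # a group of identical samples has zero median distance
  m <- null_abundance(8, 12, seed = 29)
  m[5:8, ] <- m[rep(5, 4), ]
  g <- factor(rep(c("a", "b"), each = 4))
  res <- dispersion(bray_curtis(m), g, n_perm = 99, seed = 1)
  expect_equal(unname(res$medians["b"]), 0, tolerance = 1e-12)
  expect_error(dispersion(bray_curtis(m), factor(c("a", rep("b", 7)))),
               class = "alcomediome_usage_error")

  # tighter simulated group detected at n = 200
  set.seed(30)
  base <- matrix(rlnorm(100 * 20, 0, 1), 100, 20)
  tight <- matrix(rlnorm(100 * 20, 0, 0.2), 100, 20)
  mm <- rbind(base, tight)
  mm <- 100 * mm / rowSums(mm)
  rownames(mm) <- paste0("s", 1:200)
  gg <- factor(rep(c("loose", "tight"), each = 100))
  r2 <- dispersion(bray_curtis(mm), gg, n_perm = 199, seed = 2)
  expect_lt(unname(r2$medians["tight"]), unname(r2$medians["loose"]))
  expect_lte(r2$p_perm, 0.05)
})

test_that("dispersion p-values are roughly uniform when groups share a distribution", {
  set.seed(31)
  pv <- numeric(100)
  for (s in 1:100) {
    m <- null_abundance(30, 12, seed = 600 + s)
    g <- factor(rep(1:2, each = 15))
    pv[s] <- dispersion(bray_curtis(m), g, n_perm = 99, seed = s)$p_perm
  }
  expect_lte(mean(pv <= 0.05), 0.12)
  # permutation p-values are discrete (99 atoms); the KS tie warning is
  # expected and harmless at this lenient threshold
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.001)
})
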