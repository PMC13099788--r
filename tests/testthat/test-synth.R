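test_that("generated cohorts match the configured marginals", {
  cfg <- synth_config(n_participants = 2000, seed = 1)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch), 2000L)
  # zero-consumer fraction within +/- 2 percentage points of 0.13
  expect_lt(abs(mean(ch$alcohol_g_day == 0) - 0.13), 0.02)
  # consumer median near 9 g/day, men above women
  cons <- ch$alcohol_g_day > 0
  expect_lt(abs(median(ch$alcohol_g_day[cons]) - 9) / 9, 0.2)
  expect_gt(median(ch$alcohol_g_day[cons & ch$sex == "male"]),
            median(ch$alcohol_g_day[cons & ch$sex == "female"]))
  # women are more often non-consumers
  expect_gt(mean(ch$alcohol_g_day[ch$sex == "female"] == 0),
            mean(ch$alcohol_g_day[ch$sex == "male"] == 0))
  expect_true(all(ch$age >= 55 & ch$age <= 77))
})

test_that("degenerate mixtures and invalid configs behave as specified", {
  cfg <- synth_config(n_participants = 50, prop_nonconsumers = 1.0, seed = 2)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$alcohol_g_day == 0))
  expect_error(synth_config(prop_nonconsumers = 1.3), "prop_nonconsumers")
  expect_error(synth_config(n_species = -5), "n_species")
  expect_error(synth_config(sd_richness = 0), "sd_richness")
  expect_error(synth_config(n_species = 10, n_assoc_taxa_pos = 6,
                            n_assoc_taxa_neg = 6), "n_assoc")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synth_config(n_participants = 80, n_species = 60, seed = 7)
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  a1 <- generate_abundances(c1, cfg); a2 <- generate_abundances(c2, cfg)
  expect_identical(a1, a2)
  s1 <- simulate_study(cfg); s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
})

test_that("abundances are compositional with the configured richness", {
  cfg <- synth_config(n_participants = 1000, seed = 3)
  ch <- generate_cohort(cfg)
  ab <- generate_abundances(ch, cfg)
  expect_equal(unname(rowSums(ab)), rep(100, 1000), tolerance = 1e-9)
  rich <- rowSums(ab > 0)
  expect_gte(mean(rich), 85)
  expect_lte(mean(rich), 91)
  expect_error(generate_abundances(ch[, setdiff(names(ch), "alcohol_g_day")], cfg),
               class = "alcomediome_schema_error")
})

test_that("beta_taxa = 0 leaves the designated taxa unlinked to alcohol", {
  cfg <- synth_config(n_participants = 2000, beta_taxa = 0, seed = 4)
  ch <- generate_cohort(cfg)
  ab <- generate_abundances(ch, cfg)
  rs <- vapply(c(attr(ab, "taxa_pos"), attr(ab, "taxa_neg")), function(taxon)
    suppressWarnings(cor(ab[, taxon], ch$alcohol_g_day, method = "spearman")),
    numeric(1))
  # each correlation within a 3.3-SD null band, and small on average
  expect_lt(max(abs(rs)), qnorm(0.9995) / sqrt(2000))
  expect_lt(mean(abs(rs)), 0.05)
})

test_that("outcome generation encodes the causal diagram with exact truth limits", {
  cfg0 <- synth_config(n_participants = 1500, beta_direct = 0, gamma_score = 0, seed = 5)
  sim0 <- simulate_study(cfg0)
  expect_equal(sim0$truth$total_effect, 0, tolerance = 1e-12)
  expect_true(is.na(sim0$truth$prop_mediated))

  cfgg <- synth_config(n_participants = 1500, gamma_score = 0, seed = 6)
  simg <- simulate_study(cfgg)
  expect_equal(simg$truth$acme, 0, tolerance = 1e-15)

  cfgd <- synth_config(n_participants = 1500, beta_direct = 0, seed = 7)
  simd <- simulate_study(cfgd)
  expect_equal(simd$truth$prop_mediated, 1, tolerance = 1e-12)

  cfg <- synth_config(n_participants = 1500, seed = 8)
  sim <- simulate_study(cfg)
  expect_lt(abs(mean(sim$cohort$advanced) - cfg$baseline_prev_advanced), 0.04)
  expect_equal(sim$truth$total_effect, sim$truth$acme + sim$truth$ade,
               tolerance = 1e-12)
  expect_error(generate_outcome(sim$cohort, sim$score[-1], cfg),
               class = "alcomediome_usage_error")
})

test_that("analytic truth agrees with a brute-force Bernoulli counterfactual oracle", {
  cfg <- synth_config(n_participants = 800, seed = 9)
  sim <- simulate_study(cfg)
  tr <- sim$truth
  ch <- sim$cohort
  l2a <- log2(ch$alcohol_g_day + 1)
  covpart <- cfg$beta_sex * (ch$sex == "male") + cfg$beta_age * (ch$age - 67)
  lp <- function(a_shift, m) tr$alpha + cfg$beta_direct * (l2a + a_shift) +
    cfg$gamma_score * m + covpart
  # common uniforms couple the four potential-outcome arms, so the
  # difference-of-frequencies estimator has tiny Monte-Carlo variance
  set.seed(99)
  nmc <- 400
  u <- matrix(runif(length(l2a) * nmc), length(l2a), nmc)
  draw <- function(a_shift, m) mean(u < plogis(lp(a_shift, m)))
  acme_mc <- ((draw(1, sim$score_cf) - draw(1, sim$score)) +
              (draw(0, sim$score_cf) - draw(0, sim$score))) / 2
  expect_lt(abs(acme_mc - tr$acme), 4e-4)  # ~4 Monte-Carlo SEs
})

test_that("generated tables survive a disk round trip", {
  cfg <- synth_config(n_participants = 20, n_species = 15, seed = 10)
  sim <- simulate_study(cfg)
  tmp <- tempfile(fileext = ".tsv")
  write_abundance(sim$abundances, tmp)
  back <- read_abundance(tmp)
  expect_equal(back, sim$abundances, tolerance = 1e-12, ignore_attr = TRUE)
})
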