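# Shared synthetic study for several blocks (moderate n keeps this fast).
sim_med <- simulate_study(synth_config(n_participants = 1200, seed = 31))
dat_med <- within(sim_med$cohort, {
  l2a <- log2_alcohol(alcohol_g_day)
  score <- sim_med$score
})

test_that("mediator model recovers the generating slope and flags degeneracies", {
  med <- fit_mediator_model(dat_med, "score", "l2a", c("sex", "age"))
  # structural slope: 2 * beta_taxa natural-log units per doubling
  expect_lt(abs(med$exposure_coef - 2 * sim_med$config$beta_taxa),
            3 * med$se[["l2a"]])
  expect_gt(med$sigma, 0)

  d2 <- dat_med; d2$score <- rep(1, nrow(d2))
  expect_error(fit_mediator_model(d2, "score", "l2a"),
               class = "alcomediome_domain_error")
  d3 <- dat_med; d3$l2a_copy <- d3$l2a
  expect_error(fit_mediator_model(d3, "score", "l2a", "l2a_copy"), "l2a_copy")
})

test_that("mediator slope is null-calibrated under permuted exposure", {
  covered <- 0L
  for (s in 1:100) {
    set.seed(800 + s)
    d <- dat_med[sample(nrow(dat_med), 300), ]
    d$l2a <- sample(d$l2a)
    med <- fit_mediator_model(d, "score", "l2a")
    z <- med$exposure_coef / med$se[["l2a"]]
    covered <- covered + (abs(z) < qnorm(0.975))
  }
  expect_gte(covered, 88)
})

test_that("outcome model recovers generating coefficients and rejects misuse", {
  out <- fit_outcome_model(dat_med, "advanced", "l2a", "score", c("sex", "age"))
  expect_true(out$converged)
  se <- sqrt(diag(out$vcov))
  names(se) <- names(out$coef)
  expect_lt(abs(out$coef[["l2a"]] - sim_med$config$beta_direct), 3 * se[["l2a"]])
  expect_lt(abs(out$coef[["score"]] - sim_med$config$gamma_score), 3 * se[["score"]])
  d2 <- dat_med; d2$advanced <- d2$advanced + 1
  expect_error(fit_outcome_model(d2, "advanced", "l2a", "score"),
               class = "alcomediome_usage_error")
})

test_that("decomposition is additive and its integration methods agree", {
  med <- fit_mediator_model(dat_med, "score", "l2a", c("sex", "age"))
  out <- fit_outcome_model(dat_med, "advanced", "l2a", "score", c("sex", "age"))
  dq <- decompose(med, out, dat_med$l2a, method = "quadrature")
  expect_equal(dq$total_effect, dq$acme + dq$ade, tolerance = 1e-12)
  expect_equal(dq$total_effect, dq$acme_treated + dq$ade_control, tolerance = 1e-12)
  ds <- decompose(med, out, dat_med$l2a, method = "simulate", n_sim = 4000, seed = 32)
  expect_equal(ds$acme, dq$acme, tolerance = 5e-4)
  expect_equal(ds$total_effect, dq$total_effect, tolerance = 5e-4)
})

test_that("bootstrap CIs are deterministic under a fixed seed and contain the point estimate", {
  res1 <- mediate(dat_med, "advanced", "l2a", "score", covariates = c("sex", "age"),
                  n_boot = 120, seed = 33)
  res2 <- mediate(dat_med, "advanced", "l2a", "score", covariates = c("sex", "age"),
                  n_boot = 120, seed = 33)
  expect_identical(res1$ci_acme, res2$ci_acme)
  expect_identical(res1$ci_prop, res2$ci_prop)
  expect_true(res1$ci_acme[1] <= res1$acme && res1$acme <= res1$ci_acme[2])
  expect_true(res1$ci_total[1] <= res1$total_effect &&
              res1$total_effect <= res1$ci_total[2])
  expect_error(mediate(dat_med, "advanced", "l2a", "score", n_boot = 50),
               class = "alcomediome_usage_error")
})

test_that("quasi-Bayesian flag gives comparable intervals", {
  res_b <- mediate(dat_med, "advanced", "l2a", "score", covariates = c("sex", "age"),
                   n_boot = 150, seed = 34)
  res_q <- mediate(dat_med, "advanced", "l2a", "score", covariates = c("sex", "age"),
                   n_boot = 150, seed = 34, ci_method = "quasi-bayes")
  expect_lt(abs(res_q$acme - res_b$acme), 5e-3)
  # interval widths of the same order
  wb <- diff(res_b$ci_acme); wq <- diff(res_q$ci_acme)
  expect_lt(abs(log(wq / wb)), log(2.5))
})

test_that("rare-outcome linear limit matches the product-of-coefficients oracle", {
  cfg <- synth_config(n_participants = 6000, baseline_prev_advanced = 0.05,
                      beta_direct = 0.1, gamma_score = 0.15, seed = 35)
  sim <- simulate_study(cfg)
  d <- sim$cohort
  d$l2a <- log2_alcohol(d$alcohol_g_day)
  d$score <- sim$score
  med <- fit_mediator_model(d, "score", "l2a", c("sex", "age"))
  out <- fit_outcome_model(d, "advanced", "l2a", "score", c("sex", "age"))
  dc <- decompose(med, out, d$l2a, method = "quadrature")
  # in the rare-disease limit, ACME ~ (mediator slope) x (outcome mediator
  # coefficient) x E[p(1-p)]
  pfit <- plogis(drop(out$X %*% out$coef))
  oracle <- med$exposure_coef * out$coef[["score"]] * mean(pfit * (1 - pfit))
  expect_lt(abs(dc$acme - oracle) / abs(oracle), 0.10)
})

test_that("PM estimate rises monotonically with the mediated path strength", {
  pms <- vapply(c(0.0, 0.1, 0.3), function(g) {
    cfg <- synth_config(n_participants = 4000, gamma_score = g,
                        beta_direct = 0.12, seed = 36)
    sim <- simulate_study(cfg)
    d <- sim$cohort
    d$l2a <- log2_alcohol(d$alcohol_g_day)
    d$score <- sim$score
    med <- fit_mediator_model(d, "score", "l2a", c("sex", "age"))
    out <- fit_outcome_model(d, "advanced", "l2a", "score", c("sex", "age"))
    decompose(med, out, d$l2a, method = "quadrature")$prop_mediated
  }, numeric(1))
  expect_true(all(diff(pms) > 0))
})

test_that("omitting sex as covariate only shifts PM by a bounded amount", {
  res_full <- mediate(dat_med, "advanced", "l2a", "score",
                      covariates = c("sex", "age"), n_boot = 100, seed = 37)
  res_nosex <- mediate(dat_med, "advanced", "l2a", "score",
                       covariates = "age", n_boot = 100, seed = 37)
  expect_lt(abs(res_full$acme - res_nosex$acme), 0.01)
})
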