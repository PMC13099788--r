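## Synthetic cohort generator emulating a FIT-positive colorectal
## screening cohort with FFQ-derived alcohol intake, a compositional gut
## metagenome, and an advanced-lesion outcome whose alcohol effect is
## partly transmitted through a small set of alcohol-associated taxa.
## Ground-truth mediation effects are computed by counterfactual
## regeneration with common random numbers, so parameter-recovery tests
## have an oracle.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study population: ~13% zero consumers,
#' right-skewed consumer intake with overall median 9 g/day (men 13,
#' women 5, driven by a sex-specific location shift), 787 species with a
#' mean of 88 (SD 15.5) detected per sample, and a lesion outcome whose
#' total log-odds per twofold intake increase (~0.13) is ~12% mediated by
#' the designated alcohol-associated taxa.
#'
#' @param n_participants cohort size.
#' @param n_species number of species in the abundance matrix.
#' @param mean_richness,sd_richness per-sample detected-species count
#'   distribution (Normal, truncated at 1).
#' @param prop_nonconsumers overall fraction with zero alcohol intake.
#' @param median_intake_g median intake among consumers, grams/day.
#' @param sdlog_intake log-SD of the consumer lognormal (default 1.3, set
#'   from the emulated quartiles 2.2/9/19 g/day).
#' @param n_assoc_taxa_pos,n_assoc_taxa_neg numbers of taxa whose
#'   log-abundance is shifted up/down with alcohol.
#' @param beta_taxa per-taxon natural-log abundance shift per log2-unit
#'   (twofold) alcohol increase; the implied mediator shift per doubling
#'   is `2 * beta_taxa` log-ratio units.
#' @param beta_direct direct log-odds of advanced lesion per log2-unit
#'   alcohol.
#' @param gamma_score log-odds of advanced lesion per score unit.
#' @param baseline_prev_advanced marginal advanced-lesion prevalence the
#'   outcome intercept is calibrated to.
#' @param beta_sex,beta_age outcome log-odds for male sex and per year of
#'   age (mild confounding; sex also shifts alcohol).
#' @param sigma_species residual log-abundance SD per taxon.
#' @param prop_missing fraction of missingness injected into education,
#'   affiliation, family history, BMI and activity.
#' @param seed integer RNG seed; the same seed reproduces all tables
#'   bit-identically.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 1000L, n_species = 787L,
                         mean_richness = 88, sd_richness = 15.5,
                         prop_nonconsumers = 0.13, median_intake_g = 9,
                         sdlog_intake = 1.3,
                         n_assoc_taxa_pos = 5L, n_assoc_taxa_neg = 5L,
                         beta_taxa = 0.3, beta_direct = 0.115,
                         gamma_score = 0.027, baseline_prev_advanced = 0.28,
                         beta_sex = 0.2, beta_age = 0.03,
                         sigma_species = 1.0, prop_missing = 0.02,
                         seed = 1L) {
  cfg <- as.list(environment())
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop_config("invalid config field '", field, "': must be a positive count")
  }
  for (f in c("n_participants", "n_species", "n_assoc_taxa_pos", "n_assoc_taxa_neg"))
    chk_count(f)
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_config("invalid config field '", field, "': must be a positive number")
  }
  for (f in c("mean_richness", "sd_richness", "median_intake_g",
              "sdlog_intake", "sigma_species"))
    chk_pos(f)
  for (f in c("prop_nonconsumers", "baseline_prev_advanced", "prop_missing")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_config("invalid config field '", f, "': must be a fraction in [0, 1]")
  }
  if (cfg$n_assoc_taxa_pos + cfg$n_assoc_taxa_neg > cfg$n_species)
    stop_config("invalid config: n_assoc_taxa_pos + n_assoc_taxa_neg exceeds n_species")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_config("invalid config field 'seed'")
  structure(cfg, class = "synth_config")
}

## Sex-specific zero-consumption probabilities with women:men pattern
## ~18:8 (relative to the overall fraction), calibrated so the expected
## overall zero fraction equals prop_nonconsumers at the expected sex mix.
zero_probs <- function(prop, p_male = 0.556) {
  if (prop >= 1) return(c(male = 1, female = 1))
  rho <- c(male = 8 / 13, female = 18 / 13)
  cc <- prop / unname(p_male * rho["male"] + (1 - p_male) * rho["female"])
  p <- pmin(1, cc * rho)
  names(p) <- names(rho)
  if (p[["female"]] >= 1) p[["male"]] <- min(1, max(0, (prop - (1 - p_male)) / p_male))
  setNames(as.numeric(p), c("male", "female"))
}

## Scale factor s such that the consumer intake mixture (sex medians
## proportional to 13:5) has overall median equal to target.
consumer_scale <- function(target, sdlog, w_male) {
  f <- function(s) {
    w_male * pnorm((log(target) - log(13 * s)) / sdlog) +
      (1 - w_male) * pnorm((log(target) - log(5 * s)) / sdlog) - 0.5
  }
  uniroot(f, c(1e-3, 1e3))$root
}

#' Generate a synthetic screening cohort
#'
#' One row per participant with demographics, lifestyle covariates (raw
#' questionnaire-style fields consumed by [derive_covariates()]), energy
#' intake, per-beverage alcohol intakes and total ethanol in grams/day.
#' Alcohol is a two-part mixture: zero with a sex-specific probability
#' (women more often non-consumers), otherwise lognormal with a
#' sex-specific location shift (men > women) calibrated so the consumer
#' median matches the configuration.
#'
#' @param config a [synth_config()].
#' @return data.frame with `participant_id` first.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n <- config$n_participants
  set.seed(child_seed(config$seed, 11L))
  sex <- ifelse(runif(n) < 0.556, "male", "female")
  age <- pmin(77, pmax(55, round(rnorm(n, 67, 5.5))))
  centre <- ifelse(runif(n) < 0.52, "centre1", "centre2")
  affiliation <- ifelse(runif(n) < 0.943, "norwegian", "non_norwegian")
  education <- sample(c("primary", "high_school", "university"), n, replace = TRUE,
                      prob = c(0.17, 0.40, 0.43))
  family_history <- ifelse(runif(n) < 0.19, "yes", "no")
  smoking_user <- sample(c("regular", "occasional", "former", "never"), n,
                         replace = TRUE, prob = c(0.13, 0.05, 0.32, 0.50))
  smoking_quit_years <- ifelse(smoking_user == "former", round(runif(n, 0, 35)), NA_real_)
  snus_user <- sample(c("regular", "occasional", "former", "never"), n,
                      replace = TRUE, prob = c(0.05, 0.02, 0.05, 0.88))
  snus_quit_years <- ifelse(snus_user == "former", round(runif(n, 0, 35)), NA_real_)
  height_cm <- round(rnorm(n, ifelse(sex == "male", 179, 166), 6.5), 1)
  weight_kg <- round(rnorm(n, 26.5, 3.5) * (height_cm / 100)^2, 1)
  moderate_min_week <- pmax(0, round(rnorm(n, 120, 90) / 15) * 15)
  vigorous_min_week <- pmax(0, round(rnorm(n, 30, 45) / 15) * 15)

  ## two-part alcohol model
  p0 <- zero_probs(config$prop_nonconsumers)
  is_zero <- runif(n) < p0[sex]
  s <- if (config$prop_nonconsumers < 1)
    consumer_scale(config$median_intake_g, config$sdlog_intake, w_male = 0.60)
  else 1
  meanlog <- ifelse(sex == "male", log(13 * s), log(5 * s))
  alcohol_g_day <- ifelse(is_zero, 0, rlnorm(n, meanlog, config$sdlog_intake))

  ## beverage split (consumers only): men beer-heavy, women wine-heavy
  alpha <- cbind(beer = ifelse(sex == "male", 4, 1),
                 wine = ifelse(sex == "male", 2, 4.5),
                 spirits = 0.7,
                 drinks = ifelse(sex == "male", 0.3, 0.5))
  gmat <- matrix(stats::rgamma(n * 4, shape = as.vector(alpha)), n, 4)
  prop <- gmat / rowSums(gmat)
  bev <- prop * alcohol_g_day
  colnames(bev) <- c("beer_g_day", "wine_g_day", "spirits_g_day", "drinks_g_day")
  nonalc_g_day <- ifelse(runif(n) < 0.26, rlnorm(n, log(80), 1), 0)

  ## energy intake, weakly coupled to alcohol
  energy_kcal_day <- round(rlnorm(n, ifelse(sex == "male", log(2250), log(1900)) +
                                    0.04 * log2(alcohol_g_day + 1), 0.20))

  df <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                   age = age, sex = sex, centre = centre,
                   affiliation = affiliation, education = education,
                   family_history = family_history,
                   smoking_user = smoking_user,
                   smoking_quit_years = smoking_quit_years,
                   snus_user = snus_user, snus_quit_years = snus_quit_years,
                   height_cm = height_cm, weight_kg = weight_kg,
                   moderate_min_week = moderate_min_week,
                   vigorous_min_week = vigorous_min_week,
                   energy_kcal_day = energy_kcal_day,
                   alcohol_g_day = alcohol_g_day, bev,
                   nonalc_g_day = nonalc_g_day,
                   stringsAsFactors = FALSE)

  ## inject missingness into the fields the pipeline must handle
  if (config$prop_missing > 0) {
    for (col in c("education", "affiliation", "family_history")) {
      hit <- runif(n) < config$prop_missing
      df[[col]][hit] <- NA
    }
    for (col in c("weight_kg", "moderate_min_week")) {
      hit <- runif(n) < config$prop_missing
      df[[col]][hit] <- NA
    }
  }
  df
}

#' Generate a compositional species abundance matrix
#'
#' Per-sample presence is drawn so realised richness follows
#' Normal(`mean_richness`, `sd_richness`) truncated at 1; species are
#' sampled without replacement with species-specific occupancy weights
#' (the designated alcohol-associated taxa are up-weighted so they are
#' essentially always detected). Abundances of present taxa come from a
#' lognormal model whose log-mean is shifted by `+/- beta_taxa *
#' log2(alcohol + 1)` for the designated taxa; every sample is
#' renormalised to sum to 100.
#'
#' Given the same config seed, the randomness is independent of the
#' alcohol values, so regenerating with counterfactual intakes yields
#' exact common-random-number counterfactual abundances.
#'
#' @param cohort a [generate_cohort()] table (needs `alcohol_g_day`).
#' @param config the same [synth_config()].
#' @return samples x species matrix (rows sum to 100) with attributes
#'   `taxa_pos`, `taxa_neg` naming the designated taxa.
#' @export
generate_abundances <- function(cohort, config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  if (!"alcohol_g_day" %in% names(cohort))
    stop_schema("cohort lacks an alcohol_g_day column")
  n <- nrow(cohort)
  m <- config$n_species
  set.seed(child_seed(config$seed, 22L))
  species <- sprintf("sp_%04d", seq_len(m))
  npos <- config$n_assoc_taxa_pos; nneg <- config$n_assoc_taxa_neg
  taxa_pos <- species[seq_len(npos)]
  taxa_neg <- species[npos + seq_len(nneg)]
  shift <- c(rep(config$beta_taxa, npos), rep(-config$beta_taxa, nneg),
             rep(0, m - npos - nneg))
  mu <- rnorm(m, 0, 1.5)
  ## designated taxa: fixed typical baseline so they stay a small share of
  ## total abundance -- the alcohol signal must not swamp the composition
  ## (the generator's contract is a SMALL set of shifted taxa, and a large
  ## mass shift would leak into every other taxon through renormalisation)
  mu[seq_len(npos + nneg)] <- 0
  w <- exp(mu / 2 + rnorm(m, 0, 0.5))
  w[seq_len(npos + nneg)] <- max(w) * 2    # near-ubiquitous presence
  rich <- pmin(m, pmax(1L, round(rnorm(n, config$mean_richness, config$sd_richness))))
  l2a <- log2(cohort$alcohol_g_day + 1)
  X <- matrix(0, n, m, dimnames = list(cohort$participant_id, species))
  for (i in seq_len(n)) {
    pres <- sample.int(m, rich[i], prob = w)
    lx <- mu[pres] + shift[pres] * l2a[i] + rnorm(rich[i], 0, config$sigma_species)
    X[i, pres] <- exp(lx)
  }
  X <- 100 * X / rowSums(X)
  attr(X, "taxa_pos") <- taxa_pos
  attr(X, "taxa_neg") <- taxa_neg
  X
}

## Ground-truth per-sample score from the designated taxa.
truth_score <- function(abund, pseudo = 1e-4) {
  tp <- attr(abund, "taxa_pos"); tn <- attr(abund, "taxa_neg")
  vapply(seq_len(nrow(abund)), function(i)
    gevers_score(abund[i, ], tp, tn, pseudo = pseudo), numeric(1))
}

#' Generate the advanced-lesion outcome with ground-truth mediation
#'
#' Draws the advanced-lesion indicator from
#' `logit(p) = alpha + beta_direct * log2(alcohol + 1) + gamma_score *
#' score + beta_sex * male + beta_age * (age - 67)`, with `alpha`
#' calibrated numerically so the marginal prevalence equals
#' `baseline_prev_advanced`. Non-advanced participants are split into
#' non-advanced adenoma and controls (with a weak alcohol effect on
#' adenoma, mirroring the near-null association in screening data).
#'
#' The true ACME/ADE/total effect at the twofold contrast (`a1 = a0 + 1`
#' on the log2 scale) are computed by numerically integrating the
#' potential-outcome definitions over the simulated covariate
#' distribution, using the counterfactual score `score_cf` when supplied
#' (exact, from common-random-number regeneration) or the analytic
#' mediator shift `2 * beta_taxa` per doubling otherwise.
#'
#' @param cohort cohort table.
#' @param score per-sample mediator values aligned to `cohort` rows.
#' @param config the [synth_config()].
#' @param score_cf optional counterfactual score at doubled intake.
#' @return `cohort` with columns `advanced`, `diagnostic_group`; the truth
#'   (`acme`, `ade`, `total_effect`, `prop_mediated`, `alpha`) in
#'   attribute "truth".
#' @export
generate_outcome <- function(cohort, score, config, score_cf = NULL) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n <- nrow(cohort)
  if (length(score) != n) stop_usage("score not aligned with cohort rows (", length(score), " vs ", n, ")")
  if (!is.null(score_cf) && length(score_cf) != n)
    stop_usage("score_cf not aligned with cohort rows")
  set.seed(child_seed(config$seed, 33L))
  l2a <- log2(cohort$alcohol_g_day + 1)
  covpart <- config$beta_sex * (cohort$sex == "male") +
    config$beta_age * (cohort$age - 67)
  rest <- config$beta_direct * l2a + config$gamma_score * score + covpart
  alpha <- uniroot(function(a) mean(plogis(a + rest)) - config$baseline_prev_advanced,
                   c(-30, 30))$root
  p_adv <- plogis(alpha + rest)
  advanced <- rbinom(n, 1, p_adv)
  p_aden <- plogis(stats::qlogis(0.49) + 0.03 * l2a)
  adenoma <- advanced == 0 & runif(n) < p_aden
  group <- ifelse(advanced == 1, "advanced_lesion",
                  ifelse(adenoma, "non_advanced_adenoma", "control"))
  out <- cohort
  out$advanced <- advanced
  out$diagnostic_group <- diagnostic_group(group)

  M0 <- score
  M1 <- if (is.null(score_cf)) score + 2 * config$beta_taxa else score_cf
  pfun <- function(a_shift, m) mean(plogis(alpha + config$beta_direct * (l2a + a_shift) +
                                             config$gamma_score * m + covpart))
  y11 <- pfun(1, M1); y10 <- pfun(1, M0); y00 <- pfun(0, M0); y01 <- pfun(0, M1)
  acme <- ((y11 - y10) + (y01 - y00)) / 2
  ade <- ((y10 - y00) + (y11 - y01)) / 2
  total <- acme + ade
  attr(out, "truth") <- list(
    acme = acme, ade = ade, total_effect = total,
    prop_mediated = if (abs(total) < 1e-12) NA_real_ else acme / total,
    alpha = alpha, contrast = c(delta = 1))
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_abundances()] (plus an exact common-random-number
#' counterfactual regeneration at doubled intake), the designated-taxa
#' score, and [generate_outcome()].
#'
#' @param config a [synth_config()].
#' @param pseudo pseudo-count for the ground-truth score.
#' @return list with `cohort` (including outcome columns), `abundances`,
#'   `score`, `score_cf`, `taxa_pos`, `taxa_neg`, `truth`, `config`.
#' @export
simulate_study <- function(config, pseudo = 1e-4) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  cohort <- generate_cohort(config)
  ab <- generate_abundances(cohort, config)
  cohort_cf <- cohort
  cohort_cf$alcohol_g_day <- 2 * (cohort$alcohol_g_day + 1) - 1  # doubling on log2(g+1)
  ab_cf <- generate_abundances(cohort_cf, config)
  sc <- truth_score(ab, pseudo = pseudo)
  sc_cf <- truth_score(ab_cf, pseudo = pseudo)
  cohort <- generate_outcome(cohort, sc, config, score_cf = sc_cf)
  list(cohort = cohort, abundances = ab, score = sc, score_cf = sc_cf,
       taxa_pos = attr(ab, "taxa_pos"), taxa_neg = attr(ab, "taxa_neg"),
       truth = attr(cohort, "truth"), config = config)
}
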