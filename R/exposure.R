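## Exposure derivation: alcohol variables, energy-intake exclusions and
## covariate codings used throughout the pipeline.

#' Kilocalories per gram of ethanol (standard nutrition constant)
#' @export
ETHANOL_KCAL_PER_G <- 7

#' Grams of ethanol per alcohol unit (Norwegian convention)
#' @export
GRAMS_PER_UNIT <- 12

#' Alcohol intake as energy percentage (E%)
#'
#' Fraction of total daily energy contributed by ethanol, in percent, using
#' 7 kcal per gram of ethanol.
#'
#' @param ethanol_g_day ethanol intake, grams/day (non-negative).
#' @param energy_kcal_day total energy intake, kcal/day (strictly positive).
#' @return numeric vector of energy percentages.
#' @export
ethanol_energy_pct <- function(ethanol_g_day, energy_kcal_day) {
  if (any(ethanol_g_day < 0, na.rm = TRUE)) stop_domain("ethanol intake must be non-negative")
  if (any(energy_kcal_day <= 0, na.rm = TRUE)) stop_domain("energy intake must be positive")
  100 * (ethanol_g_day * ETHANOL_KCAL_PER_G) / energy_kcal_day
}

#' Classify alcohol exposure
#'
#' Derives the exposure variables used by the association and microbiome
#' analyses from ethanol intake in grams/day:
#' * `level`: consumption category with cutpoints at 0, 10 and 20 g/day
#'   (`zero`, `gt0_lt10` for >0 and <10, `ge10_lt20` for \[10, 20),
#'   `ge20` for >= 20). Boundaries are right-open at 10 and 20.
#' * `adherence` to national guidelines, sex-specific: full adherence is
#'   zero intake; partial is below 10 g/day for women and below 20 g/day
#'   for men; non-adherence is at or above that sex-specific threshold.
#' * `units_day`: alcohol units per day, one unit = 12 g ethanol.
#' * `consumer`: any non-zero intake.
#'
#' Classification is done on unrounded gram values.
#'
#' @param ethanol_g_day non-negative ethanol intake, grams/day.
#' @param sex `"male"`/`"female"` (or a factor with those levels), recycled.
#' @return data.frame with columns `ethanol_g_day`, `units_day`, `level`,
#'   `adherence`, `consumer`.
#' @export
classify_exposure <- function(ethanol_g_day, sex) {
  g <- as.numeric(ethanol_g_day)
  if (any(!is.finite(g)) || any(g < 0)) stop_domain("ethanol intake must be finite and non-negative")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) stop_schema("sex must be 'male' or 'female'")
  if (length(sex) == 1L) sex <- rep(sex, length(g))
  if (length(sex) != length(g)) stop_usage("sex and intake lengths differ")

  level <- ifelse(g == 0, "zero",
           ifelse(g < 10, "gt0_lt10",
           ifelse(g < 20, "ge10_lt20", "ge20")))
  thr <- ifelse(sex == "female", 10, 20)
  adherence <- ifelse(g == 0, "full", ifelse(g < thr, "partial", "non"))
  data.frame(
    ethanol_g_day = g,
    units_day = g / GRAMS_PER_UNIT,
    level = factor(level, levels = c("zero", "gt0_lt10", "ge10_lt20", "ge20")),
    adherence = factor(adherence, levels = c("full", "partial", "non")),
    consumer = g > 0,
    stringsAsFactors = FALSE
  )
}

#' Apply sex-specific energy-intake exclusions
#'
#' Removes participants with implausible reported energy intake:
#' below 600 kcal/day (women) or 800 kcal/day (men), or above
#' 3500 kcal/day (women) or 4200 kcal/day (men). Bounds are exclusive, so
#' e.g. a man at exactly 4200 kcal/day is retained.
#'
#' @param cohort data.frame with columns `energy_kcal_day` and `sex`.
#' @return list with `cohort` (rows retained) and `log`, a data.frame of
#'   exclusion counts per reason (`low_energy`, `high_energy`).
#' @export
apply_energy_exclusions <- function(cohort) {
  need <- c("energy_kcal_day", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_schema("missing columns: ", paste(miss, collapse = ", "))
  e <- cohort$energy_kcal_day
  lo <- ifelse(cohort$sex == "female", 600, 800)
  hi <- ifelse(cohort$sex == "female", 3500, 4200)
  low <- !is.na(e) & e < lo
  high <- !is.na(e) & e > hi
  log <- data.frame(reason = c("low_energy", "high_energy"),
                    n_excluded = c(sum(low), sum(high)),
                    stringsAsFactors = FALSE)
  list(cohort = cohort[!(low | high), , drop = FALSE], log = log)
}

#' Derive analysis covariates from raw questionnaire fields
#'
#' Adds to the table:
#' * `activity_min_week`: moderate + 2 x vigorous minutes/week (vigorous
#'   activity weighted by two).
#' * `smoker` / `snuser`: regular or occasional users, or former users who
#'   quit within the last ten years.
#' * `bmi`: weight (kg) / height (m) squared, when `bmi` is absent and
#'   `weight_kg`/`height_cm` are present.
#' * categorical missingness for education, national affiliation, family
#'   history and smoking kept as an explicit `"missing"` level; missing
#'   continuous BMI and physical activity set to the cohort median.
#'
#' @param raw data.frame of raw metadata.
#' @return data.frame with derived columns appended/updated.
#' @export
derive_covariates <- function(raw) {
  df <- raw
  if (all(c("moderate_min_week", "vigorous_min_week") %in% names(df))) {
    df$activity_min_week <- df$moderate_min_week + 2 * df$vigorous_min_week
  }
  ten_year_rule <- function(status, quit_years) {
    s <- as.character(status)
    out <- s %in% c("regular", "occasional") |
      (s %in% "former" & !is.na(quit_years) & quit_years <= 10)
    out[is.na(s)] <- NA
    out
  }
  if ("smoking_user" %in% names(df)) {
    qy <- if ("smoking_quit_years" %in% names(df)) df$smoking_quit_years else NA_real_
    df$smoker <- ten_year_rule(df$smoking_user, qy)
  }
  if ("snus_user" %in% names(df)) {
    qy <- if ("snus_quit_years" %in% names(df)) df$snus_quit_years else NA_real_
    df$snuser <- ten_year_rule(df$snus_user, qy)
  }
  if (!"bmi" %in% names(df) && all(c("weight_kg", "height_cm") %in% names(df))) {
    df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  }
  for (col in intersect(c("education", "affiliation", "family_history"), names(df))) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- "missing"
    df[[col]] <- factor(x)
  }
  if ("smoker" %in% names(df)) {
    x <- ifelse(is.na(df$smoker), "missing", ifelse(df$smoker, "smoker", "non_smoker"))
    df$smoking_status <- factor(x, levels = c("non_smoker", "smoker", "missing")[c("non_smoker", "smoker", "missing") %in% x])
  }
  for (col in intersect(c("bmi", "activity_min_week"), names(df))) {
    x <- df[[col]]
    if (anyNA(x)) x[is.na(x)] <- median(x, na.rm = TRUE)
    df[[col]] <- x
  }
  df
}

#' Assign diagnostic groups
#'
#' Screening colonoscopy findings are grouped into controls, non-advanced
#' adenoma, and advanced lesions (colorectal cancer, advanced adenoma, or
#' advanced serrated lesion). `advanced_subtype` may only be non-missing for
#' advanced lesions.
#'
#' @param group character/factor with values `control`,
#'   `non_advanced_adenoma`, `advanced_lesion`.
#' @param advanced_subtype optional subtype (`crc`, `advanced_adenoma`,
#'   `advanced_serrated`), `NA` elsewhere.
#' @return factor with the three diagnostic levels (controls first, so that
#'   they are the model reference).
#' @export
diagnostic_group <- function(group, advanced_subtype = NULL) {
  lv <- c("control", "non_advanced_adenoma", "advanced_lesion")
  g <- as.character(group)
  if (!all(g %in% lv)) stop_schema("unknown diagnostic group value")
  if (!is.null(advanced_subtype)) {
    st <- as.character(advanced_subtype)
    bad <- !is.na(st) & g != "advanced_lesion"
    if (any(bad)) stop_schema("advanced_subtype set for a non-advanced participant")
    ok <- is.na(st) | st %in% c("crc", "advanced_adenoma", "advanced_serrated")
    if (!all(ok)) stop_schema("unknown advanced_subtype value")
  }
  factor(g, levels = lv)
}
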