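## Alcohol-associated microbial score: log-ratio of summed abundances of
## alcohol-elevated vs alcohol-depleted taxa (Gevers-style), with taxa
## selected by differential abundance under five-fold cross-validation so
## that no participant's score uses taxa selected with their own data.

#' Gevers-style log-ratio score for one sample
#'
#' `log((sum over elevated taxa + pseudo) / (sum over depleted taxa +
#' pseudo))`. The pseudo-count is added once to each summed side (a
#' per-taxon variant is available), which keeps the score stable for
#' sparse taxon sets; with all-zero abundances the score is exactly 0.
#'
#' @param x named abundance vector (relative abundances).
#' @param taxa_pos,taxa_neg disjoint, non-empty name sets.
#' @param pseudo positive pseudo-count.
#' @param base log base (default natural).
#' @param per_taxon add the pseudo-count to every taxon before summing.
#' @return scalar score in log units.
#' @export
gevers_score <- function(x, taxa_pos, taxa_neg, pseudo = 1e-4, base = exp(1),
                         per_taxon = FALSE) {
  if (length(taxa_pos) == 0L || length(taxa_neg) == 0L)
    stop_domain("both taxon sets must be non-empty")
  if (length(intersect(taxa_pos, taxa_neg)))
    stop_domain("taxon sets must be disjoint")
  if (pseudo <= 0) stop_config("pseudo must be positive")
  miss <- setdiff(c(taxa_pos, taxa_neg), names(x))
  if (length(miss)) stop_schema("taxa absent from sample: ", paste(miss, collapse = ", "))
  if (per_taxon) {
    num <- sum(x[taxa_pos] + pseudo)
    den <- sum(x[taxa_neg] + pseudo)
  } else {
    num <- sum(x[taxa_pos]) + pseudo
    den <- sum(x[taxa_neg]) + pseudo
  }
  log(num / den, base = base)
}

## Seeded fold assignment, stratified by an optional outcome so case
## balance is preserved across folds.
assign_folds <- function(n, k, stratify = NULL, seed = 1L) {
  if (n < k) stop_usage("need at least k samples")
  set.seed(seed)
  fold <- integer(n)
  strata <- if (is.null(stratify)) rep(1L, n) else as.integer(factor(stratify))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated alcohol-associated microbial score
#'
#' Samples are partitioned into `k` folds (seeded, stratified by `outcome`
#' when given). For each fold, differential abundance is fitted on the
#' other k-1 folds ([transform_abundance()] + [fit_features()]); taxa with
#' BH q below `q_select` are split by direction of association into
#' elevated/depleted sets, and the held-out fold is scored with
#' [gevers_score()]. A fold in which either set comes up empty falls back
#' to the top `fallback_m` taxa by p-value in each direction and is
#' flagged.
#'
#' @param mat samples x features relative-abundance matrix.
#' @param exposure numeric exposure (typically `log2_alcohol(g)`).
#' @param covariates optional data.frame for the differential-abundance
#'   models.
#' @param outcome optional factor used to stratify fold assignment.
#' @param k number of folds (default 5; `k = n` gives leave-one-out).
#' @param q_select BH q threshold for taxon selection within folds.
#' @param fallback_m taxa per direction when the q threshold selects none.
#' @param pseudo pseudo-count for the score (default 1e-4 on the
#'   0-100 relative-abundance scale).
#' @param min_prev prevalence filter applied within each training set.
#' @param seed RNG seed for the fold assignment.
#' @return data.frame (class `microbial_score`) with `sample_id`, `score`,
#'   `fold`; per-fold taxon sets in attribute "fold_taxa" (list with
#'   `taxa_pos`, `taxa_neg`, `fallback` flag per fold).
#' @export
cv_score <- function(mat, exposure, covariates = NULL, outcome = NULL, k = 5L,
                     q_select = 0.05, fallback_m = 10L, pseudo = 1e-4,
                     min_prev = 0.1, seed = 1L) {
  n <- nrow(mat)
  if (n < 2L * k && k < n) stop_usage("need at least 2k samples for k-fold CV")
  fold <- assign_folds(n, k, stratify = outcome, seed = seed)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  score <- numeric(n)
  fold_taxa <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te)) next
    sel <- select_taxa(mat[tr, , drop = FALSE], exposure[tr],
                       if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE],
                       q_select = q_select, fallback_m = fallback_m,
                       min_prev = min_prev)
    fold_taxa[[f]] <- sel
    for (i in te) score[i] <- gevers_score(mat[i, ], sel$taxa_pos, sel$taxa_neg, pseudo = pseudo)
  }
  out <- data.frame(sample_id = ids, score = score, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "fold_taxa") <- fold_taxa
  class(out) <- c("microbial_score", "data.frame")
  out
}

## Taxon selection on a training set; shared by the CV and non-CV routes.
select_taxa <- function(mat, exposure, covariates, q_select = 0.05,
                        fallback_m = 10L, min_prev = 0.1) {
  filt <- prevalence_filter(mat, min_prev = min_prev)
  tr <- transform_abundance(filt, normalization = "none")
  res <- fit_features(tr, exposure, covariates)
  pos <- res$feature[res$q < q_select & res$direction == "positive"]
  neg <- res$feature[res$q < q_select & res$direction == "negative"]
  fallback <- FALSE
  if (!length(pos)) {
    fallback <- TRUE
    cand <- res[res$direction == "positive", ]
    pos <- cand$feature[order(cand$p)][seq_len(min(fallback_m, nrow(cand)))]
  }
  if (!length(neg)) {
    fallback <- TRUE
    cand <- res[res$direction == "negative", ]
    neg <- cand$feature[order(cand$p)][seq_len(min(fallback_m, nrow(cand)))]
  }
  if (!length(pos) || !length(neg))
    stop_domain("could not select taxa in both directions")
  list(taxa_pos = pos, taxa_neg = neg, fallback = fallback)
}

#' Test the association between a cross-validated score and the exposure
#'
#' The natural pooled regression of the CV score on the exposure is mildly
#' anticonservative under the null: each held-out score is independent of
#' its own sample's exposure, but the taxa selected for one fold depend on
#' the exposures of the other folds, leaving second-order cross-fitting
#' dependence. The default `per_fold` method is exact by construction:
#' within a fold the scores are, conditional on the training data, an
#' independent transformation of the held-out samples, so the per-fold
#' regression p-values are individually valid, and Bonferroni combination
#' is valid under arbitrary dependence. `pooled` runs the fold-adjusted
#' pooled regression for comparison.
#'
#' @param score_df a [cv_score()] result (columns `score`, `fold`).
#' @param exposure exposure vector aligned with the score rows.
#' @return list with `p` (combined p-value), `method`, and the per-fold
#'   p-values (per_fold method only).
#' @param method `"per_fold"` (default, exact) or `"pooled"`.
#' @export
score_leakage_test <- function(score_df, exposure, method = c("per_fold", "pooled")) {
  method <- match.arg(method)
  if (length(exposure) != nrow(score_df)) stop_usage("exposure not aligned with scores")
  if (method == "pooled") {
    fit <- lm(score_df$score ~ exposure + factor(score_df$fold))
    return(list(p = summary(fit)$coefficients["exposure", 4], method = method))
  }
  folds <- sort(unique(score_df$fold))
  pf <- vapply(folds, function(f) {
    i <- score_df$fold == f
    if (sum(i) < 3L || var(exposure[i]) == 0) return(NA_real_)
    summary(lm(score_df$score[i] ~ exposure[i]))$coefficients[2, 4]
  }, numeric(1))
  pf <- pf[!is.na(pf)]
  if (!length(pf)) stop_usage("no testable folds")
  list(p = min(1, min(pf) * length(pf)), method = method, per_fold = pf)
}

#' Non-cross-validated score (for leakage comparison)
#'
#' Selects taxa on the full data set and scores every sample with them.
#' This is the biased construction the cross-validation exists to avoid;
#' it is exported so the inflation can be demonstrated and tested.
#'
#' @inheritParams cv_score
#' @return data.frame with `sample_id` and `score`; the selected sets in
#'   attribute "taxa".
#' @export
naive_score <- function(mat, exposure, covariates = NULL, q_select = 0.05,
                        fallback_m = 10L, pseudo = 1e-4, min_prev = 0.1) {
  sel <- select_taxa(mat, exposure, covariates, q_select = q_select,
                     fallback_m = fallback_m, min_prev = min_prev)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(mat)))
  score <- vapply(seq_len(nrow(mat)), function(i)
    gevers_score(mat[i, ], sel$taxa_pos, sel$taxa_neg, pseudo = pseudo), numeric(1))
  out <- data.frame(sample_id = ids, score = score, stringsAsFactors = FALSE)
  attr(out, "taxa") <- sel
  out
}
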