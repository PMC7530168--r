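#' Cross-validation configuration
#'
#' The reference protocol: five folds, the training portion of each fold
#' split 70/30 into fitting and validation subsets, the whole experiment
#' repeated (50 times at full scale) with fresh random folds, and percentile
#' 95% confidence intervals reported over the per-repeat metrics.
#'
#' @param folds Number of folds (>= 2; default 5).
#' @param repeats Number of repetitions (default 50).
#' @param train_fraction Fraction of the training portion used for fitting;
#'   the rest validates epoch/hyperparameter selection (default 0.70).
#' @param stratified Stratify folds by risk label (default `TRUE`).
#' @param seed Integer seed.
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 5L, repeats = 50L, train_fraction = 0.70,
                      stratified = TRUE, seed = 1L) {
  if (folds < 2L) stop("cv config error: folds must be >= 2")
  if (repeats < 1L) stop("cv config error: repeats must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("cv config error: train_fraction must be in (0, 1)")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# deterministic per-(repeat, fold) seed derived from the base seed
derive_seed <- function(base, r, f = 0L) {
  as.integer((as.double(base) * 7919 + r * 1009 + f * 101) %% 2147483629)
}

#' Assign subjects to cross-validation folds
#'
#' Random disjoint folds covering the whole cohort; with `stratified = TRUE`
#' the high/low risk groups are partitioned separately so each fold keeps
#' approximately the cohort prevalence.
#'
#' @param coh A `conn_cohort`.
#' @param config A [cv_config()] (its `folds`, `stratified`, `seed` fields
#'   are used).
#' @return Integer vector of fold indices in 1..folds, one per subject.
#' @export
split_folds <- function(coh, config = cv_config()) {
  n <- length(coh)
  k <- config$folds
  if (n < k) stop("cv error: cohort smaller than the number of folds")
  withr::with_seed(config$seed, {
    folds <- integer(n)
    load <- integer(k)
    strata <- if (config$stratified) split(seq_len(n), coh$risk)
              else list(seq_len(n))
    for (idx in strata) {
      if (length(idx) == 0L) next
      idx <- idx[sample.int(length(idx))]
      # deal members to the currently least-loaded folds so that both the
      # stratum counts and the total fold sizes differ by at most one
      for (i in idx) {
        target <- order(load, stats::runif(k))[1L]
        folds[i] <- target
        load[target] <- load[target] + 1L
      }
    }
    folds
  })
}

# stratified fit/validation split of index vector; returns list(fit, val)
split_train_val <- function(coh, idx, fraction, seed) {
  withr::with_seed(seed, {
    pick <- function(sub) {
      n_fit <- round(fraction * length(sub))
      n_fit <- max(min(n_fit, length(sub) - 1L), 1L)
      sub[sample.int(length(sub), n_fit)]
    }
    strata <- split(idx, coh$risk[idx], drop = TRUE)
    fit <- sort(unlist(lapply(strata, pick), use.names = FALSE))
    list(fit = fit, val = sort(setdiff(idx, fit)))
  })
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed by the rank statistic (equivalently the
#' trapezoidal rule over the empirical ROC), with tied scores counted 1/2.
#'
#' @param p Predicted probabilities or scores.
#' @param y Binary labels (1 or `"high"` = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(p, y) {
  pos <- y == 1L | y == "high"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("metric error: need both classes for AUC")
  r <- rank(p, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a probability threshold
#'
#' Sensitivity is computed on the high-risk class (`TP/(TP+FN)`),
#' specificity on the low-risk class (`TN/(TN+FP)`), balanced accuracy is
#' their mean; AUC is the rank-based estimate of [auc_rank()]. Percentages
#' are on the 0--100 scale.
#'
#' @param p Predicted high-risk probabilities.
#' @param labels Risk labels (factor with levels `low`/`high`, or 0/1).
#' @param threshold Decision threshold on `p` (default 0.5).
#' @return Named list: `balanced_accuracy`, `sensitivity`, `specificity`
#'   (percent), `auc`.
#' @export
compute_classification_metrics <- function(p, labels, threshold = 0.5) {
  y <- if (is.factor(labels)) labels == "high" else labels == 1L
  if (!any(y) || all(y))
    stop("metric error: both classes must be present")
  pred_high <- p >= threshold
  sens <- sum(pred_high & y) / sum(y)
  spec <- sum(!pred_high & !y) / sum(!y)
  list(balanced_accuracy = 100 * (sens + spec) / 2,
       sensitivity = 100 * sens,
       specificity = 100 * spec,
       auc = auc_rank(p, as.integer(y)))
}

#' Regression metrics
#'
#' Pearson correlation between predicted and observed scores (with its
#' two-sided p-value), mean absolute error, and the standard deviation of
#' the per-subject absolute errors.
#'
#' @param predictions Predicted scores.
#' @param scores Observed scores.
#' @return Named list: `r`, `p_value`, `mae`, `std_ae`.
#' @export
compute_regression_metrics <- function(predictions, scores) {
  if (length(predictions) < 2L)
    stop("metric error: need at least 2 observations")
  if (stats::sd(predictions) == 0 || stats::sd(scores) == 0)
    stop("metric error: zero variance; correlation undefined")
  ct <- stats::cor.test(predictions, scores, method = "pearson")
  ae <- abs(scores - predictions)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       mae = mean(ae), std_ae = stats::sd(ae))
}

#' Repeated stratified cross-validation of a connectome model
#'
#' Runs the full evaluation protocol: per repeat, a fresh fold split; per
#' fold, the training portion is split 70/30 into fitting and validation
#' subsets, the oversampler is fitted to and applied to the fitting subset
#' only, the model is trained, and test-fold predictions are pooled. No
#' synthetic sample ever derives from a validation or test subject; the
#' driver audits this every fold and aborts on violation. Per-repeat metrics
#' are computed on the pooled test predictions and summarized as the mean
#' with a percentile 95% confidence interval across repeats.
#'
#' @param coh A `conn_cohort`.
#' @param spec A model spec from [build_baseline()].
#' @param cv A [cv_config()].
#' @param aug An [augmentation_config()]; `expansion_factor = 1` disables
#'   oversampling.
#' @param backbone Optional shared `conn_backbone` for CNN-family specs.
#' @param collect_maps Also compute Grad-CAM maps for every test subject
#'   (transfer-learning CNN only); returned for [aggregate_importance()].
#' @return Object of class `cv_result`: per-repeat metric data frame,
#'   summary with CIs, pooled per-subject predictions, model/leakage audit
#'   counters, and optionally the saliency maps.
#' @export
run_repeated_cv <- function(coh, spec, cv = cv_config(),
                            aug = augmentation_config(),
                            backbone = NULL, collect_maps = FALSE) {
  stopifnot(inherits(coh, "conn_cohort"), inherits(spec, "conn_model_spec"))
  classify <- spec$task == "classification"
  if (spec$kind %in% c("tlcnn") && is.null(backbone))
    backbone <- build_backbone(seed = cv$seed)
  if (collect_maps && spec$kind != "tlcnn")
    stop("unsupported-model error: saliency maps need the tlcnn spec")
  per_repeat <- NULL
  predictions <- NULL
  maps <- list()
  n_models <- 0L
  for (r in seq_len(cv$repeats)) {
    fold_cfg <- cv
    fold_cfg$seed <- derive_seed(cv$seed, r)
    folds <- split_folds(coh, fold_cfg)
    pooled <- rep(NA_real_, length(coh))
    for (f in seq_len(cv$folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (classify && length(unique(coh$risk[test_idx])) < 2L &&
          cv$stratified)
        stop("stratification error: fold ", f, " lacks a class")
      sv <- split_train_val(coh, train_idx, cv$train_fraction,
                            derive_seed(cv$seed, r, f) + 1L)
      fit_coh <- coh[sv$fit]
      val_coh <- coh[sv$val]
      if (aug$expansion_factor > 1) {
        aug_f <- aug
        aug_f$seed <- derive_seed(cv$seed, r, f) + 2L
        fit_coh <- augment(fit_coh, aug_f)
        audit_leakage(fit_coh, coh$ids[c(test_idx, sv$val)])
      }
      model <- fit_spec(spec, fit_coh, val_coh, backbone = backbone,
                        seed = derive_seed(cv$seed, r, f) + 3L)
      n_models <- n_models + 1L
      pooled[test_idx] <- predict_model(model, coh[test_idx])
      if (collect_maps)
        for (t in test_idx)
          maps[[length(maps) + 1L]] <- gradcam(model, coh[t])
    }
    met <- if (classify)
      compute_classification_metrics(pooled, coh$risk)
    else compute_regression_metrics(pooled, coh$scores)
    per_repeat <- rbind(per_repeat,
                        data.frame(repeat_ = r, as.data.frame(met)))
    predictions <- rbind(predictions,
                         data.frame(repeat_ = r, subject_id = coh$ids,
                                    prediction = pooled,
                                    observed = if (classify)
                                      as.character(coh$risk)
                                    else coh$scores))
  }
  metric_cols <- setdiff(names(per_repeat), c("repeat_", "p_value"))
  summary <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- per_repeat[[mc]]
    data.frame(metric = mc, mean = mean(v),
               ci_lower = unname(stats::quantile(v, 0.025)),
               ci_upper = unname(stats::quantile(v, 0.975)))
  }))
  structure(list(per_repeat = per_repeat, summary = summary,
                 predictions = predictions, n_models = n_models,
                 task = spec$task, kind = spec$kind,
                 maps = if (collect_maps) maps else NULL,
                 leakage_audited = aug$expansion_factor > 1),
            class = "cv_result")
}

# abort if any synthetic sample derives from a held-out subject
audit_leakage <- function(aug_cohort, held_out_ids) {
  contrib <- unique(unlist(aug_cohort$contributors))
  bad <- intersect(contrib, held_out_ids)
  if (length(bad) > 0L)
    stop("leakage error: synthetic samples derive from held-out subjects: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("repeated cross-validation: %s (%s), %d repeats, %d models\n",
              x$kind, x$task, max(x$per_repeat$repeat_), x$n_models))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %7.3f  (95%% CI %7.3f, %7.3f)\n", s$metric[i],
                s$mean[i], s$ci_lower[i], s$ci_upper[i]))
  invisible(x)
}

#' Permute the region order of every connectome in a cohort
#'
#' Applies one random permutation identically to the rows and columns of
#' every connectome; scores are unchanged. The permutation is stored in the
#' `roi_permutation` attribute so edge identity can be tracked through the
#' reordering: original edge (i, j) sits at the permuted positions
#' `(inv[i], inv[j])` with `inv = order(roi_permutation)`, which lets
#' [edge_outcome_correlation()] verify that tracked correlations are
#' invariant under the relabelling.
#'
#' @param coh A `conn_cohort`.
#' @param seed Integer seed.
#' @return A `conn_cohort` with permuted region order.
#' @export
permute_roi_order <- function(coh, seed = 1L) {
  stopifnot(inherits(coh, "conn_cohort"))
  perm <- withr::with_seed(seed, sample.int(N_REGIONS))
  out <- coh
  for (s in seq_len(length(coh)))
    out$conn[, , s] <- coh$conn[perm, perm, s]
  attr(out, "roi_permutation") <- perm
  out
}
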