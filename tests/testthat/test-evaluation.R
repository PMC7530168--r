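test_that("fold splits partition the cohort evenly and deterministically", {
  coh <- generate_cohort(generator_config(80, seed = 51))
  cfg <- cv_config(folds = 5, seed = 3)
  f <- split_folds(coh, cfg)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 16))              # 80/5 even partition
  expect_identical(f, split_folds(coh, cfg))    # seed determinism
  cfg2 <- cfg; cfg2$seed <- 4L
  expect_false(identical(f, split_folds(coh, cfg2)))
  # stratification keeps class prevalence per fold
  for (k in 1:5) {
    n_high <- sum(coh$risk[f == k] == "high")
    expect_true(abs(n_high - sum(coh$risk == "high") / 5) <= 1)
  }
  expect_error(split_folds(coh[1:3], cfg), "smaller")
})

test_that("classification metrics match hand arithmetic", {
  # confusion (TP=7, FN=3, TN=8, FP=2)
  p <- c(rep(0.9, 7), rep(0.1, 3), rep(0.1, 8), rep(0.9, 2))
  y <- factor(c(rep("high", 10), rep("low", 10)), levels = c("low", "high"))
  m <- compute_classification_metrics(p, y)
  expect_equal(m$sensitivity, 70)
  expect_equal(m$specificity, 80)
  expect_equal(m$balanced_accuracy, 75)
  # perfect and anti-perfect rankings
  perf <- compute_classification_metrics(c(0.9, 0.9, 0.1),
                                         factor(c("high", "high", "low"),
                                                levels = c("low", "high")))
  expect_equal(perf$balanced_accuracy, 100)
  expect_equal(perf$auc, 1)
  expect_equal(auc_rank(c(0.1, 0.9), c(1, 0)), 0)
  expect_error(compute_classification_metrics(c(0.5, 0.5),
                                              factor(c("high", "high"),
                                                     levels = c("low",
                                                                "high"))),
               "both classes")
})

test_that("rank-based AUC matches the pairwise oracle to 1e-12", {
  withr::with_seed(8, {
    for (rep in 1:100) {
      n <- sample(8:40, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.4))       # both classes guaranteed
      p <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
      expect_equal(auc_rank(p, y), auc_pairwise(p, y), tolerance = 1e-12)
    }
  })
})

test_that("regression metrics match hand arithmetic and edge cases", {
  m <- compute_regression_metrics(c(98, 94, 108, 100), c(100, 90, 110, 95))
  expect_equal(m$mae, 3.25)                     # (2+4+2+5)/4
  expect_equal(m$std_ae, sd(c(2, 4, 2, 5)))
  perfect <- compute_regression_metrics(c(1, 2, 3) + 100, c(1, 2, 3) + 100)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$std_ae, 0)
  anti <- compute_regression_metrics(-c(95, 100, 105) + 200,
                                     c(95, 100, 105))
  expect_equal(anti$r, -1)
  expect_error(compute_regression_metrics(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("repeated CV tests every subject once per repeat and audits leakage", {
  coh <- generate_cohort(generator_config(50, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 52))
  spec <- build_baseline("lr", "classification")
  res <- run_repeated_cv(coh, spec, cv = cv_config(folds = 5, repeats = 2,
                                                   seed = 2),
                         aug = augmentation_config(expansion_factor = 3,
                                                   seed = 1))
  expect_identical(res$n_models, 10L)           # folds x repeats
  for (r in 1:2) {
    pr <- res$predictions[res$predictions$repeat_ == r, ]
    expect_identical(pr$subject_id, coh$ids)    # each tested exactly once
    expect_false(anyNA(pr$prediction))
  }
  expect_true(res$leakage_audited)
  expect_identical(nrow(res$per_repeat), 2L)
  s <- res$summary
  expect_true(all(s$ci_lower <= s$mean + 1e-12 &
                    s$mean <= s$ci_upper + 1e-12))
})

test_that("the leakage guard itself fires on contaminated input", {
  coh <- tiny_cohort(n = 12)
  aug <- augment(coh, augmentation_config(expansion_factor = 2, seed = 1))
  held_out <- aug$contributors[[which(!vapply(aug$contributors, is.null,
                                              logical(1)))[1]]][1]
  expect_error(tlcnn:::audit_leakage(aug, held_out), "leakage")
  expect_true(tlcnn:::audit_leakage(aug, "not-a-member"))
})

test_that("repeated CV is deterministic under a fixed seed", {
  coh <- generate_cohort(generator_config(40, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 53))
  spec <- build_baseline("lr", "classification")
  cv <- cv_config(folds = 4, repeats = 2, seed = 5)
  aug <- augmentation_config(expansion_factor = 2, seed = 1)
  a <- run_repeated_cv(coh, spec, cv = cv, aug = aug)
  b <- run_repeated_cv(coh, spec, cv = cv, aug = aug)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_identical(a$predictions, b$predictions)
})

test_that("label-shuffled cohorts evaluate at chance", {
  # permutation-null: destroy the edge-score link, keep everything else
  coh <- generate_cohort(generator_config(60, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 54))
  withr::with_seed(99, {
    perm <- sample.int(60)
  })
  null_coh <- coh
  null_coh$scores <- coh$scores[perm]
  null_coh$risk <- coh$risk[perm]
  spec <- build_baseline("lr", "classification")
  res <- run_repeated_cv(null_coh, spec,
                         cv = cv_config(folds = 5, repeats = 4, seed = 7),
                         aug = augmentation_config(expansion_factor = 1))
  aucs <- res$per_repeat$auc
  # chance performance: mean AUC within 3 SE of 0.5
  expect_lt(abs(mean(aucs) - 0.5), 3 * max(sd(aucs) / sqrt(length(aucs)),
                                           0.05))
})

test_that("widening repeats does not widen the percentile CI", {
  withr::with_seed(13, {
    vals5 <- rnorm(5)
    vals50 <- c(vals5, rnorm(45))
  })
  w5 <- diff(quantile(vals5, c(0.025, 0.975)))
  w50 <- diff(quantile(vals50, c(0.025, 0.975)))
  # monotone in probability; tested as non-strict with slack of 3 SE of the
  # quantile spread under the standard normal
  expect_lte(w5, w50 + 3 * 0.6)
})

test_that("region permutation preserves structure and tracks edge identity", {
  coh <- generate_cohort(generator_config(30, default_effect_edges(0.8),
                                          seed = 55))
  perm_coh <- permute_roi_order(coh, seed = 17)
  perm <- attr(perm_coh, "roi_permutation")
  expect_identical(sort(perm), 1:90)
  expect_identical(perm_coh$scores, coh$scores)
  for (s in c(1, 30)) {
    m0 <- coh$conn[, , s]
    m1 <- perm_coh$conn[, , s]
    expect_identical(m1, t(m1))
    expect_identical(unname(diag(m1)), rep(0, 90))
    expect_identical(sort(as.vector(m1)), sort(as.vector(m0)))
    # inverse permutation restores the original exactly
    inv <- order(perm)
    expect_identical(m1[inv, inv], m0)
  }
  # edge-identity-tracked correlations are invariant
  inv <- order(perm)
  eff <- default_effect_edges(0.8)
  r0 <- edge_outcome_correlation(coh, eff[, c("i", "j")])$r
  tracked <- data.frame(i = pmin(inv[eff$i], inv[eff$j]),
                        j = pmax(inv[eff$i], inv[eff$j]))
  r1 <- edge_outcome_correlation(perm_coh, tracked)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})
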