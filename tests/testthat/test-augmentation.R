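test_that("score bins follow the five-bin left-closed convention", {
  cfg <- augmentation_config()
  expect_identical(assign_bin(65, cfg), 0L)
  expect_identical(assign_bin(70, cfg), 1L)   # left-closed boundary
  expect_identical(assign_bin(79.99, cfg), 1L)
  expect_identical(assign_bin(85, cfg), 2L)
  expect_identical(assign_bin(95, cfg), 3L)
  expect_identical(assign_bin(100, cfg), 4L)
  expect_identical(assign_bin(105, cfg), 4L)
  expect_identical(assign_bin(c(40, 160), cfg), c(0L, 4L))
  expect_error(assign_bin(30, cfg), "40")
  # five bins over [40,160]
  expect_length(unique(assign_bin(seq(40, 160, by = 0.5), cfg)), 5L)
})

test_that("synthesize_sample is the exact convex combination", {
  coh <- tiny_cohort(n = 6)
  base <- coh[1]; nb <- coh[2:6]
  # degenerate weights reproduce the base subject
  d <- synthesize_sample(base, nb, c(1, 0, 0, 0, 0, 0))
  expect_identical(d$x_syn, coh$conn[, , 1])
  expect_identical(d$y_syn, coh$scores[1])
  # uniform weights give the entrywise mean
  u <- synthesize_sample(base, nb, rep(1 / 6, 6))
  expect_equal(u$x_syn, apply(coh$conn, c(1, 2), mean), tolerance = 1e-12)
  # worked example: 0.5*80 + 0.1*(85+90+70+75+95) = 81.5
  coh2 <- coh
  coh2$scores <- c(80, 85, 90, 70, 75, 95)
  coh2$risk <- assign_risk_label(coh2$scores)
  w <- c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(synthesize_sample(coh2[1], coh2[2:6], w)$y_syn, 81.5,
               tolerance = 1e-12)
  expect_error(synthesize_sample(base, nb, c(0.5, 0.1, 0.1, 0.1, 0.1, 0.3)),
               "sum to 1")
  expect_error(synthesize_sample(base, nb, rep(0.2, 5)), "k\\+1")
})

test_that("augmentation reaches the target size and keeps originals", {
  coh <- tiny_cohort(n = 20)
  aug <- augment(coh, augmentation_config(expansion_factor = 10, seed = 2))
  expect_length(aug, 200)
  expect_identical(aug$ids[1:20], coh$ids)
  expect_identical(aug$conn[, , 1:20], coh$conn)
  expect_identical(aug$provenance, "augmented")
  # factor 1 returns the originals unchanged
  same <- augment(coh, augmentation_config(expansion_factor = 1))
  expect_length(same, 20)
  expect_identical(same$conn, coh$conn)
  expect_error(augment(coh[1:3], augmentation_config()), "k\\+1")
})

test_that("every synthetic draw is convex in its contributors", {
  coh <- tiny_cohort(n = 18)
  cfg <- augmentation_config(expansion_factor = 5, seed = 7)
  aug <- augment(coh, cfg)
  syn_idx <- which(!vapply(aug$contributors, is.null, logical(1)))
  expect_length(syn_idx, 90 - 18)
  for (s in syn_idx) {
    contrib <- match(aug$contributors[[s]], coh$ids)
    expect_false(anyNA(contrib))
    lo <- apply(coh$conn[, , contrib], c(1, 2), min)
    hi <- apply(coh$conn[, , contrib], c(1, 2), max)
    expect_true(all(aug$conn[, , s] >= lo - 1e-12))
    expect_true(all(aug$conn[, , s] <= hi + 1e-12))
    expect_gte(aug$scores[s], min(coh$scores[contrib]) - 1e-12)
    expect_lte(aug$scores[s], max(coh$scores[contrib]) + 1e-12)
    # symmetry is preserved exactly
    expect_identical(aug$conn[, , s], t(aug$conn[, , s]))
    expect_identical(unname(diag(aug$conn[, , s])), rep(0, 90))
  }
})

test_that("round-robin balancing evens out occupied bins", {
  # 20 subjects spread over all five bins, expanded 10x
  coh <- tiny_cohort(n = 20)
  cfg <- augmentation_config(expansion_factor = 10, seed = 3)
  aug <- augment(coh, cfg)
  # synthetic subjects were drawn from bins round-robin, so per-bin visit
  # counts differ by at most one
  syn_contrib_bins <- vapply(21:200, function(s) {
    base_id <- aug$contributors[[s]][1]
    assign_bin(coh$scores[match(base_id, coh$ids)], cfg)
  }, integer(1))
  tab <- table(syn_contrib_bins)
  expect_lte(max(tab) - min(tab), 1)
})

test_that("augmentation is deterministic in cohort, config and seed", {
  coh <- tiny_cohort(n = 12)
  cfg <- augmentation_config(expansion_factor = 4, seed = 11)
  a <- augment(coh, cfg)
  b <- augment(coh, cfg)
  expect_identical(a$conn, b$conn)
  expect_identical(a$scores, b$scores)
  expect_identical(a$contributors, b$contributors)
  cfg2 <- cfg; cfg2$seed <- 12L
  c2 <- augment(coh, cfg2)
  expect_false(identical(a$conn, c2$conn))
})

test_that("augmentation config validates its fields", {
  expect_error(augmentation_config(k = 0), "k must be")
  expect_error(augmentation_config(expansion_factor = 0.5), "factor")
  expect_error(augmentation_config(bin_edges = c(70, 70, 90, 100)),
               "increasing")
})
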