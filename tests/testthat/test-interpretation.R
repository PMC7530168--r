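make_trained_tlcnn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(generator_config(36, default_effect_edges(0.9),
                                              edge_noise_sd = 0.01,
                                              seed = 61))
      bk <- build_backbone(seed = 6)
      fit <- tlcnn(coh[1:24], coh[25:30], backbone = bk,
                   config = train_config(epochs = 4, seed = 3))
      cache <<- list(fit = fit, coh = coh)
    }
    cache
  }
})

test_that("Grad-CAM maps are nonnegative, symmetric, zero-diagonal", {
  tc <- make_trained_tlcnn()
  g <- gradcam(tc$fit, tc$coh[31])
  expect_identical(dim(g), c(90L, 90L))
  expect_true(all(g >= 0))
  expect_lt(max(abs(g - t(g))), 1e-12)
  expect_identical(unname(diag(g)), rep(0, 90))
})

test_that("Grad-CAM rejects models without convolutional layers", {
  coh <- generate_cohort(generator_config(20, seed = 62))
  dnn <- tlcnn:::fit_spec(build_baseline("dnn", "classification",
                                         config = train_config(epochs = 2,
                                                               seed = 1)),
                          coh[1:15], coh[16:20])
  expect_error(gradcam(dnn, coh[1]), "unsupported-model")
})

test_that("a target disconnected from the input yields a zero map", {
  tc <- make_trained_tlcnn()
  dead <- tc$fit
  # zero the output layer: all gradients upstream of it vanish
  nl <- length(dead$net)
  dead$net[[nl]]$params$W[] <- 0
  dead$net[[nl]]$params$b[] <- 0
  g <- gradcam(dead, tc$coh[31])
  expect_true(all(g == 0))
})

test_that("aggregation normalizes, averages and ignores order", {
  tc <- make_trained_tlcnn()
  maps <- lapply(31:34, function(s) gradcam(tc$fit, tc$coh[s]))
  agg <- aggregate_importance(maps)
  expect_true(all(agg >= 0 & agg <= 1))
  agg_rev <- aggregate_importance(rev(maps))
  expect_equal(unclass(agg), unclass(agg_rev), tolerance = 1e-12)
  # single map: itself after min-max normalization (constructed nonzero map)
  m <- random_connectome(99) * 5
  one <- aggregate_importance(list(m))
  expect_equal(unclass(one), unclass((m - min(m)) / (max(m) - min(m))),
               tolerance = 1e-12)
  zero <- matrix(0, 90, 90)
  expect_true(all(aggregate_importance(list(zero, zero)) == 0))
  expect_error(aggregate_importance(list()), "empty")
})

test_that("edge ranking is deterministic with lexicographic tie-breaks", {
  atlas <- load_atlas()
  # single nonzero at (HIP-L, MOG-L) ranks first
  m <- matrix(0, 90, 90)
  i <- match("HIP-L", atlas$regions$abbreviation)
  j <- match("MOG-L", atlas$regions$abbreviation)
  m[i, j] <- m[j, i] <- 1
  rk <- rank_edges(m, atlas, k = 15)
  expect_identical(nrow(rk), 15L)
  expect_identical(rk$abbrev_a[1], "HIP-L")
  expect_identical(rk$abbrev_b[1], "MOG-L")
  # all-equal map: first k pairs in lexicographic order
  flat <- matrix(1, 90, 90); diag(flat) <- 0
  rk2 <- rank_edges(flat, atlas, k = 4)
  expect_identical(rk2$abbrev_a, atlas$regions$abbreviation[c(1, 1, 1, 1)])
  expect_identical(rk2$abbrev_b, atlas$regions$abbreviation[2:5])
  expect_error(rank_edges(flat, atlas, k = 5000), "4005")
  # importance column is non-increasing
  tc <- make_trained_tlcnn()
  agg <- aggregate_importance(lapply(31:33, function(s)
    gradcam(tc$fit, tc$coh[s])))
  rk3 <- rank_edges(agg, atlas, k = 50)
  expect_true(all(diff(rk3$importance) <= 1e-15))
})

test_that("edge-outcome correlations recover engineered relationships", {
  # engineered: edge weight = a*score + c with a > 0 gives r = 1
  n <- 20
  scores <- seq(60, 140, length.out = n)
  conn <- array(0.4, dim = c(90, 90, n))
  for (s in 1:n) {
    diag(conn[, , s]) <- 0
    w <- 0.2 + 0.003 * scores[s]
    conn[1, 2, s] <- conn[2, 1, s] <- w
    conn[3, 4, s] <- conn[4, 3, s] <- 0.9 - 0.003 * scores[s]
  }
  coh <- cohort(sprintf("e%02d", 1:n), conn, scores, validate = FALSE)
  ec <- edge_outcome_correlation(coh, data.frame(i = c(1, 3, 5),
                                                 j = c(2, 4, 6)))
  expect_equal(ec$r[1], 1, tolerance = 1e-12)
  expect_equal(ec$r[2], -1, tolerance = 1e-12)
  expect_true(ec$undefined[3])                  # constant edge flagged
  expect_true(is.na(ec$r[3]))
  expect_error(edge_outcome_correlation(coh[1:2], data.frame(i = 1, j = 2)),
               "at least 3")
})

test_that("planted negative-alpha edge yields negative correlation at scale", {
  coh <- generate_cohort(generator_config(2000,
                                          data.frame(i = 10, j = 20,
                                                     alpha = -0.6),
                                          seed = 63))
  ec <- edge_outcome_correlation(coh, data.frame(i = 10, j = 20))
  expect_lt(ec$r, -0.5)
})

test_that("ranking a model's aggregated map is invariant to subject order", {
  tc <- make_trained_tlcnn()
  idx <- 31:34
  maps <- lapply(idx, function(s) gradcam(tc$fit, tc$coh[s]))
  r1 <- rank_edges(aggregate_importance(maps), k = 10)
  r2 <- rank_edges(aggregate_importance(maps[c(3, 1, 4, 2)]), k = 10)
  expect_equal(r1, r2, tolerance = 1e-12)
})
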