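test_that("backbone architecture matches the very-deep configuration", {
  bk <- build_backbone(seed = 4)
  expect_length(bk$Ws, 16)                      # 16 convolutional layers
  widths <- vapply(bk$Ws, ncol, integer(1))
  expect_identical(widths, c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L,
                             512L, 512L, 512L, 512L, 512L, 512L, 512L, 512L))
  cin <- 3L
  for (l in 1:16) {                             # all kernels are 3x3
    expect_identical(nrow(bk$Ws[[l]]), 9L * cin)
    cin <- widths[l]
  }
  expect_identical(bk$pool_after, c(2L, 4L, 8L, 12L, 16L))
  # 90 -> 45 -> 22 -> 11 -> 5 -> 2 by floor halving
  sz <- 90L
  for (i in 1:5) sz <- sz %/% 2L
  expect_identical(sz, 2L)
  coh <- tiny_cohort(n = 2)
  f <- tlcnn:::backbone_features(bk, coh)
  expect_identical(dim(f), c(8L, 512L))         # 2x2 spatial x 512 channels
})

test_that("backbone weight files are validated and reproducible", {
  a <- build_backbone(seed = 10)
  b <- build_backbone(seed = 10)
  expect_identical(a$Ws, b$Ws)
  expect_false(identical(a$Ws, build_backbone(seed = 11)$Ws))
  f <- tempfile(fileext = ".rds")
  saveRDS(list(Ws = a$Ws, bs = a$bs), f)
  c2 <- build_backbone(weights_file = f)
  expect_identical(c2$Ws, a$Ws)
  expect_identical(c2$source, "pretrained-file")
  saveRDS(list(Ws = a$Ws[1:4], bs = a$bs[1:4]), f)
  expect_error(build_backbone(weights_file = f), "incompatible")
})

test_that("input adapter replicates three identical standardized channels", {
  m <- random_connectome(5)
  x <- adapt_input(m)
  expect_identical(dim(x), c(8100L, 3L))
  expect_identical(x[, 1], x[, 2])
  expect_identical(x[, 2], x[, 3])
  expect_equal(mean(x[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(x[, 1]), 1, tolerance = 1e-12)
  # explicit affine map
  x2 <- adapt_input(m, center = 0.5, scale = 0.5)
  expect_equal(x2[, 1], as.vector((m - 0.5) / 0.5))
  # zero matrix with explicit map is the constant rescaled zero
  z <- adapt_input(matrix(0, 90, 90), center = 0.5, scale = 0.5)
  expect_true(all(z == -1))
})

test_that("loss functions match hand-computed values and an independent loop", {
  expect_equal(cross_entropy_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0.8, 0.2), c(1, 0)),
               -0.5 * (log(0.8) + log(0.8)), tolerance = 1e-12)
  # perfect prediction limit under clipping
  eps <- 1e-7
  expect_lte(cross_entropy_loss(c(1, 0), c(1, 0), clip = eps),
             -log(1 - eps) + 1e-15)
  expect_equal(mae_loss(c(95, 95), c(100, 90)), 5, tolerance = 1e-12)
  expect_equal(mae_loss(c(100, 90), c(100, 90)), 0)
  # scalar-loop oracle on random inputs
  withr::with_seed(6, {
    p <- runif(50, 0.01, 0.99)
    y <- rbinom(50, 1, 0.5)
    yhat <- rnorm(50, 100, 10)
    obs <- rnorm(50, 100, 10)
  })
  ce_loop <- 0
  for (i in 1:50) ce_loop <- ce_loop - (y[i] * log(p[i]) +
                                          (1 - y[i]) * log(1 - p[i]))
  expect_equal(cross_entropy_loss(p, y), ce_loop / 50, tolerance = 1e-12)
  mae_loop <- 0
  for (i in 1:50) mae_loop <- mae_loop + abs(obs[i] - yhat[i])
  expect_equal(mae_loss(yhat, obs), mae_loop / 50, tolerance = 1e-12)
  # triangle inequality under a constant shift
  expect_lte(mae_loss(yhat + 3, obs), mae_loss(yhat, obs) + 3 + 1e-12)
  expect_error(cross_entropy_loss(numeric(0), numeric(0)), "nonempty")
  expect_error(mae_loss(1, numeric(0)), "length")
})

test_that("baseline grids match the printed hyperparameter sets", {
  lr <- build_baseline("lr", "classification")
  expect_length(lr$grid$lambda, 5)              # 10^-3 ... 10^1
  expect_equal(lr$grid$lambda, 10^(-3:1))
  svm <- build_baseline("svm-linear", "classification")
  expect_length(svm$grid$cost, 7)               # 2^-3 ... 2^3
  expect_equal(svm$grid$cost, 2^(-3:3))
  dnn_net <- tlcnn:::build_dnn_net("classification", 0.5)
  dense <- Filter(function(l) l$type == "dense", dnn_net)
  expect_identical(vapply(dense, function(l) l$dout, integer(1))[1:2],
                   c(256L, 64L))                # hidden widths 256 and 64
  expect_error(build_baseline("boost", "classification"), "unknown")
})

test_that("head and baseline architectures audit their layer counts", {
  head <- tlcnn:::build_head("classification", 0.5)
  expect_length(Filter(function(l) l$type == "conv3", head), 2)
  head_dense <- Filter(function(l) l$type == "dense", head)
  expect_length(head_dense, 3)  # FC 256, FC 64, softmax output
  expect_identical(vapply(head_dense, function(l) l$dout, integer(1)),
                   c(256L, 64L, 2L))
  cnn <- tlcnn:::build_cnn_net("regression", 0.5)
  expect_length(Filter(function(l) l$type == "conv3", cnn), 2)
  expect_identical(Filter(function(l) l$type == "conv3", cnn)[[1]]$cout,
                   256L)
  dnn <- tlcnn:::build_dnn_net("regression", 0.5)
  expect_length(Filter(function(l) l$type == "dense", dnn), 3)
})

test_that("training updates the head only and is seed-deterministic", {
  coh <- generate_cohort(generator_config(30, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 12))
  bk <- build_backbone(seed = 2)
  cs0 <- backbone_checksum(bk)
  cfg <- train_config(epochs = 3, seed = 9)
  fit1 <- tlcnn(coh[1:20], coh[21:30], backbone = bk, config = cfg)
  expect_identical(backbone_checksum(bk), cs0)  # frozen contract
  expect_identical(fit1$backbone_checksum[["before"]],
                   fit1$backbone_checksum[["after"]])
  fit2 <- tlcnn(coh[1:20], coh[21:30], backbone = bk, config = cfg)
  expect_identical(lapply(fit1$net, `[[`, "params"),
                   lapply(fit2$net, `[[`, "params"))
  expect_identical(nrow(fit1$history), 3L)
  # loss recorded per epoch and finite
  expect_true(all(is.finite(fit1$history$train_loss)))
  expect_error(tlcnn(coh[0], task = "classification"), "empty")
})

test_that("predictions are order-preserving probabilities or finite scores", {
  coh <- generate_cohort(generator_config(24, default_effect_edges(),
                                          seed = 14))
  bk <- build_backbone(seed = 2)
  fit <- tlcnn(coh[1:16], task = "classification", backbone = bk,
               config = train_config(epochs = 2, seed = 1))
  pr <- predict(fit, coh[17:24])
  expect_identical(pr$subject_id, coh$ids[17:24])
  expect_true(all(pr$p >= 0 & pr$p <= 1))
  # duplicate subject gets an identical prediction (pure function)
  dup <- cohort(c("a", "b"), coh$conn[, , c(17, 17)], coh$scores[c(17, 17)],
                provenance = "synthetic", validate = FALSE)
  pd <- predict(fit, dup)
  expect_equal(pd$p[1], pd$p[2], tolerance = 1e-12)
  fitr <- tlcnn(coh[1:16], task = "regression", backbone = bk,
                config = train_config(epochs = 2, seed = 1))
  prr <- predict(fitr, coh[17:24])
  expect_true(all(is.finite(prr$yhat)))
})

test_that("training loss decreases on a separable cohort", {
  coh <- generate_cohort(generator_config(60, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 15))
  bk <- build_backbone(seed = 3)
  fit <- tlcnn(coh, task = "classification", backbone = bk,
               config = train_config(epochs = 12, seed = 2))
  h <- fit$history$train_loss
  expect_lt(h[length(h)], h[1])
})

test_that("unsupervised pre-training reduces reconstruction loss and seeds the TL-DNN", {
  src <- generate_source_cohort(40, seed = 3)
  pre <- pretrain_unsupervised(src, train_config(epochs = 6, seed = 4))
  h <- pre$history$train_loss
  expect_lt(h[length(h)], h[1])
  expect_identical(dim(pre$enc1$W), c(4005L, 256L))
  pre2 <- pretrain_unsupervised(src, train_config(epochs = 6, seed = 4))
  expect_identical(pre$enc1, pre2$enc1)          # deterministic
  # initialization actually differs from a fresh random net
  fresh <- withr::with_seed(4, tlcnn:::build_dnn_net("classification", 0.5))
  expect_false(isTRUE(all.equal(fresh[[1]]$params$W, pre$enc1$W)))
  expect_error(pretrain_unsupervised(src[0]), "empty")
})

test_that("vector and kernel baselines fit and predict on both tasks", {
  coh <- generate_cohort(generator_config(40, default_effect_edges(0.9),
                                          edge_noise_sd = 0.01, seed = 16))
  fit_idx <- 1:24; val_idx <- 25:32; test_idx <- 33:40
  for (kind in c("lr", "svm-linear", "svm-rbf")) {
    spec <- build_baseline(kind, "classification")
    m <- tlcnn:::fit_spec(spec, coh[fit_idx], coh[val_idx])
    p <- tlcnn:::predict_model(m, coh[test_idx])
    expect_true(all(p >= 0 & p <= 1), label = kind)
    spec_r <- build_baseline(kind, "regression")
    mr <- tlcnn:::fit_spec(spec_r, coh[fit_idx], coh[val_idx])
    yh <- tlcnn:::predict_model(mr, coh[test_idx])
    expect_true(all(is.finite(yh)), label = kind)
  }
  dnn <- tlcnn:::fit_spec(build_baseline("dnn", "classification",
                                         config = train_config(epochs = 3,
                                                               seed = 5)),
                          coh[fit_idx], coh[val_idx])
  p <- tlcnn:::predict_model(dnn, coh[test_idx])
  expect_true(all(p >= 0 & p <= 1))
})
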