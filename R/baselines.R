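BASELINE_KINDS <- c("tlcnn", "lr", "svm-linear", "svm-poly", "svm-rbf",
                    "dnn", "cnn", "tl-dnn")

#' Build a model specification with its hyperparameter search grid
#'
#' Returns the specification of one of the comparison models (or of the
#' transfer-learning CNN itself) in the form consumed by
#' [run_repeated_cv()]. Grids follow the reference protocol:
#'
#' * `"lr"` — L2-penalised logistic regression (classification) or ridge
#'   linear regression (regression) on the 4005 edge vector; regularization
#'   grid `10^(-3:1)` (5 values), selected on the validation split.
#' * `"svm-linear"`, `"svm-poly"`, `"svm-rbf"` — support vector machine /
#'   regression on the edge vector; soft-margin cost grid `2^(-3:3)`
#'   (7 values); for poly/RBF kernels `gamma = 1/(p * var(x))`.
#' * `"dnn"` — fully connected network on the edge vector: FC layers of 256
#'   and 64 units, each with batch normalization and dropout, softmax or
#'   linear output.
#' * `"tl-dnn"` — the same network initialized by unsupervised
#'   reconstruction pre-training ([pretrain_unsupervised()]) on a source
#'   cohort, then fine-tuned.
#' * `"cnn"` — shallow CNN without transfer: 2 convolutional layers (256
#'   filters, 3x3) on the 90x90 matrix, then FC 256 and 64.
#' * `"tlcnn"` — the transfer-learning CNN of [tlcnn()].
#'
#' @param kind One of `r paste0('"', BASELINE_KINDS, '"', collapse = ", ")`.
#' @param task `"classification"` or `"regression"`.
#' @param source Source `conn_cohort` for `"tl-dnn"` pre-training (generated
#'   with [generate_source_cohort()] when `NULL`).
#' @param config A [train_config()] for the network models.
#' @return Object of class `conn_model_spec`.
#' @export
build_baseline <- function(kind, task = c("classification", "regression"),
                           source = NULL, config = train_config()) {
  task <- match.arg(task)
  if (!kind %in% BASELINE_KINDS)
    stop("unknown model kind: ", kind, " (known: ",
         paste(BASELINE_KINDS, collapse = ", "), ")")
  grid <- switch(kind,
                 lr = list(lambda = 10^(-3:1)),
                 `svm-linear` = , `svm-poly` = , `svm-rbf` =
                   list(cost = 2^(-3:3)),
                 list())
  structure(list(kind = kind, task = task, grid = grid, source = source,
                 config = config),
            class = "conn_model_spec")
}

#' @export
print.conn_model_spec <- function(x, ...) {
  cat(sprintf("model spec: %s (%s)\n", x$kind, x$task))
  if (length(x$grid) > 0L)
    for (nm in names(x$grid))
      cat(sprintf("  grid %s: %s\n", nm,
                  paste(signif(x$grid[[nm]], 3L), collapse = ", ")))
  invisible(x)
}

# ---- internal uniform fit/predict over model kinds --------------------------

# fit a spec on a fit/validation cohort pair; returns a trained model whose
# class carries a predict_model method
fit_spec <- function(spec, fit, val, backbone = NULL, seed = NULL) {
  stopifnot(inherits(spec, "conn_model_spec"))
  config <- spec$config
  if (!is.null(seed)) config$seed <- as.integer(seed)
  task <- spec$task
  switch(spec$kind,
    tlcnn = tlcnn(fit, val, task = task, backbone = backbone,
                  config = config),
    lr = fit_glmnet_baseline(spec, fit, val, config),
    `svm-linear` = fit_svm_baseline(spec, fit, val, "linear"),
    `svm-poly` = fit_svm_baseline(spec, fit, val, "polynomial"),
    `svm-rbf` = fit_svm_baseline(spec, fit, val, "radial"),
    dnn = fit_dnn_baseline(spec, fit, val, config, pretrained = NULL),
    `tl-dnn` = {
      source <- spec$source
      if (is.null(source))
        source <- generate_source_cohort(257L, seed = config$seed)
      pre <- pretrain_unsupervised(source, config)
      fit_dnn_baseline(spec, fit, val, config, pretrained = pre)
    },
    cnn = fit_cnn_baseline(spec, fit, val, config))
}

# uniform prediction: probability of high risk, or predicted score
predict_model <- function(model, newdata) {
  if (inherits(model, "tlcnn")) {
    pr <- predict(model, newdata)
    return(if ("p" %in% names(pr)) pr$p else pr$yhat)
  }
  pr <- predict(model, newdata)
  if ("p" %in% names(pr)) pr$p else pr$yhat
}

fit_glmnet_baseline <- function(spec, fit, val, config) {
  x <- edge_matrix(fit)
  family <- if (spec$task == "classification") "binomial" else "gaussian"
  y <- if (spec$task == "classification") as.integer(fit$risk == "high")
       else fit$scores
  lambdas <- sort(spec$grid$lambda, decreasing = TRUE)
  m <- glmnet::glmnet(x, y, family = family, alpha = 0, lambda = lambdas,
                      standardize = TRUE)
  best <- lambdas[1L]
  if (!is.null(val) && length(val) > 0L) {
    vx <- edge_matrix(val)
    vy <- if (spec$task == "classification") as.integer(val$risk == "high")
          else val$scores
    losses <- vapply(lambdas, function(l) {
      p <- as.vector(stats::predict(m, vx, s = l, type = "response"))
      if (spec$task == "classification") cross_entropy_loss(p, vy)
      else mean((p - vy)^2)
    }, numeric(1L))
    best <- lambdas[which.min(losses)]
  }
  structure(list(glmnet = m, lambda = best, task = spec$task),
            class = "conn_lr_model")
}

#' @export
predict.conn_lr_model <- function(object, newdata, ...) {
  x <- edge_matrix(newdata)
  p <- as.vector(stats::predict(object$glmnet, x, s = object$lambda,
                                type = "response"))
  if (object$task == "classification")
    data.frame(subject_id = newdata$ids, p = p)
  else data.frame(subject_id = newdata$ids, yhat = p)
}

fit_svm_baseline <- function(spec, fit, val, kernel) {
  x <- edge_matrix(fit)
  classify <- spec$task == "classification"
  y <- if (classify) factor(fit$risk, levels = c("low", "high"))
       else fit$scores
  gamma <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
  fit_one <- function(cost)
    e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
               probability = classify, scale = FALSE)
  costs <- spec$grid$cost
  models <- lapply(costs, fit_one)
  best <- 1L
  if (!is.null(val) && length(val) > 0L) {
    vx <- edge_matrix(val)
    losses <- vapply(models, function(m) {
      if (classify) {
        pred <- stats::predict(m, vx)
        mean(pred != factor(val$risk, levels = c("low", "high")))
      } else mean(abs(stats::predict(m, vx) - val$scores))
    }, numeric(1L))
    best <- which.min(losses)
  }
  structure(list(svm = models[[best]], cost = costs[best], task = spec$task),
            class = "conn_svm_model")
}

#' @export
predict.conn_svm_model <- function(object, newdata, ...) {
  x <- edge_matrix(newdata)
  if (object$task == "classification") {
    pred <- stats::predict(object$svm, x, probability = TRUE)
    p <- attr(pred, "probabilities")[, "high"]
    data.frame(subject_id = newdata$ids, p = as.vector(p))
  } else {
    data.frame(subject_id = newdata$ids,
               yhat = as.vector(stats::predict(object$svm, x)))
  }
}

build_dnn_net <- function(task, dropout, pretrained = NULL) {
  out_dim <- if (task == "classification") 2L else 1L
  net <- list(layer_dense(N_EDGES, 256L),
              layer_batchnorm(256L),
              layer_relu(),
              layer_dropout(dropout),
              layer_dense(256L, 64L),
              layer_batchnorm(64L),
              layer_relu(),
              layer_dropout(dropout),
              layer_dense(64L, out_dim, init_sd = sqrt(1 / 64)))
  if (!is.null(pretrained)) {
    net[[1L]]$params <- pretrained$enc1
    net[[5L]]$params <- pretrained$enc2
  }
  net
}

fit_dnn_baseline <- function(spec, fit, val, config, pretrained = NULL) {
  x <- edge_matrix(fit)
  center <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, sds, "/")
  y <- nn_target(spec$task, if (spec$task == "classification") fit$risk
                 else fit$scores)
  val_x <- NULL; val_y <- NULL
  if (!is.null(val) && length(val) > 0L) {
    val_x <- sweep(sweep(edge_matrix(val), 2L, center), 2L, sds, "/")
    val_y <- nn_target(spec$task, if (spec$task == "classification") val$risk
                       else val$scores)
  }
  res <- withr::with_seed(config$seed, {
    net <- build_dnn_net(spec$task, config$dropout, pretrained)
    nn_train(net, xs, y, spec$task, epochs = config$epochs,
             batch_size = config$batch_size, lr = config$learning_rate,
             val_x = val_x, val_y = val_y,
             weight_decay = config$weight_decay %||% 0)
  })
  structure(list(net = res$net, history = res$history, center = center,
                 sds = sds, task = spec$task,
                 pretrained = !is.null(pretrained)),
            class = "conn_dnn_model")
}

#' @export
predict.conn_dnn_model <- function(object, newdata, ...) {
  x <- sweep(sweep(edge_matrix(newdata), 2L, object$center), 2L, object$sds,
             "/")
  z <- nn_forward(object$net, x, training = FALSE)$out
  if (object$task == "classification") {
    zs <- z - apply(z, 1L, max)
    data.frame(subject_id = newdata$ids,
               p = exp(zs[, 2L]) / rowSums(exp(zs)))
  } else data.frame(subject_id = newdata$ids, yhat = z[, 1L])
}

build_cnn_net <- function(task, dropout) {
  out_dim <- if (task == "classification") 2L else 1L
  list(layer_conv3(1L, 256L, 90L, 90L),
       layer_relu(),
       layer_maxpool(90L, 90L),
       layer_conv3(256L, 256L, 45L, 45L),
       layer_relu(),
       layer_maxpool(45L, 45L),
       layer_gap(22L, 22L, 256L),
       layer_dense(256L, 256L),
       layer_batchnorm(256L),
       layer_relu(),
       layer_dropout(dropout),
       layer_dense(256L, 64L),
       layer_batchnorm(64L),
       layer_relu(),
       layer_dropout(dropout),
       layer_dense(64L, out_dim, init_sd = sqrt(1 / 64)))
}

fit_cnn_baseline <- function(spec, fit, val, config) {
  center <- mean(fit$conn)
  scale <- stats::sd(fit$conn)
  if (scale == 0) scale <- 1
  conv_x <- function(coh) {
    n <- length(coh)
    x <- matrix(0, 8100L * n, 1L)
    for (s in seq_len(n))
      x[(8100L * (s - 1L) + 1L):(8100L * s), 1L] <-
        as.vector((coh$conn[, , s] - center) / scale)
    x
  }
  x <- conv_x(fit)
  y <- nn_target(spec$task, if (spec$task == "classification") fit$risk
                 else fit$scores)
  val_x <- NULL; val_y <- NULL
  if (!is.null(val) && length(val) > 0L) {
    val_x <- conv_x(val)
    val_y <- nn_target(spec$task, if (spec$task == "classification") val$risk
                       else val$scores)
  }
  res <- withr::with_seed(config$seed, {
    net <- build_cnn_net(spec$task, config$dropout)
    nn_train(net, x, y, spec$task, epochs = config$epochs,
             batch_size = config$batch_size, lr = config$learning_rate,
             val_x = val_x, val_y = val_y, conv_input = TRUE, HW = 8100L,
             weight_decay = config$weight_decay %||% 0)
  })
  structure(list(net = res$net, history = res$history, center = center,
                 scale = scale, task = spec$task),
            class = "conn_cnn_model")
}

#' @export
predict.conn_cnn_model <- function(object, newdata, ...) {
  n <- length(newdata)
  x <- matrix(0, 8100L * n, 1L)
  for (s in seq_len(n))
    x[(8100L * (s - 1L) + 1L):(8100L * s), 1L] <-
      as.vector((newdata$conn[, , s] - object$center) / object$scale)
  z <- nn_forward(object$net, x, training = FALSE)$out
  if (object$task == "classification") {
    zs <- z - apply(z, 1L, max)
    data.frame(subject_id = newdata$ids,
               p = exp(zs[, 2L]) / rowSums(exp(zs)))
  } else data.frame(subject_id = newdata$ids, yhat = z[, 1L])
}

#' Unsupervised reconstruction pre-training for the fully connected model
#'
#' Trains an autoencoder (4005 -> 256 -> 64 -> 256 -> 4005) on the edge
#' vectors of a source cohort with a mean-squared reconstruction objective,
#' and returns the encoder weights used to initialize the fully connected
#' layers of the transfer-learning DNN.
#'
#' @param source Source `conn_cohort` (scores unused).
#' @param config A [train_config()]; `epochs` bounds the reconstruction
#'   training.
#' @return List with `enc1`, `enc2` (dense-layer parameter lists) and
#'   `history` (per-epoch reconstruction loss).
#' @export
pretrain_unsupervised <- function(source, config = train_config()) {
  stopifnot(inherits(source, "conn_cohort"))
  if (length(source) == 0L) stop("pretraining error: empty source cohort")
  x <- edge_matrix(source)
  center <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, sds, "/")
  res <- withr::with_seed(config$seed, {
    net <- list(layer_dense(N_EDGES, 256L),
                layer_relu(),
                layer_dense(256L, 64L),
                layer_relu(),
                layer_dense(64L, 256L),
                layer_relu(),
                layer_dense(256L, N_EDGES, init_sd = sqrt(1 / 256)))
    nn_train(net, xs, xs, "reconstruction", epochs = config$epochs,
             batch_size = config$batch_size, lr = config$learning_rate)
  })
  list(enc1 = res$net[[1L]]$params, enc2 = res$net[[3L]]$params,
       history = res$history)
}
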