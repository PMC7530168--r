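#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.001 and 50 training epochs; the learning rate steps down by a factor
#' of 10 after 30 epochs. Batch size (32) and dropout rate (0.3) are not
#' fixed by the protocol; the defaults were selected once on a held-out
#' synthetic development cohort (see the methods vignette).
#'
#' @param learning_rate Adam initial learning rate (> 0).
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param dropout Dropout rate in the fully connected head layers.
#' @param weight_decay L2 penalty on weight matrices (the very-deep-network
#'   training recipe's conventional regularizer).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 50L,
                         batch_size = 32L, dropout = 0.3,
                         weight_decay = 5e-4, seed = 1L) {
  if (learning_rate <= 0) stop("train config error: learning_rate must be > 0")
  if (epochs < 1L) stop("train config error: epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-entropy loss
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities: `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`. Probabilities
#' are clipped to `[clip, 1-clip]` for numerical safety of the logarithm.
#'
#' @param p Predicted high-risk probabilities.
#' @param y Binary labels (1 = high risk), same length as `p`.
#' @param clip Clipping epsilon (default 1e-7).
#' @return The mean loss (single numeric).
#' @export
cross_entropy_loss <- function(p, y, clip = 1e-7) {
  if (length(p) == 0L || length(p) != length(y))
    stop("loss argument error: need equal-length nonempty inputs")
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Mean absolute error loss
#'
#' `(1/N) * sum(|y - yhat|)`, the loss minimized by the score-regression
#' models.
#'
#' @param predictions Predicted scores.
#' @param scores Observed scores, same length.
#' @return The mean absolute error (single numeric).
#' @export
mae_loss <- function(predictions, scores) {
  if (length(predictions) == 0L || length(predictions) != length(scores))
    stop("loss argument error: need equal-length nonempty inputs")
  mean(abs(scores - predictions))
}

# head architecture: 2 conv layers (256 filters, 3x3, same padding) on the
# 2x2x512 backbone output, then FC 256 and 64 (each with batch normalization
# and dropout) and the task output
build_head <- function(task, dropout = 0.5) {
  out_dim <- if (task == "classification") 2L else 1L
  list(layer_conv3(512L, 256L, 2L, 2L),
       layer_relu(),
       layer_conv3(256L, 256L, 2L, 2L),
       layer_relu(),
       layer_flatten(2L, 2L, 256L),
       layer_dense(1024L, 256L),
       layer_batchnorm(256L),
       layer_relu(),
       layer_dropout(dropout),
       layer_dense(256L, 64L),
       layer_batchnorm(64L),
       layer_relu(),
       layer_dropout(dropout),
       layer_dense(64L, out_dim, init_sd = sqrt(1 / 64)))
}

# index of the last convolutional layer in the head (its post-ReLU
# activations feed Grad-CAM)
HEAD_LAST_CONV_RELU <- 4L

nn_target <- function(task, y) {
  if (task == "classification") as.integer(y == "high") else y
}

#' Fit the transfer-learning CNN
#'
#' Trains the two-stage connectome model: the frozen convolutional backbone
#' (built with [build_backbone()]) maps each 90x90 FA-weighted adjacency
#' matrix to a 2x2 x 512 feature map, and a trainable shallow head (2
#' convolutional layers with 256 3x3 filters, then fully connected layers of
#' 256 and 64 units with batch normalization and dropout) predicts either
#' the high-risk class (two-way softmax trained with cross-entropy) or the
#' continuous cognitive score (linear unit trained with mean absolute
#' error). Optimization is Adam; only head parameters are updated, which the
#' returned backbone checksum certifies.
#'
#' When a validation cohort is given, the head with the lowest validation
#' loss across epochs is returned; otherwise the final epoch's head.
#'
#' @param train Training `conn_cohort`.
#' @param val Optional validation `conn_cohort`.
#' @param task `"classification"` or `"regression"`.
#' @param backbone A `conn_backbone`; built fresh from `config$seed` when
#'   `NULL`.
#' @param config A [train_config()].
#' @param center,scale Affine input rescaling `(m - center)/scale` applied
#'   before the backbone; `NULL` (default) standardizes each matrix by its
#'   own mean and SD. With pretrained backbone weights set these to the map
#'   the weight source expects.
#' @return Object of class `tlcnn` with `print()`, `summary()`, `predict()`
#'   and `plot()` methods.
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(60, default_effect_edges(),
#'                                         seed = 7))
#' fit <- tlcnn(coh[1:45], coh[46:60],
#'              config = train_config(epochs = 5, seed = 7))
#' predict(fit, coh[46:60])
#' }
#' @export
tlcnn <- function(train, val = NULL, task = c("classification", "regression"),
                  backbone = NULL, config = train_config(), center = NULL,
                  scale = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(train, "conn_cohort"))
  if (length(train) == 0L) stop("training argument error: empty cohort")
  if (is.null(backbone)) backbone <- build_backbone(seed = config$seed)
  checksum_before <- backbone_checksum(backbone)

  x <- backbone_features(backbone, train, center, scale)
  y <- nn_target(task, if (task == "classification") train$risk
                 else train$scores)
  val_x <- NULL
  val_y <- NULL
  if (!is.null(val) && length(val) > 0L) {
    val_x <- backbone_features(backbone, val, center, scale)
    val_y <- nn_target(task, if (task == "classification") val$risk
                       else val$scores)
  }
  fit <- withr::with_seed(config$seed, {
    net <- build_head(task, config$dropout)
    nn_train(net, x, y, task, epochs = config$epochs,
             batch_size = config$batch_size, lr = config$learning_rate,
             val_x = val_x, val_y = val_y, conv_input = TRUE, HW = 4L,
             weight_decay = config$weight_decay %||% 0)
  })
  checksum_after <- backbone_checksum(backbone)
  structure(list(net = fit$net, history = fit$history, task = task,
                 backbone = backbone, center = center, scale = scale,
                 config = config, atlas = train$atlas,
                 n_train = length(train),
                 backbone_checksum = c(before = checksum_before,
                                       after = checksum_after)),
            class = "tlcnn")
}

#' Predict from a fitted transfer-learning CNN
#'
#' @param object A fitted `tlcnn` model.
#' @param newdata A `conn_cohort`.
#' @param ... Unused.
#' @return Data frame with `subject_id` and, for classification, `p` (the
#'   softmax probability of the high-risk class); for regression, `yhat`
#'   (the predicted cognitive score).
#' @export
predict.tlcnn <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "conn_cohort"))
  x <- backbone_features(object$backbone, newdata, object$center,
                         object$scale)
  z <- nn_forward(object$net, x, training = FALSE)$out
  if (object$task == "classification") {
    zs <- z - apply(z, 1L, max)
    p <- exp(zs[, 2L]) / rowSums(exp(zs))
    data.frame(subject_id = newdata$ids, p = p)
  } else {
    data.frame(subject_id = newdata$ids, yhat = z[, 1L])
  }
}

#' @export
print.tlcnn <- function(x, ...) {
  cat(sprintf("transfer-learning CNN (%s)\n", x$task))
  cat(sprintf("  frozen backbone: 16 conv layers, %s\n", x$backbone$source))
  cat(sprintf("  head: 2 conv (256 @ 3x3) + FC 256 -> 64 -> %s\n",
              if (x$task == "classification") "softmax(2)" else "linear(1)"))
  cat(sprintf("  trained %d epochs on %d subjects; final train loss %.4f\n",
              nrow(x$history), x$n_train,
              x$history$train_loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.tlcnn <- function(object, ...) {
  h <- object$history
  cat(sprintf("transfer-learning CNN, %s task\n", object$task))
  cat(sprintf("  backbone checksum before/after training: %.6f / %.6f (%s)\n",
              object$backbone_checksum[1L], object$backbone_checksum[2L],
              if (object$backbone_checksum[1L] ==
                  object$backbone_checksum[2L]) "frozen" else "CHANGED"))
  cat(sprintf("  epochs: %d; train loss %.4f -> %.4f\n", nrow(h),
              h$train_loss[1L], h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_loss)))
    cat(sprintf("  best validation loss: %.4f (epoch %d)\n",
                min(h$val_loss, na.rm = TRUE),
                which.min(h$val_loss)))
  invisible(object)
}

#' Plot the training history of a fitted model
#' @param x A fitted `tlcnn` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tlcnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
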