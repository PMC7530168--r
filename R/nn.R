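# Minimal neural-network core: layer forward/backward passes, Adam, and a
# mini-batch training loop. Convolutional activations are (B*H*W) x C
# matrices (rows grouped by sample, column-major spatial within a sample);
# dense activations are B x D matrices. im2col/col2im/maxpool run in C++.

layer_conv3 <- function(cin, cout, H, W, init_sd = sqrt(2 / (9 * cin))) {
  list(type = "conv3", H = H, W = W, cin = cin, cout = cout,
       params = list(W = matrix(stats::rnorm(9 * cin * cout, sd = init_sd),
                                9 * cin, cout),
                     b = numeric(cout)))
}
layer_relu <- function() list(type = "relu", params = list())
layer_maxpool <- function(H, W) list(type = "maxpool", H = H, W = W,
                                     params = list())
layer_flatten <- function(H, W, C) list(type = "flatten", H = H, W = W,
                                        C = C, params = list())
layer_gap <- function(H, W, C) list(type = "gap", H = H, W = W, C = C,
                                    params = list())
layer_dense <- function(din, dout, init_sd = sqrt(2 / din)) {
  list(type = "dense", din = din, dout = dout,
       params = list(W = matrix(stats::rnorm(din * dout, sd = init_sd),
                                din, dout),
                     b = numeric(dout)))
}
layer_batchnorm <- function(d, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", d = d, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, d), beta = numeric(d)),
       run_mean = numeric(d), run_var = rep(1, d))
}
layer_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate,
                                           params = list())

# forward one layer; returns list(out, cache, layer) — layer returned because
# batchnorm updates its running statistics during training
nn_forward_layer <- function(layer, x, training) {
  switch(layer$type,
    conv3 = {
      B <- nrow(x) / (layer$H * layer$W)
      cols <- im2col3_batch(x, B, layer$H, layer$W)
      out <- sweep(cols %*% layer$params$W, 2L, layer$params$b, "+")
      list(out = out, cache = list(cols = cols, B = B), layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      B <- nrow(x) / (layer$H * layer$W)
      mp <- maxpool2_batch(x, B, layer$H, layer$W)
      list(out = mp$out, cache = list(argmax = mp$argmax, n_in = nrow(x)),
           layer = layer)
    },
    flatten = {
      HW <- layer$H * layer$W
      B <- nrow(x) / HW
      a <- array(x, c(HW, B, layer$C))
      out <- matrix(aperm(a, c(2L, 1L, 3L)), B, HW * layer$C)
      list(out = out, cache = list(B = B), layer = layer)
    },
    gap = {
      HW <- layer$H * layer$W
      B <- nrow(x) / HW
      a <- array(x, c(HW, B, layer$C))
      out <- matrix(colMeans(a), B, layer$C)   # mean over spatial dim
      list(out = out, cache = list(B = B), layer = layer)
    },
    dense = {
      out <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        inv <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2L, inv, "*")
        layer$run_mean <- layer$momentum * layer$run_mean +
          (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var +
          (1 - layer$momentum) * v
        cache <- list(xhat = xhat, inv = inv)
      } else {
        inv <- 1 / sqrt(layer$run_var + layer$eps)
        xhat <- sweep(sweep(x, 2L, layer$run_mean), 2L, inv, "*")
        cache <- list(xhat = xhat, inv = inv)
      }
      out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
                   layer$params$beta, "+")
      list(out = out, cache = cache, layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- matrix(stats::runif(length(x)) >= layer$rate,
                       nrow(x), ncol(x))
        scale <- 1 / (1 - layer$rate)
        list(out = x * keep * scale, cache = list(keep = keep, scale = scale),
             layer = layer)
      } else {
        list(out = x, cache = list(keep = NULL), layer = layer)
      }
    },
    stop("unknown layer type: ", layer$type))
}

# backward one layer; returns list(dx, grads)
nn_backward_layer <- function(layer, dout, cache) {
  switch(layer$type,
    conv3 = {
      dW <- crossprod(cache$cols, dout)
      db <- colSums(dout)
      dcols <- tcrossprod(dout, layer$params$W)
      dx <- col2im3_batch(dcols, cache$B, layer$H, layer$W)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    maxpool = list(dx = maxpool2_backward(dout, cache$argmax, cache$n_in),
                   grads = list()),
    flatten = {
      HW <- layer$H * layer$W
      a <- array(dout, c(cache$B, HW, layer$C))
      dx <- matrix(aperm(a, c(2L, 1L, 3L)), HW * cache$B, layer$C)
      list(dx = dx, grads = list())
    },
    gap = {
      HW <- layer$H * layer$W
      # each spatial position receives dout/HW
      a <- array(rep(dout / HW, each = HW), c(HW, cache$B, layer$C))
      dx <- matrix(a, HW * cache$B, layer$C)
      list(dx = dx, grads = list())
    },
    dense = {
      dW <- crossprod(cache$x, dout)
      db <- colSums(dout)
      dx <- tcrossprod(dout, layer$params$W)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    batchnorm = {
      n <- nrow(dout)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$params$gamma, "*")
      # standard batchnorm backward (training-mode statistics)
      term <- sweep(dxhat, 2L, colMeans(dxhat)) -
        cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
      dx <- sweep(term, 2L, cache$inv, "*")
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    dropout = {
      if (is.null(cache$keep)) list(dx = dout, grads = list())
      else list(dx = dout * cache$keep * cache$scale, grads = list())
    },
    stop("unknown layer type: ", layer$type))
}

# full-network forward; returns output, per-layer caches and (possibly
# updated) layers
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  acts <- vector("list", length(net))
  for (l in seq_along(net)) {
    step <- nn_forward_layer(net[[l]], x, training)
    x <- step$out
    caches[[l]] <- step$cache
    net[[l]] <- step$layer
    acts[[l]] <- x
  }
  list(out = x, caches = caches, net = net, acts = acts)
}

# backward from output gradient; returns parameter grads and per-layer input
# gradients (dacts[[l]] = gradient at the INPUT of layer l)
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  dacts <- vector("list", length(net))
  for (l in rev(seq_along(net))) {
    step <- nn_backward_layer(net[[l]], dout, caches[[l]])
    grads[[l]] <- step$grads
    dacts[[l]] <- step$dx
    dout <- step$dx
  }
  list(grads = grads, dacts = dacts)
}

# loss head: returns list(loss, dout) given network output
nn_loss <- function(z, y, task) {
  n <- nrow(z)
  if (task == "classification") {
    # y: 0/1 vector (1 = high risk); z: n x 2 logits (col 2 = high risk)
    zs <- z - apply(z, 1L, max)
    logZ <- log(rowSums(exp(zs)))
    logp <- zs - logZ
    loss <- -mean(ifelse(y == 1, logp[, 2L], logp[, 1L]))
    p <- exp(logp)
    dout <- p
    dout[cbind(seq_len(n), y + 1L)] <- dout[cbind(seq_len(n), y + 1L)] - 1
    list(loss = loss, dout = dout / n)
  } else if (task == "regression") {
    err <- z[, 1L] - y
    list(loss = mean(abs(err)), dout = matrix(sign(err) / n, n, 1L))
  } else if (task == "reconstruction") {
    err <- z - y
    list(loss = mean(err^2), dout = 2 * err / length(err))
  } else stop("unknown task: ", task)
}

adam_init <- function(net) {
  lapply(net, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim = dim(p) %||% length(p)),
         v = array(0, dim = dim(p) %||% length(p)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# In-place C++ Adam over all parameter arrays. The arrays are owned
# exclusively by the training loop; snapshots taken for epoch selection are
# deep-copied by copy_net_params().
adam_step <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  c1 <- 1 / (1 - beta1^t)
  c2 <- 1 / (1 - beta2^t)
  for (l in seq_along(net)) {
    for (nm in names(net[[l]]$params)) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      # L2 decay applies to weight matrices, not biases or normalization
      wd <- if (nm == "W") weight_decay else 0
      adam_update(net[[l]]$params[[nm]], state[[l]][[nm]]$m,
                  state[[l]][[nm]]$v, g, lr, beta1, beta2, c1, c2, eps, wd)
    }
  }
  list(net = net, state = state)
}

copy_net_params <- function(net) {
  lapply(net, function(l) {
    l$params <- lapply(l$params, function(p) p + 0)  # force a fresh array
    l
  })
}

# rows of a conv-layout activation matrix belonging to the given samples
conv_rows <- function(idx, HW) {
  as.vector(outer(seq_len(HW), (idx - 1L) * HW, "+"))
}

# subset an activation batch (conv layout needs block rows)
subset_batch <- function(x, idx, conv_input, HW) {
  if (conv_input) x[conv_rows(idx, HW), , drop = FALSE]
  else x[idx, , drop = FALSE]
}

# mini-batch trainer. x/val_x follow the layout of the first layer
# (conv layout when conv_input = TRUE, sample rows otherwise). y is a 0/1
# vector, score vector, or reconstruction target matrix. Selection across
# epochs is by validation loss when a validation set is supplied; otherwise
# the final-epoch network is returned.
# recompute batch-normalization statistics for a fixed network by one
# forward pass over (up to 256 of) the training inputs ("precise BN"):
# removes the lag between running statistics and the selected weights
nn_recalibrate_bn <- function(net, x, conv_input = FALSE, HW = 1L,
                              max_samples = 256L) {
  has_bn <- vapply(net, function(l) l$type == "batchnorm", logical(1L))
  if (!any(has_bn)) return(net)
  n <- if (conv_input) nrow(x) / HW else nrow(x)
  if (n > max_samples) {
    keep <- unique(round(seq(1L, n, length.out = max_samples)))
    x <- subset_batch(x, keep, conv_input, HW)
  }
  for (l in seq_along(net)) {
    if (net[[l]]$type == "batchnorm") {
      mu <- colMeans(x)
      v <- colMeans(sweep(x, 2L, mu)^2)
      net[[l]]$run_mean <- mu
      net[[l]]$run_var <- v
    }
    if (net[[l]]$type == "dropout") next  # identity at inference
    x <- nn_forward_layer(net[[l]], x, training = FALSE)$out
  }
  net
}

nn_train <- function(net, x, y, task, epochs = 50L, batch_size = 16L,
                     lr = 1e-3, val_x = NULL, val_y = NULL,
                     conv_input = FALSE, HW = 1L, lr_decay_epochs = 30L,
                     lr_decay_factor = 0.1, weight_decay = 0) {
  n <- if (conv_input) nrow(x) / HW else nrow(x)
  n <- as.integer(n)
  state <- adam_init(net)
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, net = NULL)
  sel_y <- function(idx) if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]
  for (ep in seq_len(epochs)) {
    # step decay of the initial learning rate
    lr_ep <- lr * lr_decay_factor^((ep - 1L) %/% lr_decay_epochs)
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- subset_batch(x, idx, conv_input, HW)
      fw <- nn_forward(net, xb, training = TRUE)
      net <- fw$net
      ls <- nn_loss(fw$out, sel_y(idx), task)
      if (!is.finite(ls$loss))
        stop("training error: non-finite loss at epoch ", ep)
      bw <- nn_backward(net, fw$caches, ls$dout)
      t_step <- t_step + 1L
      upd <- adam_step(net, bw$grads, state, t_step, lr_ep,
                       weight_decay = weight_decay)
      net <- upd$net
      state <- upd$state
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    vloss <- NA_real_
    if (!is.null(val_x)) {
      # evaluate the network exactly as it would be deployed: with precise
      # BN statistics recomputed from the training inputs
      cal <- nn_recalibrate_bn(net, x, conv_input, HW)
      fv <- nn_forward(cal, val_x, training = FALSE)
      vloss <- nn_loss(fv$out, val_y, task)$loss
      # epoch selection criterion: balanced error on the validation split
      # for classification (robust to calibration drift at threshold 0.5),
      # the validation loss itself otherwise; CE ties broken by loss
      vsel <- vloss
      if (task == "classification" && length(unique(val_y)) == 2L) {
        zs <- fv$out - apply(fv$out, 1L, max)
        pv <- exp(zs[, 2L]) / rowSums(exp(zs))
        sens <- mean(pv[val_y == 1L] >= 0.5)
        spec <- mean(pv[val_y == 0L] < 0.5)
        vsel <- 1 - (sens + spec) / 2 + 1e-6 * vloss
      }
      if (vsel < best$loss)
        best <- list(loss = vsel, net = copy_net_params(cal))
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = vloss))
  }
  final <- if (!is.null(val_x) && !is.null(best$net)) best$net
           else nn_recalibrate_bn(net, x, conv_input, HW)
  list(net = final, history = history)
}

# parameter checksum (sum of all parameters); used to assert frozen weights
nn_checksum <- function(params) sum(vapply(params, function(p)
  sum(vapply(p, sum, numeric(1L))), numeric(1L)))
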