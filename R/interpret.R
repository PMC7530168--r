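# bilinear upsampling with corner alignment from an h x w grid to 90 x 90
upsample_bilinear <- function(m, out = N_REGIONS) {
  h <- nrow(m); w <- ncol(m)
  if (h == out && w == out) return(m)
  pos <- function(n_in) {
    if (n_in == 1L) rep(1, out)
    else 1 + (seq_len(out) - 1) * (n_in - 1) / (out - 1)
  }
  u <- pos(h); v <- pos(w)
  i0 <- pmin(floor(u), h - 1L); fi <- u - i0
  j0 <- pmin(floor(v), w - 1L); fj <- v - j0
  if (h == 1L) { i0 <- rep(1L, out); fi <- rep(0, out) }
  if (w == 1L) { j0 <- rep(1L, out); fj <- rep(0, out) }
  top <- m[i0, j0, drop = FALSE] * outer(1 - fi, 1 - fj) +
    m[i0, pmin(j0 + 1L, w), drop = FALSE] * outer(1 - fi, fj)
  bot <- m[pmin(i0 + 1L, h), j0, drop = FALSE] * outer(fi, 1 - fj) +
    m[pmin(i0 + 1L, h), pmin(j0 + 1L, w), drop = FALSE] * outer(fi, fj)
  top + bot
}

#' Grad-CAM edge importance for one subject
#'
#' Gradient-weighted class activation mapping on the connectome input: for
#' the last convolutional layer of the model, each channel's weight is the
#' spatial mean of the gradient of the target score with respect to that
#' channel's activations; the map is the ReLU of the channel-weighted sum of
#' activations, bilinearly upsampled to 90x90, symmetrized as
#' `(M + t(M))/2` and zeroed on the diagonal. The target score is the
#' high-risk logit for classification models and the predicted score for
#' regression models.
#'
#' Only models with convolutional layers support Grad-CAM (the
#' transfer-learning CNN, where the tap is the second head convolution on
#' the 2x2 backbone grid, and the plain CNN baseline, tapped at its second
#' convolution); fully connected models raise an unsupported-model error.
#'
#' @param model A fitted `tlcnn` or CNN-baseline model.
#' @param subject A one-subject `conn_cohort` (first subject used).
#' @return A 90x90 nonnegative symmetric importance matrix with zero
#'   diagonal (class `importance_map` attribute set).
#' @export
gradcam <- function(model, subject) {
  stopifnot(inherits(subject, "conn_cohort"))
  if (inherits(model, "tlcnn")) {
    x <- backbone_features(model$backbone, subject[1L], model$center,
                           model$scale)
    net <- model$net
    act_layer <- HEAD_LAST_CONV_RELU  # post-ReLU output of head conv 2
    grad_layer <- HEAD_LAST_CONV_RELU + 1L
    hw <- c(2L, 2L)
    task <- model$task
  } else if (inherits(model, "conn_cnn_model")) {
    x <- matrix(as.vector((subject$conn[, , 1L] - model$center) /
                            model$scale), 8100L, 1L)
    net <- model$net
    act_layer <- 5L   # post-ReLU output of conv 2 (45 x 45)
    grad_layer <- 6L
    hw <- c(45L, 45L)
    task <- model$task
  } else {
    stop("unsupported-model error: Grad-CAM needs a convolutional model")
  }
  fw <- nn_forward(net, x, training = FALSE)
  z <- fw$out
  dout <- matrix(0, 1L, ncol(z))
  dout[1L, if (task == "classification") 2L else 1L] <- 1
  bw <- nn_backward(fw$net, fw$caches, dout)
  A <- fw$acts[[act_layer]]            # (H*W) x C activations
  G <- bw$dacts[[grad_layer]]          # gradient wrt those activations
  w <- colMeans(G)                     # per-channel spatial-mean weight
  cam <- as.vector(A %*% w)
  cam <- pmax(cam, 0)
  map <- upsample_bilinear(matrix(cam, hw[1L], hw[2L]))
  map <- (map + t(map)) / 2
  diag(map) <- 0
  structure(map, class = c("importance_map", class(map)))
}

#' Aggregate per-subject importance maps
#'
#' Each map is min-max normalized to \[0, 1\] (Grad-CAM magnitudes are not
#' comparable across subjects), then the entrywise mean is taken. All-zero
#' maps stay zero.
#'
#' @param maps Nonempty list of 90x90 importance matrices.
#' @return A 90x90 aggregated importance matrix.
#' @export
aggregate_importance <- function(maps) {
  if (length(maps) == 0L) stop("aggregation error: empty map list")
  acc <- matrix(0, N_REGIONS, N_REGIONS)
  for (m in maps) {
    stopifnot(all(dim(m) == N_REGIONS))
    rng <- range(m)
    if (rng[2L] > rng[1L]) m <- (m - rng[1L]) / (rng[2L] - rng[1L])
    acc <- acc + m
  }
  out <- acc / length(maps)
  structure(out, class = c("importance_map", class(out)))
}

#' Rank the most important edges of an importance map
#'
#' Orders the 4005 upper-triangle edges by importance (ties broken
#' lexicographically by region-index pair, so output is deterministic) and
#' returns the top k with anatomical names. When a cohort is supplied, the
#' Pearson correlation of each ranked edge's FA weight with the cognitive
#' score is appended.
#'
#' @param map 90x90 importance matrix.
#' @param atlas A `conn_atlas`.
#' @param k Number of edges to report (default 15).
#' @param coh Optional `conn_cohort` for the outcome-correlation column.
#' @return Data frame with columns `region_a`, `abbrev_a`, `region_b`,
#'   `abbrev_b`, `importance` and, with a cohort, `r`.
#' @export
rank_edges <- function(map, atlas = load_atlas(), k = 15L, coh = NULL) {
  stopifnot(all(dim(map) == N_REGIONS))
  if (k > N_EDGES) stop("ranking error: k exceeds the 4005 edges")
  ut <- which(upper.tri(map), arr.ind = TRUE)
  imp <- map[ut]
  ord <- order(-imp, ut[, 1L], ut[, 2L])[seq_len(k)]
  sel <- ut[ord, , drop = FALSE]
  out <- data.frame(
    region_a = atlas$regions$name[sel[, 1L]],
    abbrev_a = atlas$regions$abbreviation[sel[, 1L]],
    region_b = atlas$regions$name[sel[, 2L]],
    abbrev_b = atlas$regions$abbreviation[sel[, 2L]],
    importance = imp[ord])
  if (!is.null(coh)) {
    ec <- edge_outcome_correlation(coh, data.frame(i = sel[, 1L],
                                                   j = sel[, 2L]))
    out$r <- ec$r
  }
  out
}

#' Correlation of edge weights with the cognitive outcome
#'
#' Pearson correlation between each listed edge's FA weight and the
#' cognitive score across a cohort. Zero-variance edges are flagged
#' undefined (correlation set to `NA`) rather than failing.
#'
#' @param coh A `conn_cohort` with at least 3 subjects.
#' @param edges Data frame with region-index columns `i`, `j`.
#' @return `edges` with appended columns `r` and `undefined`.
#' @export
edge_outcome_correlation <- function(coh, edges) {
  stopifnot(inherits(coh, "conn_cohort"))
  if (length(coh) < 3L) stop("correlation error: need at least 3 subjects")
  edges <- as.data.frame(edges)
  r <- numeric(nrow(edges))
  undef <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    w <- coh$conn[edges$i[e], edges$j[e], ]
    if (stats::sd(w) == 0 || stats::sd(coh$scores) == 0) {
      r[e] <- NA_real_
      undef[e] <- TRUE
    } else {
      r[e] <- stats::cor(w, coh$scores)
    }
  }
  edges$r <- r
  edges$undefined <- undef
  edges
}
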