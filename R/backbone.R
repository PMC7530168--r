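VGG_WIDTHS <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L,
                512L, 512L, 512L, 512L, 512L, 512L, 512L, 512L)
VGG_POOL_AFTER <- c(2L, 4L, 8L, 12L, 16L)

#' Build the frozen convolutional backbone
#'
#' Constructs the fixed feature extractor: 16 convolutional layers with 3x3
#' kernels and ReLU in the very-deep configuration (channel widths 64, 64,
#' 128, 128, 256 x4, 512 x8), with five 2x2/stride-2 max-pooling stages after
#' layers 2, 4, 8, 12 and 16. On a 90x90 input the stack yields a 2x2 spatial
#' map with 512 channels (90 -> 45 -> 22 -> 11 -> 5 -> 2 by floor halving).
#' The backbone is always frozen: its parameters never receive gradient
#' updates, and a checksum asserts this after training.
#'
#' Weights come either from an external pretrained-weights file (an RDS
#' holding `list(Ws = <list of 16 (9*cin) x cout matrices>, bs = <list of 16
#' bias vectors>)`, e.g. exported from a natural-image pretrained very-deep
#' network) or from a deterministic He-normal random initialization of the
#' same architecture. With random weights the transfer-learning benefit of
#' natural-image pretraining is absent, but the extractor is still a fixed,
#' reproducible nonlinear map, so every pipeline contract remains testable
#' offline.
#'
#' @param weights_file Optional path to a pretrained-weights RDS file.
#' @param seed Seed for the deterministic random initialization (ignored when
#'   `weights_file` is given).
#' @return An environment of class `conn_backbone` with elements `Ws`, `bs`,
#'   `pool_after`, `source`, `checksum`.
#' @export
build_backbone <- function(weights_file = NULL, seed = 1L) {
  bk <- new.env(parent = emptyenv())
  if (!is.null(weights_file)) {
    if (!file.exists(weights_file))
      stop("backbone load error: no such file: ", weights_file)
    w <- readRDS(weights_file)
    if (!is.list(w) || !all(c("Ws", "bs") %in% names(w)) ||
        length(w$Ws) != 16L)
      stop("backbone load error: weights file incompatible with the ",
           "16-conv-layer architecture")
    cin <- 3L
    for (l in 1:16) {
      if (!all(dim(w$Ws[[l]]) == c(9L * cin, VGG_WIDTHS[l])))
        stop("backbone load error: layer ", l, " weight shape mismatch")
      cin <- VGG_WIDTHS[l]
    }
    bk$Ws <- w$Ws
    bk$bs <- w$bs
    bk$source <- "pretrained-file"
  } else {
    withr::with_seed(seed, {
      Ws <- vector("list", 16L)
      bs <- vector("list", 16L)
      cin <- 3L
      for (l in 1:16) {
        fan_in <- 9L * cin
        Ws[[l]] <- matrix(stats::rnorm(fan_in * VGG_WIDTHS[l],
                                       sd = sqrt(2 / fan_in)),
                          fan_in, VGG_WIDTHS[l])
        bs[[l]] <- numeric(VGG_WIDTHS[l])
        cin <- VGG_WIDTHS[l]
      }
      bk$Ws <- Ws
      bk$bs <- bs
    })
    bk$source <- sprintf("deterministic-random(seed=%d)", as.integer(seed))
  }
  bk$pool_after <- VGG_POOL_AFTER
  bk$checksum <- backbone_checksum(bk)
  class(bk) <- "conn_backbone"
  bk
}

#' Parameter checksum of the backbone (frozen-weight audit)
#' @param backbone A `conn_backbone`.
#' @return A single numeric checksum.
#' @export
backbone_checksum <- function(backbone) {
  sum(vapply(backbone$Ws, sum, numeric(1L))) +
    sum(vapply(backbone$bs, sum, numeric(1L)))
}

#' @export
print.conn_backbone <- function(x, ...) {
  cat("frozen convolutional backbone: 16 conv layers (3x3), 5 max-pool",
      "stages\n")
  cat("  weights:", x$source, "\n")
  cat("  90x90 input -> 2x2 x 512 feature map\n")
  invisible(x)
}

#' Adapt a connectome matrix to the backbone input tensor
#'
#' The backbone expects a 3-channel image; a connectome is a single-channel
#' 90x90 matrix. The adapter replicates the matrix into three identical
#' channels and applies an affine rescaling `(m - center) / scale`. The
#' default (`NULL`) standardizes each matrix by its own mean and SD
#' (per-image standardization), which removes global FA offsets between
#' subjects and keeps the map deterministic per subject; with pretrained
#' backbone weights pass the fixed `center`/`scale` the weight source
#' expects.
#'
#' @param m 90x90 connectome matrix.
#' @param center,scale Affine rescaling parameters, or `NULL` for per-image
#'   standardization.
#' @return An 8100 x 3 matrix (column-major spatial by channel), the
#'   single-sample input layout of the backbone.
#' @export
adapt_input <- function(m, center = NULL, scale = NULL) {
  stopifnot(is.matrix(m), all(dim(m) == N_REGIONS))
  if (is.null(center)) center <- mean(m)
  if (is.null(scale)) {
    scale <- stats::sd(m)
    if (scale == 0) scale <- 1
  }
  ch <- as.vector((m - center) / scale)
  matrix(ch, N_REGIONS * N_REGIONS, 3L)
}

# Frozen features for a cohort: returns a (4*n) x 512 matrix in the conv
# activation layout (4 spatial positions per subject, 512 channels). Because
# the backbone is frozen and the input map is a fixed affine rescale,
# features of original (non-synthetic) subjects are memoized in the backbone
# environment keyed by subject id and rescaling constants.
backbone_features <- function(backbone, coh, center = NULL, scale = NULL,
                              batch = 16L) {
  stopifnot(inherits(backbone, "conn_backbone"))
  if (is.null(backbone$cache)) backbone$cache <- new.env(parent = emptyenv())
  n <- length(coh)
  cacheable <- if (is.null(coh$contributors)) rep(TRUE, n)
               else vapply(coh$contributors, is.null, logical(1L))
  keys <- sprintf("%s|%s|%s", coh$tokens,
                  if (is.null(center)) "img" else sprintf("%.17g", center),
                  if (is.null(scale)) "img" else sprintf("%.17g", scale))
  feats <- matrix(0, 4L * n, 512L)
  todo <- integer()
  for (s in seq_len(n)) {
    if (cacheable[s] && !is.null(backbone$cache[[keys[s]]]))
      feats[(4L * (s - 1L) + 1L):(4L * s), ] <- backbone$cache[[keys[s]]]
    else todo <- c(todo, s)
  }
  for (start in seq_len(ceiling(length(todo) / batch))) {
    idx <- todo[((start - 1L) * batch + 1L):min(start * batch, length(todo))]
    inp <- array(0, dim = c(N_REGIONS * N_REGIONS, 3L, length(idx)))
    for (t in seq_along(idx))
      inp[, , t] <- adapt_input(coh$conn[, , idx[t]], center, scale)
    out <- backbone_forward_batch(inp, backbone$Ws, backbone$bs,
                                  backbone$pool_after, N_REGIONS, N_REGIONS)
    for (t in seq_along(idx)) {
      slab <- matrix(out[, t], 4L, 512L)
      feats[(4L * (idx[t] - 1L) + 1L):(4L * idx[t]), ] <- slab
      if (cacheable[idx[t]]) backbone$cache[[keys[idx[t]]]] <- slab
    }
  }
  feats
}
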