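#' Configuration for binned convex-combination oversampling
#'
#' Oversampling for continuous labels: training subjects are divided into
#' five score bins (below 70, 70--80, 80--90, 90--100, above 100), bins are
#' visited round-robin, and each visit synthesizes one new sample as a convex
#' combination of a randomly chosen bin member and its k nearest neighbours,
#' with the label combined identically. Expansion continues until the
#' training set reaches `expansion_factor` times its original size.
#'
#' Bin intervals are left-closed: \[40,70), \[70,80), \[80,90), \[90,100),
#' \[100,160\].
#'
#' @param bin_edges Interior score thresholds, strictly increasing
#'   (default `c(70, 80, 90, 100)`).
#' @param k Neighbour count (default 5).
#' @param expansion_factor Final size as a multiple of the input size
#'   (default 10).
#' @param seed Integer seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(bin_edges = c(70, 80, 90, 100), k = 5L,
                                expansion_factor = 10, seed = 1L) {
  if (k < 1L) stop("augmentation config error: k must be >= 1")
  if (expansion_factor < 1)
    stop("augmentation config error: expansion_factor must be >= 1")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("augmentation config error: bin edges must be strictly increasing")
  structure(list(bin_edges = bin_edges, k = as.integer(k),
                 expansion_factor = expansion_factor, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Score bin index
#'
#' @param score Numeric scores in \[40, 160\].
#' @param config An `augmentation_config`.
#' @return Integer bin indices in 0..4 (0-based, matching the five bins
#'   below 70, 70--80, 80--90, 90--100, above 100; left-closed).
#' @export
assign_bin <- function(score, config = augmentation_config()) {
  if (any(score < 40 | score > 160))
    stop("score domain error: scores must lie in [40, 160]")
  findInterval(score, config$bin_edges)  # left-closed: [70,80) -> 1
}

#' Synthesize one sample as a convex combination
#'
#' The synthetic connectome is the entrywise convex combination
#' `x_syn = sum(w_m * x_m)` of the base subject and its k neighbours, and the
#' synthetic label is the identical combination of their scores. Weights must
#' be nonnegative and sum to 1, so every synthetic entry and the synthetic
#' score lie within the contributors' range, and symmetry and the zero
#' diagonal are preserved exactly.
#'
#' @param base One-subject `conn_cohort` (or a cohort; first subject used).
#' @param neighbors `conn_cohort` of the k neighbours.
#' @param weights Numeric vector of length k+1 (base first).
#' @return List with `x_syn` (90x90 matrix), `y_syn` (score), `weights`, and
#'   `contributor_ids`.
#' @export
synthesize_sample <- function(base, neighbors, weights) {
  stopifnot(inherits(base, "conn_cohort"), inherits(neighbors, "conn_cohort"))
  k <- length(neighbors)
  if (length(weights) != k + 1L)
    stop("augmentation argument error: need k+1 weights")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("augmentation argument error: weights must be nonnegative and sum to 1")
  x_syn <- weights[1L] * base$conn[, , 1L]
  for (m in seq_len(k))
    x_syn <- x_syn + weights[m + 1L] * neighbors$conn[, , m]
  y_syn <- sum(weights * c(base$scores[1L], neighbors$scores))
  list(x_syn = x_syn, y_syn = y_syn, weights = weights,
       contributor_ids = c(base$ids[1L], neighbors$ids))
}

#' Oversample a training cohort
#'
#' Expands `training` to `round(expansion_factor * N)` subjects: all
#' originals are retained and synthetic subjects are added one at a time,
#' visiting the five score bins round-robin (empty bins are skipped). For
#' each visit a base subject is drawn uniformly from the bin; its k nearest
#' neighbours by Euclidean distance on edge vectors are found within the bin
#' when the bin holds at least k+1 subjects, otherwise in the whole training
#' set; combination weights are drawn uniformly on the (k+1)-simplex. Every
#' synthetic subject records its contributor ids, which the cross-validation
#' driver audits against test sets.
#'
#' @param training A `conn_cohort` with at least k+1 subjects.
#' @param config An `augmentation_config`.
#' @return A `conn_cohort` with provenance `"augmented"`; originals first.
#' @export
augment <- function(training, config = augmentation_config()) {
  stopifnot(inherits(training, "conn_cohort"),
            inherits(config, "augmentation_config"))
  n0 <- length(training)
  if (n0 == 0L) stop("augmentation argument error: empty training set")
  if (n0 < config$k + 1L)
    stop("augmentation argument error: need at least k+1 = ", config$k + 1L,
         " subjects")
  n_target <- round(config$expansion_factor * n0)
  n_syn <- n_target - n0
  out <- training
  out$provenance <- "augmented"
  if (is.null(out$contributors)) out$contributors <- vector("list", n0)
  if (n_syn <= 0L) return(out)

  bins <- assign_bin(training$scores, config)
  ev <- edge_matrix(training)
  k <- config$k
  syn_conn <- array(0, dim = c(N_REGIONS, N_REGIONS, n_syn))
  syn_scores <- numeric(n_syn)
  syn_contrib <- vector("list", n_syn)

  withr::with_seed(config$seed, {
    occupied <- sort(unique(bins))
    cursor <- 0L
    for (s in seq_len(n_syn)) {
      b <- occupied[cursor %% length(occupied) + 1L]
      cursor <- cursor + 1L
      members <- which(bins == b)
      base_idx <- members[sample.int(length(members), 1L)]
      pool <- if (length(members) >= k + 1L) members else seq_len(n0)
      pool <- setdiff(pool, base_idx)
      d2 <- colSums((t(ev[pool, , drop = FALSE]) - ev[base_idx, ])^2)
      nb_idx <- pool[order(d2)[seq_len(k)]]
      w <- stats::rexp(k + 1L)          # normalized Exp(1) = flat Dirichlet
      w <- w / sum(w)
      draw <- synthesize_sample(training[base_idx], training[nb_idx], w)
      syn_conn[, , s] <- draw$x_syn
      syn_scores[s] <- draw$y_syn
      syn_contrib[[s]] <- draw$contributor_ids
    }
  })
  syn <- cohort(sprintf("syn%05d", seq_len(n_syn)), syn_conn, syn_scores,
                atlas = training$atlas, provenance = "augmented",
                contributors = syn_contrib, validate = FALSE)
  bind_cohorts(out, syn, provenance = "augmented")
}
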