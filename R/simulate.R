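#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the prediction pipeline
#' assumes: symmetric 90x90 FA-weighted matrices; cognitive scores drawn
#' Normal(100, 15) and clamped to the 40--160 scale (so roughly a quarter of
#' subjects fall in the high-risk, score < 90 group); and a chosen set of
#' "effect" edges whose weights move linearly with the standardized score.
#'
#' The effect model for an edge with strength `alpha` is
#' `w = baseline + alpha * effect_scale * z + noise`, with
#' `z = (score - score_mean)/score_sd` computed after clamping, and
#' `noise ~ Normal(0, edge_noise_sd)` drawn once per undirected edge. All
#' weights are clipped to `fa_bounds` and the matrix is symmetric with a zero
#' diagonal by construction.
#'
#' @param n Number of subjects.
#' @param effect_edges Data frame with columns `i`, `j`, `alpha`
#'   (signed strength in \[-1, 1\], region pair i < j), or `NULL` for a null
#'   cohort with no score-linked edges.
#' @param baseline_matrix 90x90 baseline mean-FA pattern; default constant
#'   0.4 off the diagonal (mid-range FA).
#' @param edge_noise_sd Edge noise SD in FA units (default 0.02).
#' @param score_mean,score_sd Score distribution parameters
#'   (defaults 100, 15 — the standardized scale).
#' @param score_bounds,fa_bounds Clamp bounds for scores and edge weights.
#' @param effect_scale FA units per score SD for a full-strength
#'   (`|alpha| = 1`) edge; default 0.1 keeps effect edges inside `fa_bounds`
#'   while detectable at cohort sizes near 80.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n, effect_edges = NULL, baseline_matrix = NULL,
                             edge_noise_sd = 0.02, score_mean = 100,
                             score_sd = 15, score_bounds = c(40, 160),
                             fa_bounds = c(0.05, 0.95), effect_scale = 0.1,
                             seed = 1L) {
  if (n < 1L) stop("generator config error: n must be >= 1")
  if (edge_noise_sd < 0) stop("generator config error: edge_noise_sd < 0")
  if (is.null(baseline_matrix)) {
    baseline_matrix <- matrix(0.4, N_REGIONS, N_REGIONS)
    diag(baseline_matrix) <- 0
  } else {
    baseline_matrix <- validate_connectome(baseline_matrix)
  }
  if (!is.null(effect_edges)) {
    effect_edges <- as.data.frame(effect_edges)
    stopifnot(all(c("i", "j", "alpha") %in% names(effect_edges)))
    if (any(effect_edges$i == effect_edges$j))
      stop("generator config error: effect edge on the diagonal")
    if (any(effect_edges$i < 1 | effect_edges$j > N_REGIONS))
      stop("generator config error: effect edge outside 1..90")
    if (any(abs(effect_edges$alpha) > 1))
      stop("generator config error: |alpha| must be <= 1")
  }
  structure(list(n = as.integer(n), effect_edges = effect_edges,
                 baseline_matrix = baseline_matrix,
                 edge_noise_sd = edge_noise_sd, score_mean = score_mean,
                 score_sd = score_sd, score_bounds = score_bounds,
                 fa_bounds = fa_bounds, effect_scale = effect_scale,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default planted effect edges for a separable synthetic cohort
#'
#' Three anatomically named edges whose weights track the cognitive score,
#' chosen to mirror connections repeatedly reported as discriminative for
#' neonatal cognitive outcome: left precentral--left putamen (positive),
#' left--right superior occipital (positive) and right hippocampus--right
#' putamen (negative).
#'
#' @param alpha Absolute effect strength applied to all three edges
#'   (default 0.8).
#' @param atlas Atlas used to resolve abbreviations.
#' @return Data frame with columns `i`, `j`, `alpha`.
#' @export
default_effect_edges <- function(alpha = 0.8, atlas = load_atlas()) {
  ab <- rbind(c("PreCG-L", "PUT-L", +1),
              c("SOG-L", "SOG-R", +1),
              c("HIP-R", "PUT-R", -1))
  i <- atlas_index(atlas, ab[, 1L])
  j <- atlas_index(atlas, ab[, 2L])
  data.frame(i = pmin(i, j), j = pmax(i, j),
             alpha = alpha * as.numeric(ab[, 3L]))
}

#' Generate a synthetic cohort
#'
#' Draws scores, builds score-linked connectomes under the linear effect
#' model of [generator_config()], and labels risk groups. Byte-identical
#' across runs with equal configs.
#'
#' @param config A `generator_config`.
#' @param id_prefix Prefix for generated subject ids.
#' @return A `conn_cohort` with provenance `"synthetic"`.
#' @export
generate_cohort <- function(config, id_prefix = "sub") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n
    scores <- stats::rnorm(n, config$score_mean, config$score_sd)
    scores <- pmin(pmax(scores, config$score_bounds[1L]),
                   config$score_bounds[2L])
    z <- (scores - config$score_mean) / config$score_sd
    base_edges <- {
      tm <- t(config$baseline_matrix); tm[lower.tri(tm)]
    }
    slope <- numeric(N_EDGES)
    if (!is.null(config$effect_edges) && nrow(config$effect_edges) > 0L) {
      pos <- edge_index(config$effect_edges$i, config$effect_edges$j)
      slope[pos] <- config$effect_edges$alpha * config$effect_scale
    }
    conn <- array(0, dim = c(N_REGIONS, N_REGIONS, n))
    # one draw for all edge noise; column s is subject s's upper triangle,
    # in the same stream order as per-subject draws
    noise <- matrix(stats::rnorm(N_EDGES * n, 0, config$edge_noise_sd),
                    N_EDGES, n)
    low_idx <- which(lower.tri(matrix(0, N_REGIONS, N_REGIONS)))
    low <- matrix(0, N_REGIONS, N_REGIONS)
    for (s in seq_len(n)) {
      v <- base_edges + slope * z[s] + noise[, s]
      v <- pmin(pmax(v, config$fa_bounds[1L]), config$fa_bounds[2L])
      low[low_idx] <- v
      conn[, , s] <- low + t(low)
    }
    ids <- sprintf("%s%04d", id_prefix, seq_len(n))
    cohort(ids, conn, scores, provenance = "synthetic", validate = FALSE)
  })
}

#' Generate a source-domain cohort for unsupervised pre-training
#'
#' Emulates a pool of full-term neonatal connectomes used only for
#' unsupervised pre-training: connectomes have a shifted baseline relative to
#' the target generator (a distribution-level domain gap) and their scores
#' are flagged unused.
#'
#' @param n Number of source subjects (the reference pool size is 257).
#' @param seed Integer seed.
#' @return A `conn_cohort` with attribute `scores_used = FALSE`.
#' @export
generate_source_cohort <- function(n = 257L, seed = 1L) {
  if (n < 1L) stop("generator config error: n must be >= 1")
  base <- matrix(0.45, N_REGIONS, N_REGIONS)  # shifted vs target 0.4
  diag(base) <- 0
  cfg <- generator_config(n = n, baseline_matrix = base,
                          edge_noise_sd = 0.03, seed = seed)
  out <- generate_cohort(cfg, id_prefix = "src")
  attr(out, "scores_used") <- FALSE
  out
}
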