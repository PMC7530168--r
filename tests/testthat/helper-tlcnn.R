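# shared fixtures, all generated in code

random_connectome <- function(seed = 1, lo = 0, hi = 0.9) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(90 * 90, lo, hi), 90, 90)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}

# small cohort with scores covering all five augmentation bins
tiny_cohort <- function(n = 12, seed = 3) {
  scores <- rep(c(65, 75, 85, 95, 105, 120), length.out = n)
  withr::with_seed(seed, {
    conn <- array(0, dim = c(90, 90, n))
    for (s in seq_len(n)) conn[, , s] <- random_connectome(seed * 100 + s)
    cohort(sprintf("t%03d", seq_len(n)), conn, scores, provenance = "real",
           validate = FALSE)
  })
}

# O(n^2) pairwise AUC oracle: ties counted 1/2
auc_pairwise <- function(p, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  tot / (length(pos) * length(neg))
}

expect_valid_connectome <- function(m) {
  expect_true(is.matrix(m) && all(dim(m) == 90))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_identical(unname(diag(m)), rep(0, 90))
  expect_true(all(m >= 0 & m <= 1))
}
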