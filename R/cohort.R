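#' Construct a cohort of subjects
#'
#' A cohort bundles an ordered set of subjects: ids, 90x90 connectomes,
#' cognitive scores on the 40--160 scale and the derived high/low risk label
#' (high iff score < 90). All subjects share one atlas.
#'
#' @param ids Character vector of unique subject ids.
#' @param connectomes 90 x 90 x n array (or list of 90x90 matrices) of
#'   validated connectome matrices.
#' @param scores Numeric vector of cognitive scores in \[40, 160\].
#' @param atlas Shared `conn_atlas`.
#' @param provenance One of `"real"`, `"synthetic"`, `"augmented"`.
#' @param contributors Optional list (one element per subject) of the ids of
#'   the real subjects a synthetic sample was combined from; `NULL` entries
#'   mark original subjects. Used by the cross-validation leakage audit.
#' @param validate Validate every connectome (set `FALSE` only for matrices
#'   already validated; generation-scale code paths do this).
#' @param tokens Session-unique per-subject tokens (internal; used to memoize
#'   frozen-backbone features safely across cohorts). Fresh tokens are
#'   assigned when `NULL`.
#' @return Object of class `conn_cohort`.
#' @export
cohort <- function(ids, connectomes, scores, atlas = load_atlas(),
                   provenance = c("real", "synthetic", "augmented"),
                   contributors = NULL, validate = TRUE, tokens = NULL) {
  provenance <- match.arg(provenance)
  if (is.list(connectomes))
    connectomes <- array(unlist(connectomes),
                         dim = c(N_REGIONS, N_REGIONS, length(connectomes)))
  n <- length(ids)
  stopifnot(is.character(ids), dim(connectomes)[3L] == n,
            length(scores) == n)
  if (anyDuplicated(ids))
    stop("cohort error: duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (validate)
    for (s in seq_len(n))
      connectomes[, , s] <- validate_connectome(connectomes[, , s])
  risk <- assign_risk_label(scores)
  if (!is.null(contributors)) stopifnot(length(contributors) == n)
  if (is.null(tokens)) tokens <- paste0(next_cohort_uid(), ":", ids)
  stopifnot(length(tokens) == n)
  structure(list(ids = ids, conn = connectomes, scores = scores,
                 risk = risk, atlas = atlas, provenance = provenance,
                 contributors = contributors, tokens = tokens),
            class = "conn_cohort")
}

# session-unique cohort counter for feature-cache tokens
.tlcnn_state <- new.env(parent = emptyenv())
next_cohort_uid <- function() {
  n <- (.tlcnn_state$uid %||% 0L) + 1L
  .tlcnn_state$uid <- n
  sprintf("c%06d", n)
}

#' @export
length.conn_cohort <- function(x) length(x$ids)

#' Subset a cohort by subject position or id
#' @param x A `conn_cohort`.
#' @param i Integer/logical positions or character ids.
#' @param ... Unused.
#' @export
`[.conn_cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  cohort(x$ids[i], x$conn[, , i, drop = FALSE], x$scores[i],
         atlas = x$atlas, provenance = x$provenance,
         contributors = if (!is.null(x$contributors)) x$contributors[i],
         validate = FALSE, tokens = x$tokens[i])
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat(sprintf("connectome cohort: %d subjects (%s)\n", length(x), x$provenance))
  cat(sprintf("  scores: mean %.1f, sd %.1f, range [%.1f, %.1f]\n",
              mean(x$scores), stats::sd(x$scores), min(x$scores),
              max(x$scores)))
  cat(sprintf("  risk: %d high (<90), %d low\n",
              sum(x$risk == "high"), sum(x$risk == "low")))
  invisible(x)
}

#' Edge-vector design matrix of a cohort
#'
#' Stacks [vectorize_edges()] of every subject into an n x 4005 matrix, the
#' input form used by the vector-input baseline models.
#'
#' @param x A `conn_cohort`.
#' @return Numeric matrix, one row per subject, ids as rownames.
#' @export
edge_matrix <- function(x) {
  stopifnot(inherits(x, "conn_cohort"))
  out <- t(apply(x$conn, 3L, function(m) {
    tm <- t(m); tm[lower.tri(tm)]
  }))
  rownames(out) <- x$ids
  out
}

#' Write a cohort to a manifest plus per-subject connectome CSVs
#'
#' The manifest is a TSV with columns `subject_id`, `connectome_path`,
#' `score`; matrices are written with [write_connectome()] into `dir`.
#'
#' @param x A `conn_cohort`.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest TSV, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "conn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(x$ids, ".csv"))
  for (s in seq_along(x$ids))
    write_connectome(x$conn[, , s], paths[s], atlas = x$atlas)
  manifest <- data.frame(subject_id = x$ids,
                         connectome_path = basename(paths),
                         score = x$scores)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort from a manifest TSV
#'
#' @param path Manifest TSV with columns `subject_id`, `connectome_path`,
#'   `score`; relative connectome paths are resolved against the manifest's
#'   directory.
#' @param atlas Shared `conn_atlas`.
#' @param provenance Provenance tag for the loaded cohort.
#' @return A `conn_cohort`.
#' @export
read_cohort <- function(path, atlas = load_atlas(), provenance = "real") {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "connectome_path", "score")
  if (!all(required %in% names(man)))
    stop("manifest error: need columns ", paste(required, collapse = ", "))
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", man$connectome_path),
                  man$connectome_path,
                  file.path(base, man$connectome_path))
  conn <- array(0, dim = c(N_REGIONS, N_REGIONS, nrow(man)))
  for (s in seq_len(nrow(man)))
    conn[, , s] <- read_connectome(files[s], atlas = atlas)
  cohort(as.character(man$subject_id), conn, man$score, atlas = atlas,
         provenance = provenance, validate = FALSE)
}

# bind two cohorts (same atlas); used by the oversampler
bind_cohorts <- function(a, b, provenance = a$provenance) {
  contr <- c(if (is.null(a$contributors)) vector("list", length(a))
             else a$contributors,
             if (is.null(b$contributors)) vector("list", length(b))
             else b$contributors)
  cohort(c(a$ids, b$ids),
         array(c(a$conn, b$conn),
               dim = c(N_REGIONS, N_REGIONS, length(a) + length(b))),
         c(a$scores, b$scores), atlas = a$atlas, provenance = provenance,
         contributors = contr, validate = FALSE,
         tokens = c(a$tokens, b$tokens))
}
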