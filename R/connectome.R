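#' @useDynLib tlcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

N_REGIONS <- 90L
N_EDGES <- 90L * 89L / 2L  # upper-triangle edge count

#' Validate a connectome adjacency matrix
#'
#' A valid connectome is a 90x90 numeric matrix of mean-FA edge weights:
#' symmetric to within `tol`, zero on the diagonal and with every entry in
#' \[0, 1\]. Asymmetries within `tol` (floating-point round-trip noise) are
#' absorbed by averaging with the transpose; larger asymmetries are errors.
#'
#' @param m Numeric 90x90 matrix.
#' @param tol Symmetry tolerance (absolute). Default `1e-9`.
#' @return The validated (symmetrized, zero-diagonal) matrix, invisibly
#'   usable as a `Connectome`.
#' @export
validate_connectome <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("connectome format error: not a numeric matrix")
  if (!all(dim(m) == N_REGIONS))
    stop("connectome format error: expected 90x90, got ",
         paste(dim(m), collapse = "x"))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("connectome format error: non-numeric cell at [",
         bad[1L], ",", bad[2L], "]")
  }
  asym <- abs(m - t(m))
  if (any(asym > tol)) {
    bad <- which(asym > tol, arr.ind = TRUE)[1L, ]
    stop("connectome symmetry error: |M - t(M)| = ",
         format(asym[bad[1L], bad[2L]]), " at [", bad[1L], ",", bad[2L], "]")
  }
  if (any(m < 0 | m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    stop("connectome range error: entry ", format(m[bad[1L], bad[2L]]),
         " outside [0,1] at [", bad[1L], ",", bad[2L], "]")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Read a connectome matrix from CSV
#'
#' Accepts a plain 90x90 numeric table, optionally carrying a header row
#' and/or a first column of region abbreviations (as written by
#' [write_connectome()]).
#'
#' @param path CSV file path.
#' @param atlas A `conn_atlas` (used to recognise abbreviation headers).
#' @return A validated 90x90 connectome matrix with region abbreviations as
#'   dimnames.
#' @export
read_connectome <- function(path, atlas = load_atlas()) {
  if (!file.exists(path)) stop("connectome format error: no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.csv(path, header = has_header, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) == N_REGIONS + 1L &&
      !is.numeric(tab[[1L]])) {
    tab <- tab[, -1L, drop = FALSE]
  }
  if (ncol(tab) != N_REGIONS || nrow(tab) != N_REGIONS)
    stop("connectome format error: expected 90x90 table, got ",
         nrow(tab), "x", ncol(tab))
  non_num <- !vapply(tab, is.numeric, logical(1L))
  if (any(non_num)) {
    j <- which(non_num)[1L]
    i <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
    stop("connectome format error: non-numeric cell at [", i, ",", j, "]")
  }
  m <- as.matrix(tab)
  dimnames(m) <- list(atlas$regions$abbreviation, atlas$regions$abbreviation)
  validate_connectome(m)
}

#' Write a connectome matrix to CSV
#'
#' Always emits a header row and a first column of region abbreviations, so
#' files are self-describing. `read_connectome(write_connectome(m, f))`
#' round-trips bit-identically.
#'
#' @param m Validated 90x90 connectome matrix.
#' @param path Output CSV path.
#' @param atlas A `conn_atlas` supplying abbreviations.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(m, path, atlas = load_atlas()) {
  m <- validate_connectome(m)
  ab <- atlas$regions$abbreviation
  # 17 significant digits so the read-back is bit-identical
  cells <- matrix(formatC(m, format = "g", digits = 17), N_REGIONS)
  lines <- c(paste(c("region", ab), collapse = ","),
             vapply(seq_len(N_REGIONS), function(i)
               paste(c(ab[i], cells[i, ]), collapse = ","), character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Vectorize a connectome to its 4005 upper-triangle edges
#'
#' Edge order is the fixed package convention: upper triangle, row-major,
#' i < j — i.e. (1,2), (1,3), ..., (1,90), (2,3), ..., (89,90). Position 1 of
#' the returned vector is edge (1,2).
#'
#' @param m Validated 90x90 connectome matrix.
#' @return Numeric vector of length 4005.
#' @seealso [devectorize_edges()], [edge_index()]
#' @export
vectorize_edges <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == N_REGIONS))
    stop("connectome format error: expected 90x90 matrix")
  tm <- t(m)
  tm[lower.tri(tm)]  # column-major lower tri of t(m) == row-major upper tri
}

#' Rebuild a connectome matrix from its edge vector
#'
#' Inverse of [vectorize_edges()]; the round-trip is exact.
#'
#' @param v Numeric vector of length 4005 in the package edge order.
#' @return Symmetric 90x90 matrix with zero diagonal.
#' @export
devectorize_edges <- function(v) {
  if (length(v) != N_EDGES)
    stop("edge vector error: expected length ", N_EDGES, ", got ", length(v))
  low <- matrix(0, N_REGIONS, N_REGIONS)
  low[lower.tri(low)] <- v
  low + t(low)
}

#' Row-major upper-triangle position of an edge
#'
#' @param i,j Region indices (any order, `i != j`).
#' @return Integer position in the length-4005 edge vector.
#' @export
edge_index <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("edge index error: diagonal is not an edge")
  if (any(lo < 1L | hi > N_REGIONS)) stop("edge index error: out of 1..90")
  as.integer((lo - 1L) * N_REGIONS - lo * (lo - 1L) / 2 + (hi - lo))
}

#' High/low risk label from a cognitive score
#'
#' Scores below 90 define the high-risk group; 90 and above, low-risk. Scores
#' live on the standardized 40--160 scale (population mean 100, SD 15).
#'
#' @param score Numeric vector of cognitive scores in \[40, 160\].
#' @return Factor with levels `c("low", "high")`.
#' @export
assign_risk_label <- function(score) {
  if (any(score < 40 | score > 160))
    stop("score domain error: scores must lie in [40, 160]")
  factor(ifelse(score < 90, "high", "low"), levels = c("low", "high"))
}
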