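#' Load a 90-region brain parcellation atlas
#'
#' Loads the region table that names the nodes of every connectome handled by
#' this package. The builtin token `"neonatal-aal-90"` loads the packaged
#' reconstruction of the 90-region neonatal AAL parcellation: region ordering
#' follows the published lobe index ranges (frontal 1--28 and 69--70,
#' occipital 43--54, central structures 55--60, parietal 61--68, temporal
#' 37--42 and 71--90); indices 29--36 are not assigned a lobe by that listing
#' and carry the tag `"unlisted"`. Left/right homologues occupy odd/even
#' indices (e.g. `HIP-L` = 37, `HIP-R` = 38).
#'
#' A custom atlas file must be a TSV with columns `index`, `name`,
#' `abbreviation`, `lobe` (comment lines starting with `#` are ignored).
#'
#' @param path Path to an atlas TSV, or the builtin token `"neonatal-aal-90"`.
#' @return An object of class `conn_atlas`: a list with element `regions`
#'   (data frame with columns `index`, `name`, `abbreviation`, `lobe`).
#' @examples
#' atlas <- load_atlas()
#' lobe_of(atlas, 43)   # "occipital"
#' @export
load_atlas <- function(path = "neonatal-aal-90") {
  if (identical(path, "neonatal-aal-90")) {
    path <- system.file("extdata", "neonatal_aal90_reconstructed.tsv",
                        package = "tlcnn", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("atlas error: file not found: ", path)
  regions <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
  required <- c("index", "name", "abbreviation", "lobe")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0L)
    stop("atlas error: missing columns: ", paste(missing, collapse = ", "))
  regions <- regions[order(regions$index), required]
  if (nrow(regions) != 90L)
    stop("atlas error: expected 90 regions, found ", nrow(regions))
  if (!identical(as.integer(regions$index), 1:90))
    stop("atlas error: region indices must be exactly 1..90")
  if (anyDuplicated(regions$abbreviation))
    stop("atlas error: duplicate abbreviations: ",
         paste(unique(regions$abbreviation[duplicated(regions$abbreviation)]),
               collapse = ", "))
  allowed <- c("frontal", "occipital", "parietal", "central", "temporal",
               "unlisted")
  bad <- setdiff(unique(regions$lobe), allowed)
  if (length(bad) > 0L)
    stop("atlas error: unknown lobe labels: ", paste(bad, collapse = ", "))
  structure(list(regions = regions), class = "conn_atlas")
}

#' Lobe label of an atlas region
#'
#' @param atlas A `conn_atlas` object.
#' @param index Region index or vector of indices in 1..90.
#' @return Character vector of lobe labels.
#' @export
lobe_of <- function(atlas, index) {
  stopifnot(inherits(atlas, "conn_atlas"))
  if (any(index < 1L | index > 90L)) stop("atlas error: index out of 1..90")
  atlas$regions$lobe[index]
}

#' @export
print.conn_atlas <- function(x, ...) {
  cat("90-region connectome atlas\n")
  tab <- table(x$regions$lobe)
  cat("  lobes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# abbreviation -> index lookup; errors on unknown abbreviations
atlas_index <- function(atlas, abbrev) {
  i <- match(abbrev, atlas$regions$abbreviation)
  if (anyNA(i)) stop("atlas error: unknown abbreviation: ",
                     paste(abbrev[is.na(i)], collapse = ", "))
  i
}
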