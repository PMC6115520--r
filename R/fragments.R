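#' Read a fragment definition table
#'
#' Fragments are GC-MS ions of (derivatized) amino acids. Each row gives the
#' skeleton carbon positions the ion retains and the elemental formula of
#' everything else in the ion (derivatization groups, backbone heteroatoms)
#' used for natural-abundance correction. Skeleton carbons are excluded from
#' the formula because they carry the biological label.
#'
#' @param path TSV with columns \code{fragment}, \code{amino_acid},
#'   \code{carbon_set} (e.g. "1-5" or "2,3"), \code{formula}.
#' @return data.frame of fragment specs.
#' @export
read_fragments <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("fragment", "amino_acid", "carbon_set", "formula")
  if (!all(need %in% names(tab))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$fragment)) {
    stop("duplicate fragment name: ", tab$fragment[duplicated(tab$fragment)][1])
  }
  tab
}

#' Parse a carbon-set string
#'
#' @param s String like \code{"1-5"}, \code{"2-5"} or \code{"1,2"}.
#' @return Sorted integer vector of carbon positions.
#' @export
parse_carbon_set <- function(s) {
  parts <- strsplit(s, ",")[[1]]
  idx <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
  if (any(is.na(idx)) || any(idx < 1)) stop("bad carbon set: ", s)
  sort(unique(idx))
}

#' Packaged fragment table for the C. thermocellum analysis
#' @return data.frame of fragment specs.
#' @export
ct_fragments <- function() {
  read_fragments(system.file("extdata", "ct_fragments.tsv", package = "emuflux"))
}
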