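#' Natural isotope abundance table
#'
#' Returns the packaged table of natural isotope abundances used to build
#' natural-abundance correction matrices. Values are IUPAC representative
#' terrestrial abundances; the table is shipped as package data
#' (\code{inst/extdata/isotope_abundances.tsv}) so that corrections are
#' reproducible bit-for-bit across versions.
#'
#' @return A named list; each element is a numeric vector of abundances by
#'   mass shift (+0, +1, +2, ...) for one element, summing to 1.
#' @export
isotope_abundances <- function() {
  path <- system.file("extdata", "isotope_abundances.tsv", package = "emuflux")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  split_ab <- split(tab, tab$element)
  lapply(split_ab, function(d) {
    d <- d[order(d$mass_shift), ]
    stopifnot(identical(d$mass_shift, seq_len(nrow(d)) - 1L))
    d$abundance
  })
}

#' Parse an elemental formula string
#'
#' @param formula A formula such as \code{"C8H26NO2Si2"}. Element symbols are
#'   one capital letter optionally followed by a lowercase letter; counts
#'   default to 1.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || formula == "" || formula == "-") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  syms <- sub("[0-9]*$", "", parts)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Z][a-z]?", "", parts), "1"))
  out <- tapply(cnts, syms, sum)
  stats::setNames(as.integer(out), names(out))
}

# Mass-shift distribution of a set of atoms: convolution of per-element
# isotope distributions, truncated to `window` shifts.
formula_shift_distribution <- function(counts, window, abundances = isotope_abundances()) {
  dist <- c(1, rep(0, window))
  for (el in names(counts)) {
    if (!el %in% names(abundances)) {
      stop("unknown element symbol: ", el)
    }
    a <- abundances[[el]]
    for (i in seq_len(counts[[el]])) {
      dist <- convolve_truncate(dist, a, window)
    }
  }
  dist
}

# Truncated discrete convolution keeping shifts 0..window.
convolve_truncate <- function(x, y, window) {
  n <- window + 1L
  out <- numeric(n)
  for (j in seq_along(y)) {
    if (j > n) break
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + x[idx] * y[j]
  }
  out
}

#' Normalize raw fragment intensities to an MDV
#'
#' Converts a vector of GC-MS intensities over masses M+0..M+k into the
#' mass isotopomer distribution vector (fractional abundances with unit sum).
#'
#' @param intensities Numeric vector of non-negative intensities.
#' @return Numeric MDV summing to 1.
#' @export
normalize_intensities <- function(intensities) {
  if (any(!is.finite(intensities))) stop("non-finite intensity")
  if (any(intensities < 0)) stop("negative intensity")
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero intensity vector")
  intensities / tot
}

#' Build a natural-abundance correction matrix
#'
#' The matrix maps the true skeleton MDV (biological labeling only) to the
#' observed MDV, accounting for naturally occurring heavy isotopes of the
#' atoms that are not skeleton carbons (derivatization groups, backbone
#' heteroatoms). Column j is the mass-shift distribution of the non-skeleton
#' atoms shifted down by j, so the matrix is lower triangular with columns
#' summing to at most 1 (mass that convolves beyond the window is lost).
#' Correction of observed data uses the inverse (see
#' \code{\link{correct_mdv}}).
#'
#' @param formula Elemental formula of the fragment excluding skeleton
#'   carbons (string or named count vector), e.g. \code{"C8H26NO2Si2"}.
#' @param n Number of skeleton carbons in the fragment.
#' @param window Mass window k (matrix spans shifts 0..k); default
#'   \code{n + 4}.
#' @param elements Elements to correct for. Default \code{c("C","H","O")}
#'   corrects carbon, hydrogen and oxygen only; set to \code{NULL} to correct
#'   every element in the formula (including N, Si, S from TBDMS
#'   derivatization).
#' @return A \code{correction_matrix} object (matrix with attributes).
#' @export
build_correction_matrix <- function(formula, n, window = n + 4L,
                                    elements = c("C", "H", "O")) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (any(counts < 0)) stop("negative element count")
  if (!is.null(elements)) counts <- counts[names(counts) %in% elements]
  dist <- formula_shift_distribution(counts, window)
  k <- window + 1L
  C <- matrix(0, k, k)
  for (j in seq_len(k)) {
    len <- k - j + 1L
    C[j:(j + len - 1L), j] <- dist[seq_len(len)]
  }
  # truncation mass loss guard
  if (1 - sum(dist) > 1e-3) {
    warning("correction window truncates ", format(1 - sum(dist)),
            " of the natural-abundance mass distribution")
  }
  structure(C, class = c("correction_matrix", "matrix"),
            n_skeleton = as.integer(n), formula = counts)
}

#' Apply natural-abundance correction to an observed MDV
#'
#' Computes C^-1 * observed, truncates to the skeleton carbon count, clamps
#' small negative entries to zero and renormalizes to unit sum. Negative mass
#' beyond \code{tol} indicates a data-quality problem and triggers a warning
#' (the correction still proceeds).
#'
#' @param observed Observed MDV (length must equal the matrix dimension).
#' @param C A \code{correction_matrix}.
#' @param tol Clamping tolerance for negative corrected abundances.
#' @return Corrected MDV of length n_skeleton + 1.
#' @export
correct_mdv <- function(observed, C, tol = 1e-6) {
  k <- nrow(C)
  if (length(observed) != k) {
    stop("observed MDV has length ", length(observed),
         " but correction matrix has dimension ", k)
  }
  x <- solve(C, observed)
  n <- attr(C, "n_skeleton")
  x <- x[seq_len(n + 1L)]
  neg <- x < 0
  if (any(x[neg] < -tol)) {
    warning("corrected MDV has negative mass ", format(min(x)),
            " beyond tolerance; check fragment formula / data quality")
  }
  x[neg] <- 0
  x / sum(x)
}

#' Forward-convolve a true skeleton MDV with natural abundance
#'
#' The forward direction of the correction: returns C * true_mdv, i.e. the
#' MDV that would be observed for a fragment whose skeleton carries
#' \code{true_mdv} and whose remaining atoms have natural isotope
#' composition. \code{\link{correct_mdv}} inverts this operation.
#'
#' @inheritParams build_correction_matrix
#' @param true_mdv Skeleton MDV of length n + 1.
#' @return Observed-style MDV of length window + 1.
#' @export
convolve_natural_abundance <- function(true_mdv, formula, n = length(true_mdv) - 1L,
                                       window = n + 4L,
                                       elements = c("C", "H", "O")) {
  C <- build_correction_matrix(formula, n, window, elements)
  padded <- c(true_mdv, rep(0, nrow(C) - length(true_mdv)))
  as.numeric(C %*% padded)
}

#' Fractional labeling of a fragment
#'
#' The mean fraction of labeled carbon positions:
#' FL = sum(i * m_i) / (n * sum(m_i)) for an MDV m over n skeleton carbons.
#'
#' @param mdv MDV of length n + 1.
#' @param n Skeleton carbon count; defaults to \code{length(mdv) - 1}.
#' @return Fractional labeling in [0, 1].
#' @export
fractional_labeling <- function(mdv, n = length(mdv) - 1L) {
  if (n < 1) stop("fragment must contain at least one skeleton carbon")
  if (length(mdv) != n + 1L) stop("MDV length must be n + 1")
  sum(seq(0, n) * mdv) / (n * sum(mdv))
}

#' Validate an MDV
#'
#' @param mdv Numeric vector.
#' @param tol Tolerance on the unit-sum constraint and on negative entries.
#' @return Invisibly, the MDV; errors if invalid.
#' @export
validate_mdv <- function(mdv, tol = 1e-9) {
  if (any(!is.finite(mdv))) stop("non-finite MDV entry")
  if (any(mdv < -1e-10)) stop("negative MDV entry beyond tolerance")
  if (abs(sum(mdv) - 1) > tol) stop("MDV does not sum to 1")
  invisible(mdv)
}
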