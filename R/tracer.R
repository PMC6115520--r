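#' Define a tracer specification
#'
#' A tracer gives, for each fed (source) metabolite, the mixture of
#' positional isotopomers in the medium, e.g. 20% [U-13C6] glucose + 80%
#' unlabeled glucose. Patterns are 0/1 strings over the metabolite's carbon
#' positions (1 = 13C at that position by design).
#'
#' @param substrates Named list; each element a data.frame with columns
#'   \code{pattern} (character) and \code{fraction} (numeric, summing to 1).
#' @param natural_13c If TRUE, carbon positions marked 0 carry natural 13C
#'   abundance (1.07\%) instead of being idealized pure 12C.
#' @return A \code{tracer_spec} object.
#' @export
make_tracer <- function(substrates, natural_13c = FALSE) {
  for (met in names(substrates)) {
    d <- substrates[[met]]
    if (!all(c("pattern", "fraction") %in% names(d))) {
      stop("tracer entry for ", met, " needs columns pattern, fraction")
    }
    if (abs(sum(d$fraction) - 1) > 1e-12) {
      stop("tracer fractions for ", met, " must sum to 1")
    }
    if (length(unique(nchar(d$pattern))) != 1) {
      stop("tracer patterns for ", met, " have inconsistent lengths")
    }
    if (any(!grepl("^[01]*$", d$pattern))) {
      stop("tracer patterns must be 0/1 strings")
    }
  }
  structure(list(substrates = substrates, natural_13c = natural_13c),
            class = "tracer_spec")
}

#' Read a tracer specification from a YAML file
#'
#' Expected structure:
#' \preformatted{
#' natural_13c: false
#' substrates:
#'   GLCX:
#'     - {pattern: "111111", fraction: 0.2}
#'     - {pattern: "000000", fraction: 0.8}
#' }
#' @param path YAML file path.
#' @return A \code{tracer_spec}.
#' @export
read_tracer <- function(path) {
  y <- yaml::read_yaml(path)
  subs <- lapply(y$substrates, function(lst) {
    data.frame(pattern = vapply(lst, function(e) as.character(e$pattern), ""),
               fraction = vapply(lst, function(e) as.numeric(e$fraction), 0))
  })
  make_tracer(subs, natural_13c = isTRUE(y$natural_13c))
}

#' Write a tracer specification to YAML
#' @param tracer A \code{tracer_spec}.
#' @param path Output path.
#' @export
write_tracer <- function(tracer, path) {
  y <- list(natural_13c = tracer$natural_13c,
            substrates = lapply(tracer$substrates, function(d) {
              lapply(seq_len(nrow(d)), function(i) {
                list(pattern = d$pattern[i], fraction = d$fraction[i])
              })
            }))
  yaml::write_yaml(y, path)
}

#' MDV of an input (source metabolite) EMU under a tracer
#'
#' Marginalizes the tracer's positional isotopomer mixture over the given
#' atom subset. With \code{natural_13c} on, positions designed unlabeled are
#' 13C with natural abundance.
#'
#' @param tracer A \code{tracer_spec}.
#' @param met Source metabolite id (must have a tracer entry).
#' @param atoms Integer vector of 1-based carbon positions.
#' @return MDV of length \code{length(atoms) + 1}.
#' @export
input_emu_mdv <- function(tracer, met, atoms) {
  d <- tracer$substrates[[met]]
  if (is.null(d)) stop("no tracer entry for source metabolite ", met)
  p13 <- if (tracer$natural_13c) 0.0107 else 0
  k <- length(atoms)
  mdv <- numeric(k + 1)
  for (i in seq_len(nrow(d))) {
    bits <- as.integer(strsplit(d$pattern[i], "")[[1]])[atoms]
    lab <- sum(bits)
    unl <- k - lab
    # designed labels give a fixed shift; unlabeled positions add binomial 13C
    binom <- stats::dbinom(0:unl, unl, p13)
    mdv[lab + seq_len(unl + 1)] <- mdv[lab + seq_len(unl + 1)] +
      d$fraction[i] * binom
  }
  mdv
}

# full positional isotopomer distribution (length 2^n) of a source
# metabolite under the tracer; bit i-1 of the state is carbon position i
input_isotopomer_dist <- function(tracer, met, n) {
  d <- tracer$substrates[[met]]
  if (is.null(d)) stop("no tracer entry for source metabolite ", met)
  p13 <- if (tracer$natural_13c) 0.0107 else 0
  dist <- numeric(2^n)
  for (i in seq_len(nrow(d))) {
    bits <- as.integer(strsplit(d$pattern[i], "")[[1]])
    for (s in 0:(2^n - 1)) {
      p <- d$fraction[i]
      for (pos in seq_len(n)) {
        on <- bitwAnd(s, bitwShiftL(1L, pos - 1L)) > 0
        p <- p * if (bits[pos] == 1) {
          if (on) 1 else 0
        } else {
          if (on) p13 else 1 - p13
        }
        if (p == 0) break
      }
      dist[s + 1] <- dist[s + 1] + p
    }
  }
  dist
}
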