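#' Read a metabolite table
#'
#' @param path TSV file with columns \code{id}, \code{n_carbons}, \code{role}
#'   (one of \code{balanced}, \code{source}, \code{sink}).
#' @return data.frame of metabolites.
#' @export
read_metabolites <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_metabolites(tab)
}

validate_metabolites <- function(tab) {
  need <- c("id", "n_carbons", "role")
  if (!all(need %in% names(tab))) {
    stop("metabolite table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate metabolite id: ", tab$id[duplicated(tab$id)][1])
  }
  if (any(tab$n_carbons < 0)) stop("n_carbons must be >= 0")
  bad <- setdiff(tab$role, c("balanced", "source", "sink"))
  if (length(bad)) stop("unknown metabolite role: ", bad[1])
  tab
}

# Parse one side of a reaction line into a list of entries
# (met, coef, atoms or NA).
parse_side <- function(side, rid) {
  entries <- strsplit(side, "\\s*\\+\\s*")[[1]]
  entries <- entries[nzchar(trimws(entries))]
  lapply(entries, function(e) {
    e <- trimws(e)
    m <- regmatches(e, regexec(
      "^([0-9]*\\.?[0-9]+\\s+)?([A-Za-z][A-Za-z0-9_]*)\\s*(\\(([a-z]*)\\))?$", e))[[1]]
    if (length(m) == 0) {
      stop("reaction ", rid, ": cannot parse entry '", e, "'")
    }
    coef <- if (nzchar(trimws(m[2]))) as.numeric(m[2]) else 1
    atoms <- if (nzchar(m[4])) m[5] else NA_character_
    list(met = m[3], coef = coef, atoms = atoms)
  })
}

#' Parse an atom-mapped reaction network
#'
#' Reads a reaction-list document: one reaction per line in the form
#' \code{ID: coeff MET (atoms) + ... -> coeff MET (atoms) + ...}
#' with \code{<->} marking reversible reactions and \code{#} comments.
#' Atom maps are lowercase letter strings, one letter per carbon, local to
#' the reaction (13CFLUX-style). A reaction written entirely without atom
#' maps is a plain stoichiometric drain (used for the biomass equation);
#' such reactions do not participate in label propagation.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param metabolites Metabolite table (see \code{\link{read_metabolites}}).
#' @return A \code{flux_network} object.
#' @export
parse_network <- function(text, metabolites) {
  metabolites <- validate_metabolites(metabolites)
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]

  nc <- stats::setNames(metabolites$n_carbons, metabolites$id)
  role <- stats::setNames(metabolites$role, metabolites$id)

  reactions <- lapply(text, function(line) {
    m <- regmatches(line, regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 0) stop("cannot parse reaction line: '", line, "'")
    rid <- m[2]
    body <- m[3]
    rev <- grepl("<->", body, fixed = TRUE)
    sides <- strsplit(body, "<->|->")[[1]]
    if (length(sides) != 2) stop("reaction ", rid, ": expected one arrow")
    reactants <- parse_side(sides[1], rid)
    products <- parse_side(sides[2], rid)

    for (e in c(reactants, products)) {
      if (!e$met %in% names(nc)) {
        stop("reaction ", rid, ": unknown metabolite reference '", e$met, "'")
      }
    }
    has_map <- vapply(c(reactants, products), function(e) !is.na(e$atoms), logical(1))
    mapped <- all(has_map)
    if (!mapped && any(has_map)) {
      stop("reaction ", rid, ": atom maps must be given for all metabolites or none")
    }
    if (mapped) {
      for (e in c(reactants, products)) {
        if (nchar(e$atoms) != nc[[e$met]]) {
          stop("reaction ", rid, ": atom map '", e$atoms, "' for ", e$met,
               " has length ", nchar(e$atoms), " but metabolite has ",
               nc[[e$met]], " carbons")
        }
        if (e$coef != 1 && nc[[e$met]] > 0) {
          stop("reaction ", rid, ": atom-mapped metabolite ", e$met,
               " must have coefficient 1 (repeat the metabolite instead)")
        }
      }
      ratoms <- unlist(strsplit(vapply(reactants, `[[`, "", "atoms"), ""))
      patoms <- unlist(strsplit(vapply(products, `[[`, "", "atoms"), ""))
      if (anyDuplicated(ratoms)) {
        stop("reaction ", rid, ": duplicate atom letter on reactant side")
      }
      if (anyDuplicated(patoms)) {
        stop("reaction ", rid, ": duplicate atom letter on product side")
      }
      if (!identical(sort(ratoms), sort(patoms))) {
        stop("reaction ", rid, ": carbon imbalance (reactant atoms {",
             paste(sort(ratoms), collapse = ""), "} vs product atoms {",
             paste(sort(patoms), collapse = ""), "})")
      }
    }
    list(id = rid, reactants = reactants, products = products,
         reversible = rev, mapped = mapped)
  })

  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  }
  names(reactions) <- ids

  net <- structure(list(metabolites = metabolites, reactions = reactions),
                   class = "flux_network")
  check_balanced_connectivity(net)
  net
}

# every balanced metabolite must be producible and consumable
check_balanced_connectivity <- function(net) {
  role <- stats::setNames(net$metabolites$role, net$metabolites$id)
  prod <- cons <- character(0)
  for (r in net$reactions) {
    rmets <- vapply(r$reactants, `[[`, "", "met")
    pmets <- vapply(r$products, `[[`, "", "met")
    cons <- c(cons, rmets)
    prod <- c(prod, pmets)
    if (r$reversible) {
      cons <- c(cons, pmets)
      prod <- c(prod, rmets)
    }
  }
  bal <- net$metabolites$id[net$metabolites$role == "balanced"]
  miss_p <- setdiff(bal, prod)
  miss_c <- setdiff(bal, cons)
  if (length(miss_p)) stop("balanced metabolite never produced: ", miss_p[1])
  if (length(miss_c)) stop("balanced metabolite never consumed: ", miss_c[1])
  invisible(net)
}

#' Read a network from files
#'
#' @param network_path Reaction-list text file.
#' @param metabolite_path Metabolite table TSV.
#' @return A \code{flux_network}.
#' @export
read_network <- function(network_path, metabolite_path) {
  parse_network(readLines(network_path), read_metabolites(metabolite_path))
}

#' @export
print.flux_network <- function(x, ...) {
  nb <- sum(x$metabolites$role == "balanced")
  cat("<flux_network> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (", nb, " balanced)\n", sep = "")
  invisible(x)
}

#' Serialize a network back to reaction-list text
#'
#' @param net A \code{flux_network}.
#' @return Character vector of reaction lines.
#' @export
serialize_network <- function(net) {
  fmt_side <- function(side) {
    paste(vapply(side, function(e) {
      coef <- if (e$coef != 1) paste0(format(e$coef), " ") else ""
      atoms <- if (!is.na(e$atoms)) paste0(" (", e$atoms, ")") else ""
      paste0(coef, e$met, atoms)
    }, ""), collapse = " + ")
  }
  vapply(net$reactions, function(r) {
    arrow <- if (r$reversible) "<->" else "->"
    paste0(r$id, ": ", fmt_side(r$reactants), " ", arrow, " ", fmt_side(r$products))
  }, "")
}

#' Stoichiometric balance matrix
#'
#' @param net A \code{flux_network}.
#' @return Matrix (balanced metabolites x reactions) of signed stoichiometric
#'   coefficients (products positive, reactants negative).
#' @export
stoichiometric_matrix <- function(net) {
  bal <- net$metabolites$id[net$metabolites$role == "balanced"]
  S <- matrix(0, length(bal), length(net$reactions),
              dimnames = list(bal, names(net$reactions)))
  for (r in net$reactions) {
    for (e in r$reactants) {
      if (e$met %in% bal) S[e$met, r$id] <- S[e$met, r$id] - e$coef
    }
    for (e in r$products) {
      if (e$met %in% bal) S[e$met, r$id] <- S[e$met, r$id] + e$coef
    }
  }
  S
}

#' Reaction reversibility flags
#' @param net A \code{flux_network}.
#' @return Named logical vector.
#' @export
reversibility <- function(net) {
  vapply(net$reactions, `[[`, logical(1), "reversible")
}

#' Free-flux parameterization of the steady-state space
#'
#' Computes an affine parameterization v(theta) = v0 + N theta of all net
#' flux vectors satisfying S v = 0 together with the fixed-value constraints.
#' The dimension of theta equals #reactions - rank(S augmented with the
#' fixed constraints). Exchange fluxes of reversible reactions are separate
#' non-negative parameters, handled by the callers.
#'
#' @param net A \code{flux_network}.
#' @param fixed Named numeric vector of reaction net-flux values to fix.
#' @param tol Rank / feasibility tolerance.
#' @return A \code{flux_basis} object with elements \code{v0} (particular
#'   solution), \code{N} (null-space basis, reactions x n_free),
#'   \code{n_free}, \code{reactions}, \code{irreversible}.
#' @export
free_flux_basis <- function(net, fixed = numeric(0), tol = 1e-9) {
  S <- stoichiometric_matrix(net)
  rxns <- colnames(S)
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    bad <- setdiff(names(fixed), rxns)
    if (length(bad)) stop("fixed value for unknown reaction: ", bad[1])
    E <- matrix(0, length(fixed), ncol(S), dimnames = list(names(fixed), rxns))
    for (r in names(fixed)) E[r, r] <- 1
    A <- rbind(S, E)
    b <- c(b, unname(fixed))
  }
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  d <- sv$d
  rank <- sum(d > tol * max(d, 1))
  # particular solution by pseudo-inverse
  dinv <- ifelse(seq_along(d) <= rank, 1 / d, 0)
  v0 <- sv$v[, seq_along(d), drop = FALSE] %*% (dinv * crossprod(sv$u[, seq_along(d), drop = FALSE], b))
  v0 <- as.numeric(v0)
  resid <- A %*% v0 - b
  if (max(abs(resid)) > 1e-6 * max(1, max(abs(b)))) {
    viol <- rownames(A)[abs(resid) > 1e-6 * max(1, max(abs(b)))]
    stop("fixed values admit no steady-state completion; violated balances: ",
         paste(viol, collapse = ", "))
  }
  n_free <- ncol(A) - rank
  N <- if (n_free > 0) sv$v[, rank + seq_len(n_free), drop = FALSE] else
    matrix(0, ncol(A), 0)
  rownames(N) <- rxns
  names(v0) <- rxns
  structure(list(v0 = v0, N = N, n_free = n_free, reactions = rxns,
                 irreversible = rxns[!reversibility(net)], fixed = fixed),
            class = "flux_basis")
}

#' Construct a flux vector from free parameters
#'
#' @param basis A \code{flux_basis}.
#' @param theta Numeric vector of length \code{basis$n_free}.
#' @param exchange Named non-negative exchange fluxes for reversible
#'   reactions (default all zero).
#' @return A \code{flux_vector}: list with named \code{net} and
#'   \code{exchange} components.
#' @export
flux_from_free <- function(basis, theta = numeric(basis$n_free),
                           exchange = numeric(0)) {
  stopifnot(length(theta) == basis$n_free)
  net <- basis$v0 + as.numeric(basis$N %*% theta)
  names(net) <- basis$reactions
  flux_vector(net, exchange)
}

#' Create a flux vector
#'
#' @param net Named numeric vector of net fluxes (all reactions).
#' @param exchange Named non-negative numeric vector of exchange fluxes for
#'   reversible reactions; missing entries default to 0.
#' @return A \code{flux_vector}.
#' @export
flux_vector <- function(net, exchange = numeric(0)) {
  if (any(exchange < 0)) stop("exchange fluxes must be >= 0")
  structure(list(net = net, exchange = exchange), class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> ", length(x$net), " net fluxes",
      if (length(x$exchange)) paste0(", ", sum(x$exchange > 0), " active exchanges"),
      "\n", sep = "")
  invisible(x)
}

#' Check steady state of a flux vector
#'
#' @param net A \code{flux_network}.
#' @param v A \code{flux_vector}.
#' @param tol Relative tolerance.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_steady_state <- function(net, v, tol = 1e-9) {
  S <- stoichiometric_matrix(net)
  imbalance <- S %*% v$net[colnames(S)]
  scale <- max(abs(v$net), 1)
  if (max(abs(imbalance)) > tol * scale) {
    stop("flux vector violates steady state; worst metabolite: ",
         rownames(S)[which.max(abs(imbalance))])
  }
  invisible(TRUE)
}

#' Normalize a flux vector to glucose uptake = 100
#'
#' @param v A \code{flux_vector}.
#' @param uptake Glucose uptake rate in the units of \code{v}.
#' @return Scaled \code{flux_vector}.
#' @export
normalize_to_glucose <- function(v, uptake) {
  if (!is.finite(uptake) || uptake <= 0) stop("glucose uptake must be > 0")
  flux_vector(v$net * 100 / uptake, v$exchange * 100 / uptake)
}
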