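# Exhaustive positional-isotopomer simulator. Independent oracle for the
# EMU path: solves the full isotopomer balance of every balanced metabolite
# by fixed-point iteration over the complete 2^n state space per metabolite.

#' Brute-force steady-state isotopomer simulation
#'
#' Solves the full positional isotopomer balance exactly (to iteration
#' tolerance) for every balanced metabolite. Intended as an independent
#' correctness oracle for \code{\link{simulate_labeling}} on small networks;
#' guarded by a total state-space limit.
#'
#' @param net A \code{flux_network}.
#' @param v A \code{flux_vector}.
#' @param tracer A \code{tracer_spec}.
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param max_iter Iteration cap.
#' @param max_states Guard on the summed state-space size (sum of 2^n).
#' @return Named list: metabolite -> positional isotopomer distribution
#'   (length 2^n; bit i-1 of the 0-based state index is carbon i).
#' @export
brute_force_simulate <- function(net, v, tracer, tol = 1e-13,
                                 max_iter = 20000L, max_states = 2^20) {
  role <- stats::setNames(net$metabolites$role, net$metabolites$id)
  ncarb <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  bal <- net$metabolites$id[net$metabolites$role == "balanced" & net$metabolites$n_carbons > 0]
  if (sum(2^ncarb[bal]) > max_states) {
    stop("state-space guard exceeded: ", sum(2^ncarb[bal]), " > ", max_states)
  }
  dirs <- directional_reactions(net)
  dflux <- directional_fluxes(dirs, v)
  drop_tol <- 1e-12 * max(dflux, 1)

  dists <- list()
  for (m in names(role)) {
    n <- ncarb[[m]]
    if (n == 0) next
    if (role[[m]] == "source") {
      dists[[m]] <- input_isotopomer_dist(tracer, m, n)
    } else {
      dists[[m]] <- c(1, numeric(2^n - 1))  # start unlabeled
    }
  }

  # precompute production terms per balanced metabolite:
  # for each (direction, product entry) producing m, record per-substrate
  # position maps and per-product-state sub-indices
  prod_terms <- stats::setNames(vector("list", length(bal)), bal)
  for (k in seq_along(dirs)) {
    d <- dirs[[k]]
    for (pe in d$prods) {
      m <- pe$met
      if (!m %in% bal) next
      n <- ncarb[[m]]
      patoms <- strsplit(pe$atoms, "")[[1]]
      parts <- list()
      for (s in d$subs) {
        satoms <- strsplit(s$atoms, "")[[1]]
        ppos <- match(satoms, patoms)        # product position of each substrate atom
        keep <- !is.na(ppos)
        if (!any(keep)) next
        parts[[length(parts) + 1]] <- list(met = s$met,
                                           spos = which(keep),
                                           ppos = ppos[keep])
      }
      # per product state, per part: integer index into the part marginal
      states <- 0:(2^n - 1)
      sub_idx <- lapply(parts, function(pt) {
        idx <- integer(length(states))
        for (j in seq_along(pt$ppos)) {
          bit <- bitwAnd(bitwShiftR(states, pt$ppos[j] - 1L), 1L)
          idx <- idx + bitwShiftL(bit, j - 1L)
        }
        idx + 1L
      })
      prod_terms[[m]][[length(prod_terms[[m]]) + 1]] <-
        list(dir_idx = k, parts = parts, sub_idx = sub_idx)
    }
  }

  marginal <- function(dist, positions) {
    n <- as.integer(log2(length(dist)))
    out <- numeric(2^length(positions))
    states <- 0:(length(dist) - 1L)
    idx <- integer(length(states))
    for (j in seq_along(positions)) {
      bit <- bitwAnd(bitwShiftR(states, positions[j] - 1L), 1L)
      idx <- idx + bitwShiftL(bit, j - 1L)
    }
    for (s in seq_along(states)) out[idx[s] + 1L] <- out[idx[s] + 1L] + dist[s]
    out
  }

  W <- stats::setNames(numeric(length(bal)), bal)
  for (m in bal) {
    W[m] <- sum(vapply(prod_terms[[m]], function(t) dflux[t$dir_idx], 0))
    if (W[m] <= drop_tol) {
      stop("metabolite ", m, " has zero total production at these fluxes")
    }
  }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in bal) {
      acc <- numeric(2^ncarb[[m]])
      for (t in prod_terms[[m]]) {
        vt <- dflux[t$dir_idx]
        if (vt <= drop_tol) next
        margs <- lapply(t$parts, function(pt) marginal(dists[[pt$met]], pt$spos))
        term <- rep(vt, length(acc))
        for (j in seq_along(margs)) term <- term * margs[[j]][t$sub_idx[[j]]]
        acc <- acc + term
      }
      newd <- acc / W[m]
      delta <- max(delta, max(abs(newd - dists[[m]])))
      dists[[m]] <- newd   # Gauss-Seidel update
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("brute-force iteration did not reach tolerance (delta = ",
            format(delta), ")")
  }
  dists
}

#' Marginalize a positional isotopomer distribution to a fragment MDV
#'
#' @param dist Distribution over 2^n states (bit i-1 = carbon i).
#' @param atoms Carbon positions of the fragment.
#' @return MDV of length \code{length(atoms) + 1}.
#' @export
mdv_from_isotopomers <- function(dist, atoms) {
  n <- as.integer(round(log2(length(dist))))
  states <- 0:(length(dist) - 1L)
  shift <- integer(length(states))
  for (a in atoms) shift <- shift + bitwAnd(bitwShiftR(states, a - 1L), 1L)
  out <- numeric(length(atoms) + 1L)
  for (s in seq_along(states)) out[shift[s] + 1L] <- out[shift[s] + 1L] + dist[s]
  out
}
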