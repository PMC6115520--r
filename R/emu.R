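# EMU (elementary metabolite unit) decomposition and steady-state solve.
#
# An EMU is a metabolite together with a subset of its carbon atoms. At
# isotopic steady state the MDV of every EMU satisfies a flux-weighted
# balance: total production flux times its MDV equals the sum over producing
# reactions of flux times the MDV of the corresponding reactant EMU(s);
# condensations contribute convolutions of smaller EMUs. Grouping unknowns
# by EMU size yields one linear system per size, solved in increasing order.

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

# expand reactions into directional (irreversible) label-carrying reactions;
# each has substrates, products and a flux accessor (rid, dir)
directional_reactions <- function(net) {
  out <- list()
  for (r in net$reactions) {
    if (!r$mapped) next
    out[[length(out) + 1]] <- list(rid = r$id, dir = 1L,
                                   subs = r$reactants, prods = r$products)
    if (r$reversible) {
      out[[length(out) + 1]] <- list(rid = r$id, dir = -1L,
                                     subs = r$products, prods = r$reactants)
    }
  }
  out
}

# flux carried by each directional reaction under flux vector v
directional_fluxes <- function(dirs, v) {
  vapply(dirs, function(d) {
    net <- v$net[[d$rid]]
    exch <- if (d$rid %in% names(v$exchange)) v$exchange[[d$rid]] else 0
    if (d$dir == 1L) max(net, 0) + exch else max(-net, 0) + exch
  }, 0)
}

#' Decompose a network into the EMU reaction graph for target fragments
#'
#' Traces every target EMU back through all producing reactions until only
#' source-metabolite (input) EMUs remain, recording convolution terms where
#' a reaction condenses carbon from several substrates. The result is a
#' compiled structure (integer-indexed EMU table, per-EMU production terms,
#' size levels in solve order) reusable across flux vectors and tracers.
#'
#' @param net A \code{flux_network}.
#' @param targets List of \code{list(met =, atoms =)} target EMUs, or a
#'   fragment table (data.frame with \code{amino_acid}, \code{carbon_set}).
#' @return An \code{emu_decomposition}.
#' @export
emu_decompose <- function(net, targets) {
  if (is.data.frame(targets)) {
    targets <- lapply(seq_len(nrow(targets)), function(i) {
      list(met = targets$amino_acid[i],
           atoms = parse_carbon_set(targets$carbon_set[i]))
    })
  }
  role <- stats::setNames(net$metabolites$role, net$metabolites$id)
  dirs <- directional_reactions(net)

  prod_index <- list()  # metabolite -> matrix of (direction idx, product entry idx)
  for (k in seq_along(dirs)) {
    for (pi in seq_along(dirs[[k]]$prods)) {
      met <- dirs[[k]]$prods[[pi]]$met
      prod_index[[met]] <- rbind(prod_index[[met]], c(k, pi))
    }
  }

  id_of <- new.env(parent = emptyenv())
  emus <- list()   # id -> list(met, atoms, size, input)
  terms <- list()  # id -> list of list(dir_idx, src_ids)
  queue <- integer(0)
  register <- function(met, atoms) {
    key <- emu_key(met, atoms)
    id <- id_of[[key]]
    if (is.null(id)) {
      id <- length(emus) + 1L
      assign(key, id, envir = id_of)
      emus[[id]] <<- list(met = met, atoms = atoms, size = length(atoms),
                          input = unname(role[met]) == "source")
      if (!emus[[id]]$input) queue <<- c(queue, id)
    }
    id
  }
  target_ids <- vapply(targets, function(t) {
    if (!t$met %in% names(role)) stop("target references unknown metabolite ", t$met)
    register(t$met, sort(t$atoms))
  }, 0L)

  done <- integer(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    if (id %in% done) next
    done <- c(done, id)
    e <- emus[[id]]
    producers <- prod_index[[e$met]]
    tlist <- list()
    if (!is.null(producers)) {
      for (row in seq_len(nrow(producers))) {
        k <- producers[row, 1]; pi <- producers[row, 2]
        d <- dirs[[k]]
        patoms <- strsplit(d$prods[[pi]]$atoms, "")[[1]]
        letters <- patoms[e$atoms]
        src_ids <- integer(0)
        for (s in d$subs) {
          satoms <- strsplit(s$atoms, "")[[1]]
          pos <- which(satoms %in% letters)
          if (length(pos)) src_ids <- c(src_ids, register(s$met, pos))
        }
        tlist[[length(tlist) + 1]] <- list(dir_idx = k, src_ids = src_ids)
      }
    }
    if (!length(tlist)) {
      stop("unreachable EMU: ", emu_key(e$met, e$atoms),
           " has no producing reaction")
    }
    terms[[id]] <- tlist
  }

  sizes <- vapply(emus, `[[`, 0L, "size")
  inputs <- vapply(emus, `[[`, TRUE, "input")
  levels <- lapply(sort(unique(sizes[!inputs])), function(s) {
    which(sizes == s & !inputs)
  })
  structure(list(emus = emus, terms = terms, levels = levels, dirs = dirs,
                 targets = targets, target_ids = target_ids,
                 input_ids = which(inputs)),
            class = "emu_decomposition")
}

#' @export
print.emu_decomposition <- function(x, ...) {
  sizes <- vapply(x$emus, `[[`, 0L, "size")
  cat("<emu_decomposition> ", length(x$emus), " EMUs over sizes {",
      paste(sort(unique(sizes)), collapse = ", "), "}, ",
      length(x$input_ids), " inputs\n", sep = "")
  invisible(x)
}

# full discrete convolution (sizes add)
convolve_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  out <- numeric(n)
  for (j in seq_along(y)) {
    idx <- j:(j + length(x) - 1L)
    out[idx] <- out[idx] + x * y[j]
  }
  out
}

#' Solve steady-state EMU balances
#'
#' @param net A \code{flux_network}.
#' @param v A \code{flux_vector} (steady-state feasible).
#' @param tracer A \code{tracer_spec}.
#' @param decomp An \code{emu_decomposition} from \code{\link{emu_decompose}}.
#' @return List of MDVs indexed like \code{decomp$emus}.
#' @export
solve_emus <- function(net, v, tracer, decomp) {
  dflux <- directional_fluxes(decomp$dirs, v)
  drop_tol <- 1e-12 * max(dflux, 1)
  emus <- decomp$emus
  vals <- vector("list", length(emus))
  for (id in decomp$input_ids) {
    vals[[id]] <- input_emu_mdv(tracer, emus[[id]]$met, emus[[id]]$atoms)
  }
  for (lev in decomp$levels) {
    n <- length(lev)
    s <- emus[[lev[1]]]$size
    pos <- integer(length(emus)); pos[lev] <- seq_len(n)
    A <- matrix(0, n, n)
    B <- matrix(0, n, s + 1L)
    for (i in seq_len(n)) {
      id <- lev[i]
      W <- 0
      for (t in decomp$terms[[id]]) {
        vt <- dflux[t$dir_idx]
        if (vt <= drop_tol) next
        W <- W + vt
        src <- t$src_ids
        if (length(src) == 1L && pos[src] > 0L) {
          A[i, pos[src]] <- A[i, pos[src]] - vt
        } else {
          known <- vals[[src[1]]]
          if (length(src) > 1L) {
            for (j in 2:length(src)) known <- convolve_full(known, vals[[src[j]]])
          }
          B[i, ] <- B[i, ] + vt * known
        }
      }
      if (W <= drop_tol) {
        stop("singular EMU balance: ", emu_key(emus[[id]]$met, emus[[id]]$atoms),
             " has zero total production at these fluxes")
      }
      A[i, i] <- A[i, i] + W
    }
    X <- tryCatch(solve(A, B), error = function(e) {
      stop("singular EMU system at size ", s, ": ", conditionMessage(e))
    })
    for (i in seq_len(n)) {
      x <- X[i, ]
      x[x < 0] <- 0
      vals[[lev[i]]] <- x / sum(x)
    }
  }
  vals
}

#' Simulate steady-state fragment MDVs
#'
#' Forward-simulates the mass isotopomer distributions of the requested
#' fragments from a flux vector and a tracer, via EMU decomposition.
#'
#' @param net A \code{flux_network}.
#' @param v A \code{flux_vector}.
#' @param tracer A \code{tracer_spec}.
#' @param fragments Fragment table (data.frame) or list of targets.
#' @param decomp Optional precomputed \code{emu_decomposition} (reused
#'   across calls with the same network and fragments, e.g. in the fitter).
#' @return Named list: fragment name -> MDV.
#' @export
simulate_labeling <- function(net, v, tracer, fragments, decomp = NULL) {
  if (is.null(decomp)) decomp <- emu_decompose(net, fragments)
  vals <- solve_emus(net, v, tracer, decomp)
  out <- lapply(decomp$target_ids, function(id) vals[[id]])
  names(out) <- if (is.data.frame(fragments)) fragments$fragment else
    vapply(decomp$targets, function(t) emu_key(t$met, sort(t$atoms)), "")
  out
}

#' MDV of a single metabolite carbon subset
#'
#' Convenience wrapper simulating one EMU.
#'
#' @inheritParams simulate_labeling
#' @param met Metabolite id.
#' @param atoms Carbon positions (default all).
#' @return MDV.
#' @export
emu_mdv <- function(net, v, tracer, met, atoms = NULL) {
  if (is.null(atoms)) {
    nc <- net$metabolites$n_carbons[match(met, net$metabolites$id)]
    atoms <- seq_len(nc)
  }
  simulate_labeling(net, v, tracer, list(list(met = met, atoms = atoms)))[[1]]
}
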