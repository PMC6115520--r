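# Synthetic-data generation: toy fixtures, ground-truth flux sampling and
# simulated GC-MS tracer datasets with the error structure the analysis
# assumes (additive Gaussian per mass channel, then renormalization).

#' Toy network fixtures
#'
#' Small atom-mapped networks used throughout the tests and documentation:
#' \describe{
#'   \item{linear}{chain AX -> B -> CX, two carbons}
#'   \item{diamond}{split AX -> A; A -> B and A -> C (atoms swapped on the
#'     C branch); both rejoin at D}
#'   \item{condense}{condensation XX -> X, YY -> Y, X + Y -> Z}
#'   \item{emp_serine}{EMP-only glucose-to-serine route: FBA split, TPI
#'     interconversion, serine from 3-phosphoglycerate}
#'   \item{reference}{the packaged C. thermocellum network}
#'   \item{tca_added}{reference plus an oxidative 2OG -> OAA reaction}
#' }
#'
#' @return Named list of \code{flux_network} objects.
#' @export
toy_networks <- function() {
  lin_mets <- data.frame(id = c("AX", "B", "CX"), n_carbons = c(2, 2, 2),
                         role = c("source", "balanced", "sink"))
  linear <- parse_network(c("UPT: AX (ab) -> B (ab)",
                            "OUT: B (ab) -> CX (ab)"), lin_mets)

  dia_mets <- data.frame(id = c("AX", "A", "B", "C", "D", "DX"),
                         n_carbons = c(2, 2, 2, 2, 2, 2),
                         role = c("source", rep("balanced", 4), "sink"))
  diamond <- parse_network(c("UPT: AX (ab) -> A (ab)",
                             "R1: A (ab) -> B (ab)",
                             "R2: A (ab) -> C (ba)",
                             "R3: B (ab) -> D (ab)",
                             "R4: C (ab) -> D (ab)",
                             "OUT: D (ab) -> DX (ab)"), dia_mets)

  con_mets <- data.frame(id = c("XX", "YY", "X", "Y", "Z", "ZX"),
                         n_carbons = c(1, 1, 1, 1, 2, 2),
                         role = c("source", "source", rep("balanced", 3), "sink"))
  condense <- parse_network(c("U1: XX (a) -> X (a)",
                              "U2: YY (a) -> Y (a)",
                              "COND: X (a) + Y (b) -> Z (ab)",
                              "OUT: Z (ab) -> ZX (ab)"), con_mets)

  emp_mets <- data.frame(
    id = c("GLCX", "FBP", "DHAP", "GAP", "PGA", "SER", "SERX"),
    n_carbons = c(6, 6, 3, 3, 3, 3, 3),
    role = c("source", rep("balanced", 5), "sink"))
  emp_serine <- parse_network(c(
    "UPT: GLCX (abcdef) -> FBP (abcdef)",
    "FBA: FBP (abcdef) -> DHAP (abc) + GAP (def)",
    "TPI: DHAP (abc) -> GAP (cba)",
    "GAPD: GAP (abc) -> PGA (abc)",
    "SERS: PGA (abc) -> SER (abc)",
    "OUT: SER (abc) -> SERX (abc)"), emp_mets)

  list(linear = linear, diamond = diamond, condense = condense,
       emp_serine = emp_serine, reference = ct_network(),
       tca_added = ct_network("tca_added"))
}

#' Draw a random feasible ground-truth flux vector
#'
#' Samples the steady-state flux polytope (S v = 0, fixed values honored,
#' irreversible net fluxes non-negative, all net fluxes within \code{cap})
#' by hit-and-run from a feasible interior point. Deterministic per seed;
#' the caller's RNG state is left untouched.
#'
#' @param net A \code{flux_network}.
#' @param seed Integer seed.
#' @param fixed Named fixed net fluxes (default glucose uptake 100 when the
#'   network has a \code{GLCUP} reaction, otherwise the first reaction at
#'   100).
#' @param cap Bound on |net flux| defining a bounded polytope.
#' @param n_steps Hit-and-run steps.
#' @return A steady-state \code{flux_vector} with zero exchange fluxes.
#' @export
make_ground_truth <- function(net, seed = 1L, fixed = NULL, cap = 500,
                              n_steps = 60L) {
  if (is.null(fixed)) {
    r1 <- if ("GLCUP" %in% names(net$reactions)) "GLCUP" else
      names(net$reactions)[1]
    fixed <- stats::setNames(100, r1)
  }
  basis <- free_flux_basis(net, fixed = fixed)
  if (basis$n_free == 0) return(flux_from_free(basis))

  # inequality system G theta <= h encoding irreversibility and the cap
  irr <- basis$irreversible
  G <- rbind(-basis$N[irr, , drop = FALSE],
             basis$N, -basis$N)
  h <- c(basis$v0[irr], cap - basis$v0, cap + basis$v0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  theta <- feasible_point(basis, G, h)
  for (step in seq_len(n_steps)) {
    d <- stats::rnorm(basis$n_free)
    d <- d / sqrt(sum(d^2))
    gd <- as.numeric(G %*% d)
    slack <- h - as.numeric(G %*% theta)
    tmax <- suppressWarnings(min((slack / gd)[gd > 1e-12]))
    tmin <- suppressWarnings(max((slack / gd)[gd < -1e-12]))
    if (!is.finite(tmax)) tmax <- 0
    if (!is.finite(tmin)) tmin <- 0
    if (tmax <= tmin) next
    theta <- theta + stats::runif(1, tmin, tmax) * d
  }
  flux_from_free(basis, theta)
}

# find an interior point of {G theta <= h} by penalized least squares
feasible_point <- function(basis, G, h, margin = 1e-3, budget = 200L) {
  theta <- numeric(basis$n_free)
  fn <- function(th) {
    viol <- pmax(as.numeric(G %*% th) - h + margin, 0)
    sum(viol^2)
  }
  gr <- function(th) {
    viol <- pmax(as.numeric(G %*% th) - h + margin, 0)
    2 * as.numeric(crossprod(G, viol))
  }
  opt <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = budget))
  if (fn(opt$par) > 1e-12) {
    stop("no feasible interior point found (rejection budget exceeded); ",
         "bounds are infeasible or the polytope has empty interior")
  }
  opt$par
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Noise model for synthetic GC-MS measurements
#'
#' @param sd Additive Gaussian standard deviation per mass channel, in
#'   absolute mole-fraction units (default 0.005 = 0.5 mol\%).
#' @param natural_abundance Convolve simulated fragment MDVs with natural
#'   isotope abundance of the non-skeleton atoms before adding noise.
#' @param seed Integer seed.
#' @return A \code{noise_model} list.
#' @export
noise_model <- function(sd = 0.005, natural_abundance = FALSE, seed = 1L) {
  if (sd <= 0) stop("noise sd must be > 0")
  structure(list(sd = sd, natural_abundance = natural_abundance,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Simulate a synthetic tracer dataset
#'
#' For each tracer, simulates steady-state fragment MDVs from the
#' ground-truth fluxes, optionally convolves natural abundance, adds seeded
#' Gaussian noise per mass channel, clamps negatives and renormalizes, and
#' attaches the configured sd as the reported measurement sd. Extracellular
#' rates are emitted noise-free from the truth with nominal sds.
#'
#' @param net A \code{flux_network}.
#' @param truth Ground-truth \code{flux_vector}.
#' @param tracers Named list of \code{tracer_spec}s.
#' @param fragments Fragment table.
#' @param noise A \code{noise_model} (or NULL for noise-free).
#' @param rate_reactions Reactions whose net fluxes are reported as measured
#'   extracellular rates.
#' @param rate_sd Standard deviation attached to the rates.
#' @param ratios Optional ratio-constraint definitions: data.frame with
#'   columns \code{branch}, \code{num}, \code{den} (comma-separated reaction
#'   ids) and \code{sd}; values are computed from the truth.
#' @return A \code{measurement_set}: list with data.frames \code{mdv}
#'   (tracer, fragment, mass, value, sd), \code{rates} (reaction, value,
#'   sd), \code{ratios} (branch, num, den, value, sd).
#' @export
simulate_dataset <- function(net, truth, tracers, fragments,
                             noise = noise_model(),
                             rate_reactions = character(0), rate_sd = 1,
                             ratios = NULL) {
  decomp <- emu_decompose(net, fragments)
  rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(noise)) set.seed(noise$seed)
  for (tn in names(tracers)) {
    sim <- simulate_labeling(net, truth, tracers[[tn]], fragments, decomp)
    for (i in seq_len(nrow(fragments))) {
      fname <- fragments$fragment[i]
      mdv <- sim[[fname]]
      if (!is.null(noise) && noise$natural_abundance) {
        mdv <- convolve_natural_abundance(mdv, fragments$formula[i])
        mdv <- mdv / sum(mdv)
      }
      if (!is.null(noise)) {
        mdv <- mdv + stats::rnorm(length(mdv), 0, noise$sd)
        mdv <- pmax(mdv, 0)
        mdv <- mdv / sum(mdv)
      }
      rows[[length(rows) + 1]] <- data.frame(
        tracer = tn, fragment = fname, mass = seq_along(mdv) - 1L,
        value = mdv, sd = if (is.null(noise)) 1e-4 else noise$sd)
    }
  }
  mdv_tab <- do.call(rbind, rows)
  rates <- if (length(rate_reactions)) {
    data.frame(reaction = rate_reactions,
               value = unname(truth$net[rate_reactions]),
               sd = rate_sd)
  } else NULL
  ratio_tab <- NULL
  if (!is.null(ratios)) {
    ratio_tab <- ratios
    ratio_tab$value <- vapply(seq_len(nrow(ratios)), function(i) {
      num <- sum(truth$net[strsplit(ratios$num[i], ",")[[1]]])
      den <- sum(truth$net[strsplit(ratios$den[i], ",")[[1]]])
      num / den
    }, 0)
  }
  measurement_set(mdv_tab, rates, ratio_tab)
}

#' Construct a measurement set
#'
#' @param mdv data.frame with columns tracer, fragment, mass, value, sd.
#' @param rates data.frame with columns reaction, value, sd (may be empty).
#' @param ratios Optional data.frame with columns branch, num, den, value,
#'   sd; num/den are comma-separated reaction id lists whose summed net
#'   fluxes form the constrained ratio.
#' @return A \code{measurement_set}.
#' @export
measurement_set <- function(mdv, rates = NULL, ratios = NULL) {
  if (any(mdv$sd <= 0)) stop("measurement sds must be > 0")
  if (!is.null(rates) && nrow(rates) && any(rates$sd <= 0)) {
    stop("rate sds must be > 0")
  }
  if (!is.null(ratios) && nrow(ratios) && any(ratios$sd <= 0)) {
    stop("ratio sds must be > 0")
  }
  structure(list(mdv = mdv, rates = rates, ratios = ratios),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set> ", length(unique(x$mdv$fragment)), " fragments x ",
      length(unique(x$mdv$tracer)), " tracer(s), ",
      if (!is.null(x$rates)) nrow(x$rates) else 0, " rates, ",
      if (!is.null(x$ratios)) nrow(x$ratios) else 0, " ratio constraints\n",
      sep = "")
  invisible(x)
}
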