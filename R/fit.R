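# Global flux estimation: weighted sum-of-squared-residuals minimization
# over the free-flux parameterization, against fragment MDVs, extracellular
# rates and ratio pseudo-measurements; goodness of fit by the chi-square
# criterion; per-flux profile-likelihood confidence intervals.

# LM with the solver's iteration-budget chatter muffled (multi-start and
# profile searches hit those caps by design; convergence is judged on the
# returned objective, not the stopping code)
quiet_lm <- function(...) {
  withCallingHandlers(
    minpack.lm::nls.lm(...),
    warning = function(w) {
      if (grepl("lmdif|lmder|maxiter|maxfev", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# internal: evaluation context shared by the fitter and the CI search
fit_context <- function(net, meas, tracers, fragments, fixed,
                        free_exchanges, exchange_cap) {
  basis <- free_flux_basis(net, fixed = fixed)
  decomp <- emu_decompose(net, fragments)
  # index measurement rows into the simulated MDV list once
  mdv <- meas$mdv
  mdv$row_id <- seq_len(nrow(mdv))
  groups <- split(mdv, mdv$tracer)
  for (tn in names(groups)) {
    if (!tn %in% names(tracers)) {
      stop("measurements reference tracer '", tn, "' not supplied")
    }
  }
  list(net = net, meas = meas, tracers = tracers, fragments = fragments,
       basis = basis, decomp = decomp, groups = groups,
       free_exchanges = free_exchanges, exchange_cap = exchange_cap,
       n_par = basis$n_free + length(free_exchanges))
}

ctx_flux <- function(ctx, par) {
  theta <- par[seq_len(ctx$basis$n_free)]
  exch <- numeric(0)
  if (length(ctx$free_exchanges)) {
    t <- par[ctx$basis$n_free + seq_along(ctx$free_exchanges)]
    exch <- stats::setNames(ctx$exchange_cap * t / (1 - t), ctx$free_exchanges)
  }
  flux_from_free(ctx$basis, theta, exchange = exch)
}

# measurement residuals (weighted) for a flux vector; simulation failures
# surface as a uniformly large residual so the optimizer retreats
ctx_residuals <- function(ctx, v, penalty_weight = 1e3) {
  res <- numeric(0)
  sim_res <- tryCatch({
    out <- numeric(nrow(ctx$meas$mdv))
    for (tn in names(ctx$groups)) {
      g <- ctx$groups[[tn]]
      sim <- simulate_labeling(ctx$net, v, ctx$tracers[[tn]],
                               ctx$fragments, ctx$decomp)
      simv <- vapply(seq_len(nrow(g)), function(i) {
        sim[[g$fragment[i]]][g$mass[i] + 1L]
      }, 0)
      out[g$row_id] <- (simv - g$value) / g$sd
    }
    out
  }, error = function(e) rep(1e3, nrow(ctx$meas$mdv)))
  res <- c(res, sim_res)
  if (!is.null(ctx$meas$rates) && nrow(ctx$meas$rates)) {
    r <- ctx$meas$rates
    res <- c(res, (v$net[r$reaction] - r$value) / r$sd)
  }
  if (!is.null(ctx$meas$ratios) && nrow(ctx$meas$ratios)) {
    r <- ctx$meas$ratios
    rr <- vapply(seq_len(nrow(r)), function(i) {
      num <- sum(v$net[strsplit(r$num[i], ",")[[1]]])
      den <- sum(v$net[strsplit(r$den[i], ",")[[1]]])
      num / den
    }, 0)
    res <- c(res, (rr - r$value) / r$sd)
  }
  pen <- penalty_weight * pmin(v$net[ctx$basis$irreversible], 0)
  list(meas = res, penalty = pen)
}

#' Weighted sum of squared residuals
#'
#' The fit objective: sum over all MDV mass channels, rates and ratio
#' constraints of ((simulated - observed) / sd)^2.
#'
#' @param v A \code{flux_vector}.
#' @param meas A \code{measurement_set}.
#' @param net A \code{flux_network}.
#' @param tracers Named list of \code{tracer_spec}s.
#' @param fragments Fragment table.
#' @return Scalar SSR.
#' @export
weighted_ssr <- function(v, meas, net, tracers, fragments) {
  ctx <- fit_context(net, meas, tracers, fragments, fixed = numeric(0),
                     free_exchanges = character(0), exchange_cap = 1)
  sum(ctx_residuals(ctx, v)$meas^2)
}

# independent measurement count: per fragment/tracer MDV the unit-sum
# channel is redundant, so k masses contribute k - 1
count_measurements <- function(meas) {
  n_mdv <- 0
  if (nrow(meas$mdv)) {
    per <- table(paste(meas$mdv$tracer, meas$mdv$fragment))
    n_mdv <- sum(per - 1L)
  }
  n_mdv + (if (!is.null(meas$rates)) nrow(meas$rates) else 0) +
    (if (!is.null(meas$ratios)) nrow(meas$ratios) else 0)
}

#' Fit fluxes to tracer data
#'
#' Multi-start bounded nonlinear least squares (Levenberg-Marquardt) over
#' the free-flux parameters. Net fluxes are parameterized on the
#' steady-state null space (so every iterate balances exactly); exchange
#' fluxes listed in \code{free_exchanges} are optimized on the transformed
#' scale t = exch / (exch + cap) in [0, 1). Irreversible-flux sign
#' constraints enter as smooth penalty residuals. Deterministic given
#' \code{seed}.
#'
#' @param net A \code{flux_network}.
#' @param meas A \code{measurement_set}.
#' @param tracers Named list of \code{tracer_spec}s matching the tracer
#'   column of the measurements.
#' @param fragments Fragment table.
#' @param fixed Named fixed net fluxes (e.g. \code{c(GLCUP = 100)}).
#' @param free_exchanges Reversible reaction ids whose exchange fluxes are
#'   fitted (others fixed at zero).
#' @param restarts Number of random starts.
#' @param seed Integer seed for the start draws.
#' @param exchange_cap Scale constant of the exchange transform (default
#'   10x the largest fixed flux, i.e. 10x glucose uptake on the 100 scale).
#' @param maxiter LM iteration cap per start.
#' @return A \code{flux_fit} object.
#' @export
fit_fluxes <- function(net, meas, tracers, fragments,
                       fixed = c(GLCUP = 100),
                       free_exchanges = character(0),
                       restarts = 20L, seed = 1L,
                       exchange_cap = NULL, maxiter = 500L) {
  if (restarts < 1) stop("at least one restart is required")
  if (is.null(exchange_cap)) exchange_cap <- 10 * max(abs(fixed), 10)
  ctx <- fit_context(net, meas, tracers, fragments, fixed,
                     free_exchanges, exchange_cap)
  n_meas <- count_measurements(meas)
  dof <- n_meas - ctx$n_par
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  lower <- c(rep(-Inf, ctx$basis$n_free), rep(0, length(free_exchanges)))
  upper <- c(rep(Inf, ctx$basis$n_free), rep(0.99, length(free_exchanges)))

  best <- NULL
  n_ok <- 0L
  for (k in seq_len(restarts)) {
    start_seed <- sample.int(2^30, 1)
    th0 <- tryCatch({
      v0 <- make_ground_truth(net, seed = start_seed, fixed = fixed)
      qr.solve(ctx$basis$N, v0$net - ctx$basis$v0)
    }, error = function(e) NULL)
    if (is.null(th0)) next
    par0 <- c(th0, stats::runif(length(free_exchanges), 0, 0.3))
    fn <- function(p) {
      r <- ctx_residuals(ctx, ctx_flux(ctx, p))
      c(r$meas, r$penalty)
    }
    ans <- tryCatch(
      quiet_lm(par0, lower = lower, upper = upper, fn = fn,
               control = minpack.lm::nls.lm.control(
                 maxiter = maxiter, maxfev = 100000L, ftol = 1e-12,
                 ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(ans)) next
    n_ok <- n_ok + 1L
    r <- ctx_residuals(ctx, ctx_flux(ctx, ans$par))
    ssr <- sum(r$meas^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = ans$par, ssr = ssr, residuals = r$meas,
                   trace = ans$rsstrace, info = ans$info)
    }
  }
  if (is.null(best)) {
    stop("no feasible start found / optimizer failed in all restarts")
  }
  v <- ctx_flux(ctx, best$par)
  # clamp penalty-level negatives on irreversible fluxes
  v$net[ctx$basis$irreversible] <- pmax(v$net[ctx$basis$irreversible], 0)
  structure(list(flux = v, par = best$par, ssr = best$ssr,
                 residuals = best$residuals, dof = dof, n_meas = n_meas,
                 n_par = ctx$n_par, restarts = restarts, n_converged = n_ok,
                 seed = seed, trace = best$trace, ctx = ctx),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> SSR = %.4g on %d dof (%d measurements, %d parameters), %d/%d starts converged\n",
              x$ssr, x$dof, x$n_meas, x$n_par, x$n_converged, x$restarts))
  invisible(x)
}

#' Chi-square goodness of fit
#'
#' Accepts the fit when the SSR lies inside the central chi-square interval
#' [chi2(alpha/2, dof), chi2(1 - alpha/2, dof)].
#'
#' @param fit A \code{flux_fit}.
#' @param alpha Significance level (default 0.05).
#' @return List with the verdict and the acceptance interval.
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  if (fit$dof <= 0) stop("degrees of freedom must be positive")
  lo <- stats::qchisq(alpha / 2, fit$dof)
  hi <- stats::qchisq(1 - alpha / 2, fit$dof)
  list(ssr = fit$ssr, dof = fit$dof, lower = lo, upper = hi,
       accept = fit$ssr <= hi, alpha = alpha)
}

# profile SSR at net flux of `reaction` pinned to `target`, warm-started
profile_ssr <- function(fit, reaction, target, warm, pin_sd = 1e-5,
                        maxiter = 100L) {
  ctx <- fit$ctx
  fn <- function(p) {
    v <- ctx_flux(ctx, p)
    r <- ctx_residuals(ctx, v)
    c(r$meas, r$penalty, (v$net[[reaction]] - target) / pin_sd)
  }
  lower <- c(rep(-Inf, ctx$basis$n_free),
             rep(0, length(ctx$free_exchanges)))
  upper <- c(rep(Inf, ctx$basis$n_free),
             rep(0.99, length(ctx$free_exchanges)))
  ans <- quiet_lm(warm, lower = lower, upper = upper, fn = fn,
                  control = minpack.lm::nls.lm.control(
                    maxiter = maxiter, maxfev = 100000L, ftol = 1e-12,
                    ptol = 1e-10))
  r <- ctx_residuals(ctx, ctx_flux(ctx, ans$par))
  list(ssr = sum(r$meas^2), par = ans$par)
}

#' Profile-likelihood confidence intervals for net fluxes
#'
#' For each reaction, finds the flux range over which the re-optimized SSR
#' stays below SSR_min + chi2(1, 1 - alpha), by outward stepping and
#' bisection on each side (one degree of freedom per profiled flux). A side
#' that never crosses the threshold before \code{search_cap} is reported
#' open-ended (infinite bound, \code{flag = "open"}), marking an
#' unidentifiable direction.
#'
#' @param fit A \code{flux_fit}.
#' @param reactions Reaction ids to profile (default: all non-fixed).
#' @param alpha Significance level (default 0.05 for 95\% intervals).
#' @param step_tol Bisection tolerance in flux units.
#' @param search_cap Maximum |flux| explored before declaring a side open.
#' @return data.frame(reaction, estimate, lower, upper, flag).
#' @export
confidence_intervals <- function(fit, reactions = NULL, alpha = 0.05,
                                 step_tol = 1e-3, search_cap = 1e4) {
  ctx <- fit$ctx
  if (is.null(reactions)) {
    reactions <- setdiff(ctx$basis$reactions, names(ctx$basis$fixed))
  }
  thr <- fit$ssr + stats::qchisq(1 - alpha, 1)
  out <- lapply(reactions, function(r) {
    est <- fit$flux$net[[r]]
    # flux fully determined by the constraints -> degenerate interval
    span <- if (ctx$basis$n_free)
      sqrt(sum(ctx$basis$N[r, ]^2)) else 0
    if (span < 1e-12) {
      return(data.frame(reaction = r, estimate = est, lower = est,
                        upper = est, flag = "determined"))
    }
    one_side <- function(sgn) {
      step <- max(0.02 * max(abs(est), 1), 10 * step_tol)
      warm <- fit$par
      inner <- est
      repeat {
        target <- inner + sgn * step
        if (r %in% ctx$basis$irreversible) target <- max(target, 0)
        p <- profile_ssr(fit, r, target, warm)
        if (p$ssr > thr) { outer <- target; break }
        warm <- p$par
        inner <- target
        if (r %in% ctx$basis$irreversible && target <= 0) {
          return(list(bound = 0, flag = "ok"))
        }
        if (abs(target) > search_cap) {
          return(list(bound = sgn * Inf, flag = "open"))
        }
        step <- step * 2
      }
      while (abs(outer - inner) > step_tol) {
        mid <- (outer + inner) / 2
        p <- profile_ssr(fit, r, mid, warm)
        if (p$ssr > thr) outer <- mid else { inner <- mid; warm <- p$par }
      }
      list(bound = (outer + inner) / 2, flag = "ok")
    }
    lo <- one_side(-1)
    hi <- one_side(+1)
    flag <- if (lo$flag == "open" || hi$flag == "open") "open" else "ok"
    data.frame(reaction = r, estimate = est,
               lower = min(lo$bound, est), upper = max(hi$bound, est),
               flag = flag)
  })
  do.call(rbind, out)
}
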