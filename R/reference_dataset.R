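#' Default synthetic measurement configuration for the reference network
#'
#' Builds the standard synthetic GC-MS dataset used to exercise global flux
#' fitting on the packaged network: all packaged amino-acid fragments under
#' the 20\% [U-13C6] glucose tracer, extracellular rates (lactate, acetate,
#' ethanol, formate excretion and growth) taken noise-free from the truth,
#' and two ratio pseudo-measurements that steady-state labeling alone
#' cannot resolve because the routes form no distinguishable carbon-carbon
#' bonds: the PPDK share of direct PEP-to-pyruvate conversion, and the
#' malate-shunt share of total pyruvate formation from PEP. Supplying such
#' branch-point ratios from independent experiments is standard practice
#' for this network.
#'
#' @param net The reference network (or \code{tca_added} variant).
#' @param truth Ground-truth \code{flux_vector} (default packaged regime).
#' @param noise A \code{noise_model}, or NULL for noise-free data.
#' @param rate_sd Standard deviation attached to the rates.
#' @param ratio_sd Standard deviation of the ratio pseudo-measurements.
#' @return List with elements \code{measurements} (a
#'   \code{measurement_set}), \code{tracers}, \code{fragments},
#'   \code{truth}.
#' @export
ct_reference_dataset <- function(net = ct_network(),
                                 truth = ct_reference_fluxes(net),
                                 noise = NULL, rate_sd = 0.5,
                                 ratio_sd = 0.02) {
  fragments <- ct_fragments()
  tracers <- list(glc_u13c_20 = ct_tracer("glc_u13c_20"))
  rates <- c("LDH", "PTA", "ADH", "FOROUT", "BIOMASS")
  ratios <- data.frame(
    branch = c("ppdk_vs_pk", "malate_shunt"),
    num = c("PPDK", "ME"),
    den = c("PK,PPDK", "PK,PPDK,ME"),
    sd = ratio_sd)
  meas <- simulate_dataset(net, truth, tracers, fragments, noise = noise,
                           rate_reactions = rates, rate_sd = rate_sd,
                           ratios = ratios)
  list(measurements = meas, tracers = tracers, fragments = fragments,
       truth = truth)
}
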