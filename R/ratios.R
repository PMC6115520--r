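# Local flux-ratio estimators at pathway branch points. All estimators are
# constrained least squares on the two-endmember mixture model
# observed = f * a + (1 - f) * b, with f restricted to [0, 1].

#' Constrained two-endmember mixture fit
#'
#' Finds f in [0, 1] minimizing ||observed - f a - (1 - f) b||^2 by
#' closed-form projection onto the segment between the endmembers.
#'
#' @param observed Observed MDV (or any numeric vector).
#' @param endmember_a MDV predicted if the pool derives entirely from
#'   pathway A (f = 1).
#' @param endmember_b MDV predicted for pathway B (f = 0).
#' @param branch Label for reporting.
#' @return A \code{ratio_estimate}: list(value, residual, branch).
#' @export
mixture_ratio <- function(observed, endmember_a, endmember_b,
                          branch = "mixture") {
  if (length(observed) != length(endmember_a) ||
      length(observed) != length(endmember_b)) {
    stop("observed and endmember MDVs must have equal length")
  }
  d <- endmember_a - endmember_b
  nd2 <- sum(d^2)
  if (nd2 < 1e-20) {
    stop("identical endmembers: mixture fraction is unidentifiable for ",
         branch)
  }
  f <- sum((observed - endmember_b) * d) / nd2
  f <- min(max(f, 0), 1)
  resid <- sqrt(sum((observed - f * endmember_a - (1 - f) * endmember_b)^2))
  structure(list(value = f, residual = resid, branch = branch),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> %s: f = %.4f (residual %.3g)\n",
              x$branch, x$value, x$residual))
  invisible(x)
}

#' Fraction of serine derived through the EMP pathway
#'
#' Under 100\% [1-13C] glucose, serine made through EMP glycolysis is
#' labeled at C3 in half of the molecules (MDV [0.5, 0.5, 0, 0]) while
#' serine from other glycolytic routes is unlabeled ([1, 0, 0, 0]); the
#' mixture weight is therefore f = 2 m1.
#'
#' @param serine_mdv Corrected serine C1-C3 MDV (length 4).
#' @param tol Consistency tolerance on m1 <= 0.5.
#' @return A \code{ratio_estimate}; flagged (attribute
#'   \code{inconsistent = TRUE}) when m1 exceeds 0.5 beyond \code{tol}.
#' @export
serine_emp_fraction <- function(serine_mdv, tol = 0.02) {
  if (length(serine_mdv) != 4) stop("serine MDV must cover C1-C3 (length 4)")
  est <- mixture_ratio(serine_mdv, c(0.5, 0.5, 0, 0), c(1, 0, 0, 0),
                       branch = "serine_EMP")
  if (serine_mdv[2] > 0.5 + tol) {
    warning("serine m1 = ", format(serine_mdv[2]),
            " exceeds the EMP-model maximum of 0.5; estimate flagged")
    attr(est, "inconsistent") <- TRUE
  }
  est
}

#' Fraction of oxaloacetate formed oxidatively from 2-oxoglutarate
#'
#' Estimates, from an aspartate (oxaloacetate-derived) MDV, the mixture
#' weight between OAA formed oxidatively from 2-oxoglutarate (TCA cycle)
#' and OAA formed anaplerotically from PEP + CO2. Endmember MDVs are built
#' from precursor labeling simulated under the actual tracer: the oxidative
#' endmember maps 2OG carbons 2-5 onto OAA 1-4 (C1 lost as CO2); the
#' anaplerotic endmember is the convolution of PEP and the CO2 pool per the
#' PEP carboxylase atom map.
#'
#' @param asp_mdv Observed aspartate MDV over the fragment carbons.
#' @param net Network used to simulate precursor labeling (use the
#'   \code{tca_added} variant when the oxidative route carries flux).
#' @param v Flux vector for the precursor simulation.
#' @param tracer A \code{tracer_spec}.
#' @param carbons Aspartate carbons covered by the fragment (default 1:4).
#' @return A \code{ratio_estimate} for the oxidative fraction f.
#' @export
oaa_from_tca_fraction <- function(asp_mdv, net, v, tracer, carbons = 1:4) {
  carbons <- sort(carbons)
  # oxidative: OAA[i] = 2OG[i + 1]
  ox <- emu_mdv(net, v, tracer, "OG", carbons + 1L)
  # anaplerotic: OAA C1-C3 from PEP C1-C3, C4 from the CO2 pool
  pep_part <- intersect(carbons, 1:3)
  parts <- list()
  if (length(pep_part)) parts <- c(parts, list(emu_mdv(net, v, tracer, "PEP", pep_part)))
  if (4 %in% carbons) parts <- c(parts, list(emu_mdv(net, v, tracer, "CO2", 1L)))
  an <- Reduce(convolve_full, parts)
  if (length(asp_mdv) != length(carbons) + 1) {
    stop("aspartate MDV length does not match the fragment carbon set")
  }
  mixture_ratio(asp_mdv, ox, an, branch = "OAA_from_TCA")
}

#' Fraction of serine C3 supplied by one-carbon metabolism
#'
#' Under a 13C-formate tracer, label at serine C3 can only come from the
#' formate-derived methylene-THF one-carbon unit; the fraction of serine
#' drawing C3 from the one-carbon pool is the observed C3 labeled fraction
#' divided by the enrichment of the one-carbon donor.
#'
#' @param c3_labeled_fraction Fraction of serine labeled at C3.
#' @param formate_enrichment 13C enrichment of the formate-derived donor.
#' @return A \code{ratio_estimate}.
#' @export
serine_one_carbon_fraction <- function(c3_labeled_fraction, formate_enrichment) {
  if (formate_enrichment <= 0) stop("formate enrichment must be > 0")
  if (c3_labeled_fraction < 0 || c3_labeled_fraction > 1 ||
      formate_enrichment > 1) {
    stop("fractions must lie in [0, 1]")
  }
  f <- min(max(c3_labeled_fraction / formate_enrichment, 0), 1)
  structure(list(value = f, residual = 0, branch = "serine_one_carbon"),
            class = "ratio_estimate")
}

#' Citramalate vs threonine route to isoleucine
#'
#' Joint constrained mixture fit over a concatenated isoleucine fragment
#' pair (full skeleton and lacking C1). The citramalate route leaves a
#' single label confined to C1 (present in the full fragment, absent from
#' the C1-lacking fragment); the threonine route labels additional
#' positions.
#'
#' @param full_fragment Observed MDV of the full-skeleton fragment.
#' @param minus_c1_fragment Observed MDV of the fragment lacking C1.
#' @param predicted_citramalate List of the two predicted MDVs (full,
#'   minus-C1) if all isoleucine derives from the citramalate route.
#' @param predicted_threonine Same pair for the threonine route.
#' @return A \code{ratio_estimate} for the citramalate fraction.
#' @export
ile_citramalate_fraction <- function(full_fragment, minus_c1_fragment,
                                     predicted_citramalate,
                                     predicted_threonine) {
  obs <- c(full_fragment, minus_c1_fragment)
  a <- c(predicted_citramalate[[1]], predicted_citramalate[[2]])
  b <- c(predicted_threonine[[1]], predicted_threonine[[2]])
  mixture_ratio(obs, a, b, branch = "ile_citramalate")
}

#' Citrate synthase stereospecificity report
#'
#' Under 13C-bicarbonate labeling, both carboxyl carbons of oxaloacetate
#' become labeled (C1 via reversed PFOR and PPDK back-flux, C4 via PEP
#' carboxylase). Si-citrate synthase propagates the OAA C4 label to
#' glutamate C1 (read out as m1 of the C1-C2 fragment); Re-citrate synthase
#' propagates it to glutamate C5 (m1 of the C2-C5 fragment).
#'
#' @param glu_1_2 Corrected MDV of the glutamate C1-C2 fragment.
#' @param glu_2_5 Corrected MDV of the glutamate C2-C5 fragment.
#' @param threshold Labeled-fraction evidence threshold (default 0.10).
#' @return A \code{stereo_report}: labeled fractions and a classification
#'   in \{Re-only, Si-only, both, neither\}.
#' @export
citrate_synthase_stereo <- function(glu_1_2, glu_2_5, threshold = 0.10) {
  c1_evidence <- glu_1_2[2]
  c5_evidence <- glu_2_5[2]
  si <- c1_evidence >= threshold
  re <- c5_evidence >= threshold
  classification <- if (si && re) "both" else if (re) "Re-only" else
    if (si) "Si-only" else "neither"
  structure(list(c1_labeled_fraction = c1_evidence,
                 c5_labeled_fraction = c5_evidence,
                 classification = classification, threshold = threshold),
            class = "stereo_report")
}

#' @export
print.stereo_report <- function(x, ...) {
  cat(sprintf(paste0("<stereo_report> %s (C1 evidence %.3f, C5 evidence ",
                     "%.3f, threshold %.2f)\n"),
              x$classification, x$c1_labeled_fraction,
              x$c5_labeled_fraction, x$threshold))
  invisible(x)
}

#' Entner-Doudoroff pathway diagnostic
#'
#' Under [1-13C] glucose, ED-pathway flux labels pyruvate (hence alanine)
#' at C1, while EMP flux labels C3. The fragment pair (full skeleton vs
#' lacking C1) attributes alanine m1 to the two positions: C1 evidence is
#' the excess of full-fragment m1 over the minus-C1 fragment m1.
#'
#' @param ala_full MDV of the full alanine fragment (C1-C3).
#' @param ala_minus_c1 MDV of the alanine fragment lacking C1 (C2-C3).
#' @param threshold Evidence threshold on C1 labeling.
#' @return List with C1/C3 labeling evidence and the qualitative verdict
#'   \code{ed_active}.
#' @export
ed_pathway_report <- function(ala_full, ala_minus_c1, threshold = 0.05) {
  c1 <- max(ala_full[2] - ala_minus_c1[2], 0)
  c3 <- ala_minus_c1[2]
  list(c1_labeling = c1, c3_labeling = c3, threshold = threshold,
       ed_active = c1 >= threshold)
}
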