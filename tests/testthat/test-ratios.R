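test_that("mixture fit recovers the weight, matching a grid-search oracle", {
  a <- c(0.5, 0.5, 0, 0)
  b <- c(1, 0, 0, 0)
  expect_equal(mixture_ratio(a, a, b)$value, 1)
  expect_equal(mixture_ratio(b, a, b)$value, 0)

  obs <- 0.62 * a + 0.38 * b
  est <- mixture_ratio(obs, a, b)
  # independent oracle: dense grid search over f
  grid <- seq(0, 1, by = 0.001)
  sse <- vapply(grid, function(f) sum((obs - f * a - (1 - f) * b)^2), 0)
  expect_equal(est$value, grid[which.min(sse)], tolerance = 1e-3)
  expect_equal(est$value, 0.62, tolerance = 1e-12)
  expect_lt(est$residual, 1e-12)

  expect_error(mixture_ratio(obs, a, a), "unidentifiable")
})

test_that("noisy mixture estimates recover the weight within the stated error", {
  a <- c(0.5, 0.5, 0, 0)
  b <- c(1, 0, 0, 0)
  set.seed(31)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    errs <- replicate(200, {
      obs <- f * a + (1 - f) * b + stats::rnorm(4, 0, 0.005)
      abs(mixture_ratio(obs, a, b)$value - f)
    })
    expect_lt(mean(errs), 0.03)
  }
})

test_that("serine EMP fraction equals twice m1 and is exact on simulated EMP serine", {
  expect_equal(serine_emp_fraction(c(0.5, 0.5, 0, 0))$value, 1)
  expect_equal(serine_emp_fraction(c(1, 0, 0, 0))$value, 0)
  expect_equal(serine_emp_fraction(c(0.69, 0.31, 0, 0))$value, 0.62,
               tolerance = 1e-12)
  expect_warning(est <- serine_emp_fraction(c(0.3, 0.7, 0, 0)), "flagged")
  expect_true(isTRUE(attr(est, "inconsistent")))

  nets <- toys()
  v <- make_ground_truth(nets$emp_serine, seed = 3, fixed = c(UPT = 100))
  ser <- emu_mdv(nets$emp_serine, v, tracer_1c(), "SER")
  expect_equal(serine_emp_fraction(ser)$value, 1)
})

test_that("the OAA-from-TCA estimator returns ~0 on the incomplete-TCA network", {
  net <- ct_network()
  v <- ct_reference_fluxes(net)
  tr <- tracer_u20()
  asp <- emu_mdv(net, v, tr, "ASP")
  est <- oaa_from_tca_fraction(asp, net, v, tr)
  expect_lt(est$value, 0.01)

  # endmember sanity: observed == endmember recovers the corners
  ox <- emu_mdv(net, v, tr, "OG", 2:5)
  an <- emuflux:::convolve_full(emu_mdv(net, v, tr, "PEP", 1:3),
                                emu_mdv(net, v, tr, "CO2", 1L))
  expect_equal(oaa_from_tca_fraction(an, net, v, tr)$value, 0)
  expect_equal(oaa_from_tca_fraction(ox, net, v, tr)$value, 1)
})

test_that("the OAA-from-TCA estimator tracks a known oxidative flux", {
  net2 <- ct_network("tca_added")
  truth <- ct_reference_fluxes(net2, extra = c(
    OGOAA = 5, ICTDH = 6.1, ACO = 6.1, CS_SI = 3.05, CS_RE = 3.05,
    PTA = 60, CO2OUT = 130.1))
  f_true <- truth$net[["OGOAA"]] /
    (truth$net[["OGOAA"]] + truth$net[["PEPC"]])
  tr <- tracer_u20()
  asp <- emu_mdv(net2, truth, tr, "ASP")
  est <- oaa_from_tca_fraction(asp, net2, truth, tr)
  expect_lt(abs(est$value - f_true), 0.05)
})

test_that("serine one-carbon fraction is the enrichment-normalized C3 labeling", {
  expect_equal(serine_one_carbon_fraction(0, 1.0)$value, 0)
  expect_equal(serine_one_carbon_fraction(0.25, 1.0)$value, 0.25)
  expect_equal(serine_one_carbon_fraction(0.20, 0.80)$value, 0.25)
  expect_error(serine_one_carbon_fraction(0.2, 0), "> 0")
})

test_that("isoleucine route discrimination favors citramalate on the reference regime", {
  net <- ct_network()
  tr <- ct_tracer("bicarbonate_13c")
  base <- ct_reference_fluxes(net)
  base$exchange <- c(PFOR = 60, PPDK = 60)

  frags <- list(full = 1:6, m85 = 2:6)
  sim_pair <- function(v) {
    lapply(frags, function(a) emu_mdv(net, v, tr, "ILE", a))
  }
  # route-pure endmember regimes
  v_cit <- ct_reference_fluxes(net, extra = c(CIMS = 4, THRDA = 0,
                                              THRS = 5, ASPS = 5.6))
  v_thr <- ct_reference_fluxes(net, extra = c(CIMS = 0, THRDA = 4,
                                              THRS = 9, ASPS = 9.6))
  v_cit$exchange <- v_thr$exchange <- c(PFOR = 60, PPDK = 60)
  pred_cit <- sim_pair(v_cit)
  pred_thr <- sim_pair(v_thr)

  expect_equal(ile_citramalate_fraction(pred_cit$full, pred_cit$m85,
                                        pred_cit, pred_thr)$value, 1)
  expect_equal(ile_citramalate_fraction(pred_thr$full, pred_thr$m85,
                                        pred_cit, pred_thr)$value, 0)

  # default regime is citramalate-dominant (90%): the label sits on C1
  obs <- sim_pair(base)
  est <- ile_citramalate_fraction(obs$full, obs$m85, pred_cit, pred_thr)
  expect_gt(est$value, 0.8)
  # citramalate signature: label present in the full fragment, scarce in
  # the C1-lacking fragment
  expect_gt(obs$full[2], obs$m85[2])
})

test_that("stereo classification thresholds the two glutamate fragment signals", {
  r <- citrate_synthase_stereo(c(0.72, 0.28, 0), c(0.74, 0.26, 0, 0, 0))
  expect_equal(r$classification, "both")
  expect_equal(citrate_synthase_stereo(c(1, 0, 0), c(0.7, 0.3, 0, 0, 0))$classification,
               "Re-only")
  expect_equal(citrate_synthase_stereo(c(1, 0, 0), c(1, 0, 0, 0, 0))$classification,
               "neither")
  expect_equal(citrate_synthase_stereo(c(0.7, 0.3, 0), c(1, 0, 0, 0, 0))$classification,
               "Si-only")
})

test_that("simulated stereo-pure regimes label the expected glutamate fragment", {
  net <- ct_network()
  tr <- ct_tracer("bicarbonate_13c")
  # boost CO2 pool enrichment so the signal is well above threshold
  si_only <- ct_reference_fluxes(net, extra = c(
    CS_SI = 1.1, CS_RE = 0, CO2IN = 100, CO2OUT = 195))
  re_only <- ct_reference_fluxes(net, extra = c(
    CS_SI = 0, CS_RE = 1.1, CO2IN = 100, CO2OUT = 195))
  si_only$exchange <- re_only$exchange <- c(PFOR = 60, PPDK = 60)
  g <- function(v, atoms) emu_mdv(net, v, tr, "GLU", atoms)
  r_si <- citrate_synthase_stereo(g(si_only, 1:2), g(si_only, 2:5))
  r_re <- citrate_synthase_stereo(g(re_only, 1:2), g(re_only, 2:5))
  expect_equal(r_si$classification, "Si-only")
  expect_equal(r_re$classification, "Re-only")
})

test_that("the ED diagnostic sees no C1 labeling from EMP-only glycolysis", {
  net <- ct_network()
  v <- ct_reference_fluxes(net)
  tr <- tracer_1c()
  rep <- ed_pathway_report(emu_mdv(net, v, tr, "ALA", 1:3),
                           emu_mdv(net, v, tr, "ALA", 2:3))
  expect_false(rep$ed_active)
  expect_lt(rep$c1_labeling, 0.01)
  expect_gt(rep$c3_labeling, 0.3)
})
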