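test_that("GHK anion reversal reproduces known limits and the recording prediction", {
  # published pipette/bath recipe: 29 mM Cl in, 136.5 out, 16/26 HCO3, 4:1
  expect_close(ghk_anion_reversal(), -37, 1)
  # single-ion limit reduces to the chloride Nernst potential
  expect_close(ghk_anion_reversal(perm_ratio_cl_to_hco3 = Inf),
               nernst(29, 136.5), 1e-9)
  # symmetric concentrations give 0 mV
  expect_equal(ghk_anion_reversal(cl_in = 100, cl_out = 100,
                                  hco3_in = 20, hco3_out = 20), 0)
  expect_error(ghk_anion_reversal(cl_in = -1), "concentrations")
})

test_that("I-V reversal extrapolation is exact on a line and unbiased under noise", {
  v <- seq(-80, -10, by = 10)
  expect_close(reversal_from_iv(v, 2 * (v + 40)), -40, 1e-9)
  set.seed(11)
  est <- replicate(500, reversal_from_iv(v, 2 * (v + 40) + rnorm(length(v), 0, 5)))
  expect_close(mean(est), -40, 0.5)
  expect_error(reversal_from_iv(c(-60, -40), c(-1, 1)), "at least 3")
  expect_error(reversal_from_iv(v, rep(1, length(v))), "degenerate")
})

test_that("equilibrium E_Cl is the conductance-weighted mean", {
  p <- anion_params()
  expect_equal(equilibrium_ecl(0, 0.81, p), p$e_k)
  expect_close(equilibrium_ecl(1, 1e-12, p), p$v_mean, 1e-9)
  expect_close(equilibrium_ecl(1, 0.81, anion_params(e_k = -95)), -75.66, 0.01)
  expect_error(equilibrium_ecl(0, 0, p), "both")
})

test_that("anion current obeys its decomposition identities", {
  p <- anion_params()
  z <- anion_current(0, 0.81, p)
  expect_equal(z$i_anion, 0)
  expect_equal(z$i_cl, 0)
  set.seed(3)
  for (i in 1:20) {
    pp <- anion_params(x = runif(1, 0.5, 0.95), e_k = runif(1, -100, -70),
                       e_hco3 = runif(1, -30, -5))
    g <- runif(1, 0.1, 5); m <- runif(1, 0.2, 2)
    r <- anion_current(g, m, pp)
    expect_close(r$i_anion, r$i_cl + r$i_hco3, 1e-9)
    expect_close(r$g_cl + r$g_hco3, g, 1e-9)
  }
  # zero driving force: choose v_eff equal to the weighted reversal
  r0 <- anion_current(1, 0.81, p)
  p2 <- anion_params(v_eff = r0$e_anion)
  expect_close(anion_current(1, 0.81, p2)$i_anion, 0, 1e-9)
})

test_that("kcc2 flux is linear and vanishes at E_Cl = E_K", {
  expect_equal(kcc2_flux(-80, -80, 3)$flux, 0)
  expect_gt(kcc2_flux(-70, -90, 1)$flux, 0)
  expect_lt(kcc2_flux(-95, -90, 1)$flux, 0)
  expect_close(kcc2_flux(-70, -90, 2)$flux, 2 * kcc2_flux(-70, -90, 1)$flux, 1e-12)
})

test_that("relative current change matches a direct grid computation", {
  p <- anion_params()
  expect_equal(delta_anion_current(0, 0, p), 0)
  expect_gt(delta_anion_current(0, 0.3, p), 0)  # more extrusion helps
  base <- anion_current(1, 0.81, p)$i_anion
  for (dgi in c(-0.5, 0, 0.8, 2)) for (dgk in c(0, 0.4, 1)) {
    brute <- 100 * (anion_current(1 + dgi, 0.81 * (1 + dgk), p)$i_anion / base - 1)
    expect_close(delta_anion_current(dgi, dgk, p), brute, 1e-9)
  }
})

test_that("optimal conductance matches the closed-form stationary point", {
  # worked rational-form case: alpha = -1, beta = 16.183, m = 0.81
  # corresponds to g* = 2.90 and a 23.8% maximal increase over g = 1
  ifun <- function(g, a, b, m) g * (a * g + b) / (g + m)
  g_star <- -0.81 + sqrt(0.81 * (0.81 + 16.183))
  expect_close(g_star, 2.90, 0.005)
  expect_close(ifun(g_star, -1, 16.183, 0.81) / ifun(1, -1, 16.183, 0.81),
               1.238, 0.001)
  # numeric optimizer equals closed form over random collapse-regime params
  set.seed(5)
  for (i in 1:25) {
    pp <- anion_params(x = runif(1, 0.6, 0.95),
                       e_k = runif(1, -110, -80),
                       e_hco3 = runif(1, -35, -25),
                       g_kcc2_base = runif(1, 0.3, 1.5))
    cf <- gabakcc2:::anion_current_coeffs(pp)
    if (cf$alpha >= 0) next
    opt <- optimal_conductance(pp)
    expect_close(opt$g_star, opt$g_star_closed_form, 1e-5)
  }
})

test_that("KCC2 enhancement shifts the collapse optimum rightward", {
  cal <- calibrated_model()
  c1 <- collapse_curve(kcc2_scale = 1, params = cal$params)
  c14 <- collapse_curve(kcc2_scale = 1.4, params = cal$params)
  peak1 <- c1$g_inh[which.max(c1$i_anion)]
  peak14 <- c14$g_inh[which.max(c14$i_anion)]
  expect_gt(peak1, min(c1$g_inh)); expect_lt(peak1, max(c1$g_inh))
  expect_gt(peak14, peak1)
  # and monotonically so, over a scale sweep (collapse prevention)
  peaks <- vapply(seq(0.8, 2, by = 0.2), function(s)
    optimal_conductance(cal$params, cal$params$g_kcc2_base * s)$g_star,
    numeric(1))
  expect_true(all(diff(peaks) > 0))
  # linearity in overall current units
  expect_equal(collapse_curve(params = cal$params)$i_anion * 2,
               {
                 p2 <- cal$params
                 collapse_curve(params = p2)$i_anion * 2
               })
})

test_that("effect relation calibration solves the two anchors exactly", {
  eff <- calibrate_effect(list(c(26, 25), c(67, 42)), offset = 6)
  expect_close(eff$curhalf, 50.8, 0.05)
  expect_close(eff$max_effect, 73.9, 0.1)
  expect_close(effect_of_current(26, eff), 25, 1e-9)
  expect_close(effect_of_current(67, eff), 42, 1e-9)
  expect_equal(effect_of_current(0, eff), 0)
  # strictly increasing, bounded by Max
  di <- seq(0, 500, by = 5)
  e <- effect_of_current(di, eff)
  expect_true(all(diff(e) > 0))
  expect_true(all(e < eff$max_effect))
  expect_error(calibrate_effect(list(c(26, 25))), "two anchors")
})

test_that("linear current inversion reproduces the published anchor arithmetic", {
  expect_close(linear_current_for_effect(19), 19.8, 0.05)
  expect_equal(linear_current_for_effect(25), 26)
  expect_equal(linear_current_for_effect(0), 0)
})

test_that("anion-constant calibration recovers a known truth and reports the over-determined residual", {
  # self-consistency: anchors generated from known constants
  truth <- anion_params(x = 0.75, e_k = -92, e_hco3 = -20)
  base <- anion_current(1, truth$g_kcc2_base, truth)
  e_anion <- truth$x * base$e_cl + (1 - truth$x) * truth$e_hco3
  opt <- optimal_conductance(truth)
  # generate the current anchor from the closed-form stationary point so the
  # anchor itself carries no optimizer error
  di_true <- 100 * (anion_current(opt$g_star_closed_form, truth$g_kcc2_base,
                                  truth)$i_anion / base$i_anion - 1)
  cal <- calibrate_anion_constants(e_anion, opt$g_star_closed_form - 1,
                                   di_true, x = 0.75)
  expect_close(cal$params$e_k, truth$e_k, 1e-6)
  expect_close(cal$params$e_hco3, truth$e_hco3, 1e-6)
  expect_true(all(abs(cal$residuals) < 1e-8))
  # published anchors: e_anion and g* fit exactly, the 26% anchor cannot be
  # met (attainable ~23.8%), and the residual says so
  cal2 <- calibrate_anion_constants(-65, 1.9, 26, x = 0.8)
  expect_close(cal2$residuals[["e_anion"]], 0, 1e-8)
  expect_close(cal2$residuals[["g_star"]], 0, 1e-8)
  expect_close(cal2$residuals[["di_star"]], 23.8 - 26, 0.1)
})

test_that("effector maps close the round trip and are monotone", {
  cal <- calibrated_model()
  maps <- effector_maps(hill_a_true, hill_b_true, cal$effect, cal$params)
  expect_equal(maps$dg_inh(0), 0)
  expect_equal(maps$dg_kcc2(0), 0)
  # round trip: forward model through the mapped conductance change
  # reproduces the offset-corrected experimental effect
  for (d in c(0.2, 0.5, 1, 3)) {
    target <- hill_response(d, hill_a_true) - hill_a_true$y0
    di <- delta_anion_current(maps$dg_inh(d), 0, cal$params)
    expect_close(effect_of_current(di, cal$effect), target, 1e-6)
  }
  for (d in c(5, 20, 60, 120)) {
    target <- hill_response(d, hill_b_true) - hill_b_true$y0
    di <- delta_anion_current(0, maps$dg_kcc2(d), cal$params)
    expect_close(effect_of_current(di, cal$effect), target, 1e-6)
  }
  # monotone on domain
  da <- seq(0, min(maps$dose_max_a, 5), length.out = 20)
  expect_true(all(diff(maps$dg_inh(da)) > -1e-12))
  db <- seq(0, 140, length.out = 20)
  expect_true(all(diff(maps$dg_kcc2(db)) > -1e-12))
  # outside the invertible domain the map is masked
  expect_true(is.na(maps$dg_inh(maps$dose_max_a * 1.01)))
})

test_that("equivalent-dose transform closes through the common effector", {
  cal <- calibrated_model()
  maps <- effector_maps(hill_a_true, hill_b_true, cal$effect, cal$params)
  expect_equal(current_equivalent_dose(0, maps), 0)
  doses <- c(10, 40, 80)
  eq <- current_equivalent_dose(doses, maps)
  expect_true(all(diff(eq) > 0))
  for (i in seq_along(doses)) {
    di_b <- delta_anion_current(0, maps$dg_kcc2(doses[i]), cal$params)
    di_a <- delta_anion_current(maps$dg_inh(eq[i]), 0, cal$params)
    expect_close(di_a, di_b, 1e-6)
  }
})

test_that("distinct-effector surface dominates the common-effector surface", {
  cal <- calibrated_model()
  maps <- effector_maps(hill_a_true, hill_b_true, cal$effect, cal$params)
  surf <- combination_surfaces(seq(0, 3, length.out = 9),
                               seq(0, 90, length.out = 9), maps)
  # single-drug edge: both reduce to the a-alone curve
  edge <- vapply(surf$dose_a, function(a) {
    di <- delta_anion_current(maps$dg_inh(a), 0, cal$params)
    effect_of_current(di, cal$effect)
  }, numeric(1))
  expect_equal(surf$common[, 1], edge, tolerance = 1e-9)
  expect_equal(surf$distinct[, 1], edge, tolerance = 1e-9)
  # interior dominance (qualitative synergy of the distinct mechanism)
  interior <- surf$distinct[-1, -1] - surf$common[-1, -1]
  expect_true(all(interior > 0, na.rm = TRUE))
  # spot check against hand composition
  a <- surf$dose_a[5]; b <- surf$dose_b[5]
  di <- delta_anion_current(maps$dg_inh(a), maps$dg_kcc2(b), cal$params)
  expect_close(surf$distinct[5, 5], effect_of_current(di, cal$effect), 1e-9)
})
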