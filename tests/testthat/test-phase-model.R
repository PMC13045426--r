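test_that("electrostatic amplitude scales as lambda^2 and matches the Bessel quadrature oracle", {
  expect_equal(electrostatic_amplitude(0, 0.7, 0.3, 3.9), 0)
  a1 <- electrostatic_amplitude(1.5, 0.7, 0.3, 3.9)
  expect_equal(electrostatic_amplitude(3.0, 0.7, 0.3, 3.9), 4 * a1,
               tolerance = 1e-12)
  # closed-form arithmetic with K1 from its integral representation
  expected <- 8 * pi * 3^2 * 0.7 * exp(-0.3 * 3.9) /
    (0.3^3 * 3.9^2 * k1_oracle(0.3 * 3.9 / 2)^2)
  expect_equal(electrostatic_amplitude(3, 0.7, 0.3, 3.9), expected,
               tolerance = 1e-8)
})

test_that("effective diameter bracket root, clamp and arithmetic behave as specified", {
  # the amplitude that zeroes the logarithmic bracket leaves D_eff = D
  a_root <- exp(0.5 - 0.5772156649015329 - log(2))
  expect_equal(effective_diameter(3.9, 0.5, a_root), 3.9, tolerance = 1e-12)
  # below the root the clamp engages
  expect_equal(effective_diameter(3.9, 0.5, a_root / 10), 3.9)
  # direct arithmetic case
  expect_equal(effective_diameter(3.9, 1 / 3.05, 50),
               3.9 + 3.05 * (log(50) + 0.5772156649015329 + log(2) - 0.5),
               tolerance = 1e-12)
  expect_warning(effective_diameter(3.9, 0.5, 0), "neutral")
})

test_that("twisting factor and the composite prefactor are consistent", {
  expect_equal(twisting_factor(1, 1), 1)
  # the kappa * D_eff at which the composite prefactor reaches 3.659
  kde <- 0.75 / (1 - 3.290 / 3.659)
  expect_equal(kde, 7.437, tolerance = 1e-3)
  h <- twisting_factor(kde, 1)
  expect_equal(h, 0.1344, tolerance = 1e-3)
  expect_equal(3.290 / (1 - 0.75 * h), 3.659, tolerance = 1e-6)
  # h falls as screening strengthens at fixed D_eff
  expect_true(all(diff(twisting_factor(seq(0.1, 2, by = 0.1), 10)) < 0))
})

test_that("threshold volume fraction recovers the hard-rod limit and its monotonicities", {
  geom <- lys_geom()
  hard <- structure(list(A_prime = 0, D_eff = geom$D, h = 0,
                         C_E = 0.5772156649, prefactor = 3.290,
                         kappa = 1, b0 = 3.290),
                    class = "electrostatic_rod_params")
  expect_equal(threshold_volume_fraction(geom, hard),
               3.290 * geom$D / geom$L, tolerance = 1e-12)

  # larger effective diameter lowers the threshold; larger twist raises it
  mk <- function(D_eff, h) structure(
    list(A_prime = 1, D_eff = D_eff, h = h, C_E = 0.5772156649,
         prefactor = 3.290 / (1 - 0.75 * h), kappa = 1, b0 = 3.290),
    class = "electrostatic_rod_params")
  phis_d <- vapply(seq(4, 14, by = 2),
                   function(de) threshold_volume_fraction(geom, mk(de, 0.1)),
                   numeric(1))
  expect_true(all(diff(phis_d) < 0))
  phis_h <- vapply(seq(0, 1.2, by = 0.2),
                   function(h) threshold_volume_fraction(geom, mk(10, h)),
                   numeric(1))
  expect_true(all(diff(phis_h) > 0))
  expect_error(threshold_volume_fraction(geom, mk(10, 1.4)), "4/3")
})

test_that("volume fraction and weight percent convert exactly both ways", {
  expect_equal(wt_from_volume_fraction(0), 0)
  expect_equal(wt_from_volume_fraction(1), 100)
  # 1 percent volume at the default densities
  expect_equal(wt_from_volume_fraction(0.01), 100 * 0.013 / (0.013 + 0.99),
               tolerance = 1e-12)
  expect_equal(round(wt_from_volume_fraction(0.01), 3), 1.296)
  phi <- seq(0, 1, by = 0.05)
  expect_equal(volume_fraction_from_wt(wt_from_volume_fraction(phi)), phi,
               tolerance = 1e-12)
  expect_error(wt_from_volume_fraction(1.2), "0, 1")
  expect_error(volume_fraction_from_wt(-5), "0, 100")
})

test_that("predicted threshold concentration increases with internal ionic strength", {
  geom <- lys_geom()
  Is <- 10^seq(-2, -0.3, length.out = 15)
  cs <- vapply(Is, function(I) {
    cond <- solution_conditions(2, I_in = I)
    predict_threshold_concentration(geom, 3.0, cond)$c_IN_wt
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("the hard-rod limit of the prediction chain matches Onsager", {
  geom <- lys_geom()
  cond <- solution_conditions(2, I_in = 0.02)
  pred <- suppressWarnings(predict_threshold_concentration(geom, 0, cond))
  phi_hard <- 3.290 / (1 - 0.75 / (cond$kappa * geom$D)) * geom$D / geom$L
  expect_equal(pred$phi_IN, phi_hard, tolerance = 1e-12)
  expect_equal(pred$D_eff_nm, geom$D)
})

test_that("Donnan solver round-trips a threshold generated at known internal ionic strength", {
  geom <- lys_geom()
  cond <- solution_conditions(2)
  I_star <- 0.05
  c_obs <- predict_threshold_concentration(
    geom, 3.0, solution_conditions(2, I_in = I_star))$c_IN_wt
  sol <- solve_internal_ionic_strength(c_obs, geom, 3.0, cond)
  expect_equal(sol$I_in, I_star, tolerance = 1e-5)
  expect_lt(abs(sol$prediction$c_IN_wt - c_obs) / c_obs, 1e-6)
  # an unreachable observation reports the achievable interval
  expect_error(solve_internal_ionic_strength(1e-4, geom, 3.0, cond),
               "achievable")
})

test_that("regime classification follows the charge and concentration thresholds", {
  expect_equal(classify_regime(3, 1.0, c_IN = 1.49), "isotropic")
  expect_equal(classify_regime(3, 2.0, c_IN = 1.49), "LLCPS")
  expect_equal(classify_regime(0.9, 1.0, c_IN = 1.49, c_onset = 0.5), "LLPS")
  expect_equal(classify_regime(c(3, 3, 0.9), c(1, 2, 1), c_IN = 1.49,
                               c_onset = 0.5),
               c("isotropic", "LLCPS", "LLPS"))
})

test_that("phase-diagram assembly solves every row of the observed transition set", {
  geom <- lys_geom()
  obs <- tibble::tibble(pH = c(2, 3, 4, 5, 6, 7),
                        c_mean = c(1.49, 0.97, 0.90, 0.83, 0.68, 0.58))
  lam <- tibble::tibble(pH = c(2, 3, 4, 5, 6, 7),
                        lambda = c(3.0, 2.6, 2.2, 1.9, 1.5, 1.17))
  pd <- build_phase_diagram(obs, lam, geom)
  expect_equal(nrow(pd), 6)
  expect_true(all(pd$status == "ok"))
  # the solved internal ionic strength varies monotonically with pH
  expect_true(all(diff(pd$I_in_M) < 0))
  # Donnan retention: internal never below nominal
  expect_true(all(pd$I_in_M >= pd$I_nom_M))
  # the matched rows sit in the demixed regime
  expect_true(all(pd$regime == "LLCPS"))
  # the matched concentration is reproduced
  expect_equal(pd$c_IN_wt, pd$c_mean, tolerance = 1e-6)

  # single-row input gives a fully populated single row
  pd1 <- build_phase_diagram(obs[1, ], lam, geom)
  expect_equal(nrow(pd1), 1)
  expect_false(anyNA(pd1$prefactor))
  # a row with an unreachable observation is flagged, not fatal
  bad <- tibble::tibble(pH = c(2, 3), c_mean = c(1e-5, 0.97))
  pd_bad <- build_phase_diagram(bad, lam, geom)
  expect_match(pd_bad$status[1], "no solution")
  expect_equal(pd_bad$status[2], "ok")
})

test_that("generated phase observations recover the generating internal ionic strengths", {
  geom <- lys_geom()
  lam_tbl <- tibble::tibble(pH = c(2, 4, 6), lambda = c(3.0, 2.2, 1.5))
  iin_tbl <- tibble::tibble(pH = c(2, 4, 6), I_in = c(0.02, 0.006, 0.0026))
  obs <- sim_phase_observations(geom, lam_tbl, iin_tbl, pH_grid = c(2, 4, 6),
                                c_grid = seq(0.05, 3, by = 0.005),
                                jitter = 0, seed = 9)
  thr <- attr(obs, "thresholds")
  starts <- extract_start_concentrations(obs)
  # extracted windows bracket the generating thresholds
  expect_true(all(starts$c_min >= thr$c_IN - 1e-9))
  expect_true(all(starts$c_min - 0.005 <= thr$c_IN + 1e-9))
  lam_fn <- smooth_charge_vs_ph(lam_tbl)
  solved <- vapply(seq_len(nrow(starts)), function(i) {
    solve_internal_ionic_strength(
      starts$c_mean[i], geom, lam_fn(starts$pH[i]),
      solution_conditions(starts$pH[i]))$I_in
  }, numeric(1))
  expect_equal(solved, iin_tbl$I_in, tolerance = 0.05)
})
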