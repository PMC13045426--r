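test_that("Henry factor interpolates between the cylinder limits and is monotone", {
  expect_equal(henry_factor_cylinder(1e-9), 0.5, tolerance = 1e-6)
  expect_equal(henry_factor_cylinder(1e9), 1, tolerance = 1e-6)
  grid <- 10^seq(-3, 4, length.out = 200)
  expect_true(all(diff(henry_factor_cylinder(grid)) > 0))
  # frozen value of the adopted closed form at kappa_a = 1
  expect_equal(henry_factor_cylinder(1),
               0.5 * (1 + 1 / (1 + 2.55 / (1 + exp(-1)))^2),
               tolerance = 1e-12)
})

test_that("mobility-potential relation is linear and round-trips through the forward model", {
  cond <- solution_conditions(2, I_nom = 0.0157)  # kappa D/2 ~ 2 for D = 3.9
  D <- 3.9
  expect_equal(mobility_to_surface_potential(0, D, cond), 0)
  # linearity
  p1 <- mobility_to_surface_potential(1.3, D, cond)
  expect_equal(mobility_to_surface_potential(2.6, D, cond), 2 * p1,
               tolerance = 1e-12)
  # forward-model a 25 mV rod with the orientation-averaged Henry
  # expression written out independently, then invert
  f <- (1 + 2 * henry_factor_cylinder(cond$kappa * D / 2)) / 3
  mob <- (orc$eps0 * cond$eps_r * 25e-3 * f / 0.933e-3) / 1e-8
  expect_equal(mobility_to_surface_potential(mob, D, cond), 25,
               tolerance = 1e-12)
})

test_that("nonlinear PB charge agrees with the Debye-Hueckel Bessel-quotient oracle at low potential", {
  D <- 3.9
  cond <- solution_conditions(2, I_nom = 0.00628)  # kappa D/2 ~ 1
  ka <- cond$kappa * D / 2
  lam_dh_oracle <- function(psi_mV) {
    pi * D * orc$eps0 * cond$eps_r * (cond$kappa * 1e9) * (psi_mV * 1e-3) /
      orc$e * k1_oracle(ka) / k0_oracle(ka) * 1e-18
  }
  for (psi in c(1, 2, 5)) {
    cs <- surface_potential_to_linear_charge(psi, D, cond)
    expect_equal(cs$lambda, lam_dh_oracle(psi), tolerance = 0.01)
  }
  # zero potential -> neutral rod
  expect_equal(surface_potential_to_linear_charge(0, D, cond)$lambda, 0)
  # charge saturation asymmetry: the nonlinear solution needs more charge
  # than the linear theory to sustain a high potential
  cs_hi <- surface_potential_to_linear_charge(100, D, cond)
  expect_gt(abs(cs_hi$lambda), abs(lam_dh_oracle(100)))
  # negative potentials mirror positive ones
  cs_neg <- surface_potential_to_linear_charge(-25, D, cond)
  cs_pos <- surface_potential_to_linear_charge(25, D, cond)
  expect_equal(cs_neg$lambda, -cs_pos$lambda, tolerance = 1e-9)
})

test_that("lambda = pi D sigma identity holds in every charge state", {
  D <- 3.9
  cond <- solution_conditions(3, I_nom = 0.01)
  for (psi in c(-80, -5, 2, 30, 120)) {
    cs <- surface_potential_to_linear_charge(psi, D, cond)
    expect_identical(cs$lambda, pi * D * cs$sigma)
    expect_equal(sign(cs$psi0), sign(cs$lambda))
  }
})

test_that("charge -> mobility -> charge round trip closes within 2 percent", {
  D <- 3.9
  cases <- expand.grid(lambda = c(0.1, 1, 3, 5), ka = c(0.2, 2, 10))
  for (i in seq_len(nrow(cases))) {
    lam <- cases$lambda[i]
    # pick the ionic strength that realizes the target kappa a
    kappa <- cases$ka[i] / (D / 2)
    I <- (kappa / inverse_debye_length(1))^2
    cond <- solution_conditions(3, I_nom = I)
    psi <- fibrilphase:::.linear_charge_to_surface_potential(lam, D, cond)
    mob <- fibrilphase:::.surface_potential_to_mobility(psi, D, cond)
    res <- linear_charge_from_mobility(
      tibble::tibble(pH = 3, I = I, mobility = mob), D)
    expect_equal(res$lambda_e_nm, lam, tolerance = 0.02)
  }
  # zero mobility -> zero charge
  res0 <- linear_charge_from_mobility(
    tibble::tibble(pH = 3, I = 0.01, mobility = 0), D)
  expect_equal(res0$lambda_e_nm, 0)
})

test_that("the synthetic titration forward model recovers its generating charge curve", {
  lam_fn <- function(pH) 3.2 - 0.32 * (pH - 2)   # crosses zero at pH 12
  tbl <- sim_mobility_titration(lam_fn, D = 3.9, pH_grid = c(2, 4, 6),
                                noise = 0, seed = 5)
  res <- linear_charge_from_mobility(tbl, D = 3.9)
  expect_equal(res$lambda_e_nm, res$lambda_true, tolerance = 0.02)
  # determinism
  tbl2 <- sim_mobility_titration(lam_fn, D = 3.9, pH_grid = c(2, 4, 6),
                                 noise = 0, seed = 5)
  expect_identical(tbl, tbl2)
})

test_that("mobility sign change tracks the isoelectric point of the charge curve", {
  lam_fn <- function(pH) 2 * (10 - pH) / 8        # zero at pH 10
  tbl <- sim_mobility_titration(lam_fn, D = 3.9, pH_grid = c(9, 9.5, 10.5, 11),
                                noise = 0, seed = 2)
  expect_true(all(tbl$mobility[tbl$pH < 10] > 0))
  expect_true(all(tbl$mobility[tbl$pH > 10] < 0))
})

test_that("charge-vs-pH interpolant is exact at knots, monotone between them, and validates input", {
  pts <- tibble::tibble(pH = c(2, 3, 5, 7), lambda = c(3.0, 2.6, 1.9, 1.17))
  fn <- smooth_charge_vs_ph(pts)
  expect_equal(fn(pts$pH), pts$lambda, tolerance = 1e-12)
  dense <- fn(seq(2, 7, by = 0.01))
  expect_true(all(diff(dense) <= 1e-12))
  expect_error(smooth_charge_vs_ph(pts[1:2, ]), "three")
  expect_error(smooth_charge_vs_ph(
    tibble::tibble(pH = c(2, 2, 3), lambda = 1:3)), "duplicate")
  expect_error(smooth_charge_vs_ph(
    tibble::tibble(pH = c(3, 2, 4), lambda = 1:3)), "increasing")
})
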