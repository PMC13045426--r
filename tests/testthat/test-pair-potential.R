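test_that("effective line charge satisfies the amplitude identity and its thin-rod limit", {
  # A' = 2 pi lambda_eff^2 Q / kappa across a parameter grid, to machine
  # precision
  grid <- expand.grid(lambda = c(0.5, 1.5, 3), kappa = c(0.1, 0.3, 1),
                      D = c(2, 3.9, 8))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    Q <- 0.7
    le <- effective_line_charge(g$lambda, g$kappa, g$D)
    expect_equal(2 * pi * le^2 * Q / g$kappa,
                 electrostatic_amplitude(g$lambda, Q, g$kappa, g$D),
                 tolerance = 1e-12)
  }
  # kappa D -> 0: the cylinder correction disappears
  expect_equal(effective_line_charge(3, 1e-5, 3.9), 3, tolerance = 1e-4)
  # quadrature oracle for the Bessel factor
  z <- 0.3 * 3.9 / 2
  expect_equal(effective_line_charge(3, 0.3, 3.9),
               3 * exp(-z) / (z * k1_oracle(z)), tolerance = 1e-8)
})

test_that("electrostatic branches are positive, decay with distance, and tie back to the amplitude", {
  geom <- lys_geom()
  cond <- solution_conditions(2, I_in = 0.0195)
  x <- seq(1.2, 12, by = 0.4) * geom$D
  upar <- electrostatic_pair(x, 0, geom$L, geom$D, 3, cond)
  uperp <- electrostatic_pair(x, 90, geom$L, geom$D, 3, cond)
  expect_true(all(upar > 0) && all(uperp > 0))
  expect_true(all(diff(upar) < 0) && all(diff(uperp) < 0))
  # theta = 90 equals A' exp(-kappa x)
  ap <- electrostatic_amplitude(3, cond$Q, cond$kappa, geom$D)
  expect_equal(uperp, ap * exp(-cond$kappa * x), tolerance = 1e-12)
  # neutral rods do not interact
  expect_equal(electrostatic_pair(10, 0, geom$L, geom$D, 0, cond), 0)
  expect_equal(electrostatic_pair(10, 45, geom$L, geom$D, 0, cond), 0)
  # parallel repulsion exceeds crossed repulsion at the nematic spacing
  expect_gt(electrostatic_pair(5.4 * geom$D, 0, geom$L, geom$D, 3, cond),
            electrostatic_pair(5.4 * geom$D, 90, geom$L, geom$D, 3, cond))
})

test_that("van der Waals closed forms obey their scaling laws and sign", {
  D <- 3.9; L <- 370
  expect_equal(vdw_pair(10, 90, D, L, A_H = 0), 0)
  expect_equal(vdw_pair(10, 0, D, L, A_H = 0), 0)
  # crossed form is an exact 1/s law
  u1 <- vdw_pair(D + 2, 90, D, L)
  expect_equal(vdw_pair(D + 4, 90, D, L), u1 / 2, tolerance = 1e-12)
  x <- seq(D + 0.5, D + 40, by = 0.5)
  for (th in c(0, 90)) {
    u <- vdw_pair(x, th, D, L)
    expect_true(all(u < 0))
    expect_true(all(diff(u) > 0))       # rises toward zero
  }
  expect_lt(abs(vdw_pair(D + 1e3, 90, D, L)), 1e-3)
  expect_error(vdw_pair(D, 90, D, L), "overlap")
})

test_that("van der Waals closed forms are the near-contact asymptote of the Hamaker integration", {
  D <- 3.9; R <- D / 2; L <- 370; A_H <- 3
  s_over_R <- c(0.0125, 0.05, 0.2)
  ratio_par <- vapply(s_over_R, function(sr) {
    s <- sr * R
    vdw_pair(s + D, 0, D, L, A_H) / vdw_parallel_oracle(s + D, R, A_H, L)
  }, numeric(1))
  ratio_cross <- vapply(s_over_R, function(sr) {
    s <- sr * R
    vdw_pair(s + D, 90, D, L, A_H) / vdw_crossed_oracle(s + D, R, A_H)
  }, numeric(1))
  # within 5 percent where the near-contact assumption holds ...
  expect_lt(abs(ratio_par[1] - 1), 0.05)
  expect_lt(abs(ratio_cross[1] - 1), 0.05)
  # ... and approaching 1 monotonically from above as s -> 0
  expect_true(all(diff(ratio_par) > 0))
  expect_true(all(diff(ratio_cross) > 0))
  expect_true(all(ratio_par > 1) && all(ratio_cross > 1))
})

test_that("total potential is the exact sum of its parts and vanishes at large separation", {
  geom <- lys_geom()
  cond <- solution_conditions(2, I_in = 0.0195)
  x <- seq(1.5, 10, by = 0.5) * geom$D
  for (th in c(0, 90)) {
    expect_equal(total_pair_potential(x, th, geom, 3, cond),
                 electrostatic_pair(x, th, geom$L, geom$D, 3, cond) +
                   vdw_pair(x, th, geom$D, geom$L, 3),
                 tolerance = 1e-12)
  }
  expect_lt(abs(total_pair_potential(500 * geom$D, 90, geom, 3, cond)), 1e-3)
})

test_that("relative probability is the Boltzmann weight of the orientation energy gap", {
  expect_equal(relative_probability(2.5, 2.5), 1)
  expect_equal(relative_probability(log(100), 0), 0.01, tolerance = 1e-12)
  expect_gt(relative_probability(0, 3), 1)   # parallel favoured
  expect_error(relative_probability(Inf, 0), "finite")
})

test_that("pair-potential curves carry both branches with the documented signs", {
  geom <- lys_geom()
  cond <- solution_conditions(2, I_in = 0.0195)
  curve <- pair_potential_curve(geom, 3, cond)
  expect_s3_class(curve, "fp_pair_curve")
  expect_true(all(curve$U_el_par >= 0) && all(curve$U_el_perp >= 0))
  expect_true(all(curve$U_vdW_par <= 0) && all(curve$U_vdW_perp <= 0))
  expect_equal(curve$P,
               exp(-(curve$U_tot_par - curve$U_tot_perp)),
               tolerance = 1e-12)
  expect_error(pair_potential_curve(geom, 3, cond, x_over_D = c(0.5, 2)),
               "exceed 1")
})

test_that("nematic spacing solver round-trips and responds to screening", {
  geom <- lys_geom()
  cond <- solution_conditions(3, I_in = 0.0075)
  # round trip: target the probability at a known spacing on the outer
  # branch
  x0 <- 4.5
  P0 <- relative_probability(
    total_pair_potential(x0 * geom$D, 0, geom, 2.6, cond),
    total_pair_potential(x0 * geom$D, 90, geom, 2.6, cond))
  expect_equal(solve_nematic_spacing(P0, geom, 2.6, cond), x0,
               tolerance = 1e-3)
  # weaker screening pushes the spacing outward at fixed charge
  xs <- vapply(c(0.008, 0.005, 0.003), function(I) {
    solve_nematic_spacing(0.012, geom, 2.6, solution_conditions(3, I_in = I))
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
  # unreachable target reports failure
  expect_error(solve_nematic_spacing(0.012, geom, 2.6, cond,
                                 bracket = c(8, 50)), "no solution")
})
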