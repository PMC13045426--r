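test_that("cylinder form factor has the forward-scattering limit and rod-like decay", {
  D <- 4; L <- 380
  V <- pi * (D / 2)^2 * L
  # q -> 0: scale * V^2 (background subtracted)
  expect_equal(cylinder_form_factor(1e-8, D, L, scale = 2, background = 0.5),
               2 * V^2 + 0.5, tolerance = 1e-6)
  # intermediate-q envelope ~ 1/q over a decade for L >> D
  q <- 10^seq(log10(0.005), log10(0.05), length.out = 60)
  I <- cylinder_form_factor(q, D, L)
  slope <- coef(stats::lm(log(I) ~ log(q)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
})

test_that("fixed-node orientation average matches an independent adaptive quadrature", {
  D <- 4; L <- 380
  V <- pi * (D / 2)^2 * L
  oracle <- function(qA) {
    qn <- qA * 10
    f <- function(a) {
      za <- qn * (D / 2) * sin(a)
      zl <- qn * (L / 2) * cos(a)
      amp <- ifelse(za < 1e-10, 1, 2 * besselJ(za, 1) / za) *
        ifelse(abs(zl) < 1e-10, 1, sin(zl) / zl)
      amp^2 * sin(a)
    }
    V^2 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-10,
                           subdivisions = 2000)$value
  }
  for (qA in c(0.003, 0.01, 0.03, 0.1)) {
    expect_equal(cylinder_form_factor(qA, D, L), oracle(qA),
                 tolerance = 1e-4)
  }
})

test_that("form-factor fit recovers generating parameters", {
  # noise-free profile: exact self-consistent recovery
  clean <- sim_saxs_profiles(D = 4, L = 380, c_list = 1, noise = 0, seed = 1)
  fit0 <- fit_form_factor(clean)
  expect_equal(fit0$D, 4, tolerance = 1e-4)
  expect_equal(fit0$L, 380, tolerance = 1e-3)
  # 2 percent multiplicative noise, 200 points, fixed seed: D within 5
  # percent, L within 15 percent (weakly constrained at q_min L >> 1)
  noisy <- sim_saxs_profiles(D = 4, L = 380, c_list = 1, noise = 0.02,
                             seed = 42)
  fit <- fit_form_factor(noisy)
  expect_equal(fit$D, 4, tolerance = 0.05)
  expect_equal(fit$L, 380, tolerance = 0.15)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4)
  expect_error(fit_form_factor(clean[1:10, ]), "30")
})

test_that("structure factor is unity for a concentration rescale and finds an injected peak", {
  ref <- sim_saxs_profiles(D = 4, L = 380, c_list = 1, seed = 3)
  dense <- dplyr::mutate(ref, I = 2 * I)
  sf <- structure_factor(dense, ref, N_ratio = 2)
  expect_true(all(abs(sf$S - 1) < 1e-12))
  expect_error(find_sf_peak(sf), "monotone|peak")

  # injected correlation peak at 0.030 1/Angstrom
  profs <- sim_saxs_profiles(D = 4, L = 380, c_list = c(1, 3),
                             peak = list(q0 = 0.030, amplitude = 0.6,
                                         width = 0.006), seed = 4)
  ref2 <- dplyr::filter(profs, c_wt == 1)
  dn2 <- dplyr::filter(profs, c_wt == 3)
  sf2 <- structure_factor(dn2, ref2, N_ratio = 3)
  qgrid_step <- max(diff(sf2$q[sf2$q >= 0.01 & sf2$q <= 0.04]))
  expect_equal(find_sf_peak(sf2), 0.030, tolerance = qgrid_step / 0.030)

  # the peak survives realistic acquisition noise
  noisy <- sim_saxs_profiles(D = 4, L = 380, c_list = c(1, 3),
                             peak = list(q0 = 0.030, amplitude = 0.6,
                                         width = 0.006),
                             noise = 0.01, seed = 5)
  sf3 <- structure_factor(dplyr::filter(noisy, c_wt == 3),
                          dplyr::filter(noisy, c_wt == 1), N_ratio = 3)
  expect_equal(find_sf_peak(sf3), 0.030, tolerance = 2 * qgrid_step / 0.030)

  # grid mismatch beyond the interpolation range is an error
  expect_error(structure_factor(dense[10:50, ], ref, 2), "interpolate")
})

test_that("peak position converts to real-space periodicity by the reciprocal law", {
  # q doubled -> d halved, exactly
  expect_equal(spacing_from_peak(0.06), spacing_from_peak(0.03) / 2,
               tolerance = 1e-12)
  # round trip through d -> 2 pi / d is the identity (with the
  # Angstrom-to-nm factor of 10 asserted)
  d <- 17.3
  expect_equal(spacing_from_peak(2 * pi / (10 * d)), d, tolerance = 1e-12)
  expect_error(spacing_from_peak(0), "> 0")
})

test_that("SAXS generator is seed-deterministic and its dilute member is form-factor only", {
  a <- sim_saxs_profiles(D = 4, L = 380, c_list = c(1, 3),
                         peak = list(q0 = 0.03, amplitude = 0.5,
                                     width = 0.005),
                         noise = 0.02, seed = 11)
  b <- sim_saxs_profiles(D = 4, L = 380, c_list = c(1, 3),
                         peak = list(q0 = 0.03, amplitude = 0.5,
                                     width = 0.005),
                         noise = 0.02, seed = 11)
  expect_identical(a, b)
  # without noise, doubling the concentration without a peak leaves S = 1
  flat <- sim_saxs_profiles(D = 4, L = 380, c_list = c(1, 2), seed = 1)
  sf <- structure_factor(dplyr::filter(flat, c_wt == 2),
                         dplyr::filter(flat, c_wt == 1), N_ratio = 2)
  expect_true(all(abs(sf$S - 1) < 1e-12))
})
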