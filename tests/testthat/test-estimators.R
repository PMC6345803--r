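test_that("tangent correlation is exact on straight lines and circular arcs", {
  # straight track: no decorrelation in any bin
  straight <- list(cbind(seq(0, 5000, by = 50), rep(0, 101)))
  corr <- tangent_correlation(straight, bin_width = 100, smooth_window = 1)
  expect_true(all(abs(corr$mean_cos - 1) < 1e-12))

  # circular arc of radius rho: cos theta(L) = cos(L / rho)
  rho <- 5000
  s <- seq(0, 3000, by = 25)
  arc <- list(cbind(rho * cos(s / rho), rho * sin(s / rho)))
  corr <- tangent_correlation(arc, bin_width = 50, smooth_window = 1)
  expect_true(all(abs(corr$mean_cos - cos(corr$L_nm / rho)) < 2e-3))
})

test_that("tracks that are too short are skipped, empty input errors", {
  good <- cbind(seq(0, 1000, by = 100), 0)
  expect_warning(corr <- tangent_correlation(list(good, cbind(0:1, 0:1))),
                 "skipping")
  expect_s3_class(corr, "tangent_correlation")
  expect_error(suppressWarnings(tangent_correlation(list(cbind(0:1, 0:1)))),
               "no usable tracks")
})

test_that("persistence-length fit inverts a noiseless exponential exactly", {
  L <- seq(0, 8000, by = 100)
  corr <- structure(
    data.frame(L_nm = L, mean_cos = exp(-L / 16000), count = 1000),
    class = c("tangent_correlation", "data.frame"))
  f <- fit_persistence_length(corr)
  expect_equal(f$Lp_nm, 8000, tolerance = 1e-9)
  # no decay: the failure path must trigger, not return a clipped value
  flat <- structure(
    data.frame(L_nm = L, mean_cos = rep(1, length(L)), count = 1000),
    class = c("tangent_correlation", "data.frame"))
  expect_error(fit_persistence_length(flat), "non-negative")
})

test_that("persistence-length estimation is scale-equivariant", {
  trk <- generate_wlc(4000, 6000, n_chains = 40, seed = 3)
  f1 <- fit_persistence_length(tangent_correlation(trk), min_count = 10)
  trk2 <- trk
  trk2$x_nm <- trk2$x_nm * 2
  trk2$y_nm <- trk2$y_nm * 2
  f2 <- fit_persistence_length(tangent_correlation(trk2, bin_width = 200),
                               min_count = 10)
  expect_equal(f2$Lp_nm, 2 * f1$Lp_nm, tolerance = 0.02)
})

test_that("Hill fit recovers noiseless curves exactly", {
  conc <- c(5, 15, 44, 88, 176, 400)
  # Langmuir (n = 1)
  bc <- generate_binding_curve(1, 88, 1, conc, cv = 0, seed = 1)
  f <- fit_hill(bc)
  expect_equal(f$Kd_nM, 88, tolerance = 1e-6)
  expect_equal(f$S_sat, 1, tolerance = 1e-6)
  expect_equal(f$hill_n, 1, tolerance = 1e-6)
  # half-saturation at the dissociation constant for any Hill exponent
  for (h in c(1, 2.5))
    expect_equal(generate_binding_curve(10, 88, h, c(44, 88, 176), cv = 0,
                                        seed = 1)$bound_per_um2[2], 5)
  # fixed-exponent fit
  f2 <- fit_hill(generate_binding_curve(3500, 88, 2, conc, cv = 0, seed = 1),
                 fix_hill_n = 2)
  expect_equal(f2$Kd_nM, 88, tolerance = 1e-6)
  expect_true(f2$fixed_n)
})

test_that("bending-modulus fit inverts the entropic regime exactly", {
  sig <- exp(seq(log(1e-6), log(4.9e-4), length.out = 8))
  ser <- generate_aspiration_series(10.5, Inf, sig, noise_sd = 0, seed = 1)
  expect_equal(suppressWarnings(fit_bending_modulus(ser))$kappa_kT, 10.5,
               tolerance = 1e-9)  # noiseless: summary.lm warns on perfect fit
  # invariance to the reference tension: rescaling sigma0 shifts only the
  # intercept
  ser2 <- ser
  attr(ser2, "sigma0") <- sig[3]
  expect_equal(suppressWarnings(fit_bending_modulus(ser2))$kappa_kT, 10.5,
               tolerance = 1e-9)
  expect_error(fit_bending_modulus(ser[1:3, ]), "at least 4")
})

test_that("stretching-modulus fit inverts the dilation regime exactly", {
  sig <- seq(2e-3, 8e-3, length.out = 6)
  ser <- generate_aspiration_series(Inf, 65, sig, noise_sd = 0, seed = 1)
  expect_equal(suppressWarnings(fit_stretching_modulus(ser))$Ka_mN_per_m, 65,
               tolerance = 1e-9)
  expect_error(fit_stretching_modulus(ser[1:2, ]), "at least 3")
  flat <- ser
  flat$rel_area <- rep(0.01, nrow(flat))
  expect_error(fit_stretching_modulus(flat), "non-positive")
})

test_that("aspiration tension follows the Laplace relation", {
  expect_equal(tension_from_aspiration(0, 3, 15), 0)
  expect_equal(tension_from_aspiration(100, 3, 15), 1.875e-4)
  # R_p << R_v limit: sigma -> dP R_p / 2
  expect_equal(tension_from_aspiration(100, 0.01, 1e5), 100 * 0.01e-6 / 2,
               tolerance = 1e-6)
  expect_error(tension_from_aspiration(100, 3, 3), "R_pipette")
  expect_error(tension_from_aspiration(-1, 3, 15), ">= 0")
})
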