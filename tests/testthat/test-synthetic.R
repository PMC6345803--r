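test_that("generators are deterministic under a seed and restore RNG state", {
  set.seed(999)
  before <- .Random.seed
  a <- generate_wlc(8000, 5000, n_chains = 3, seed = 5)
  expect_identical(.Random.seed, before)
  b <- generate_wlc(8000, 5000, n_chains = 3, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_wlc(8000, 5000, n_chains = 3, seed = 6)))

  expect_identical(generate_binding_curve(1, 88, 2, c(10, 50, 250), seed = 4),
                   generate_binding_curve(1, 88, 2, c(10, 50, 250), seed = 4))
  sig <- c(1e-5, 1e-4, 5e-4)
  expect_identical(generate_aspiration_series(10, Inf, sig, seed = 4),
                   generate_aspiration_series(10, Inf, sig, seed = 4))
  expect_identical(generate_spiky_contour(10, 0.9, 3.9, 1, jitter_sd = 0.01, seed = 4),
                   generate_spiky_contour(10, 0.9, 3.9, 1, jitter_sd = 0.01, seed = 4))
})

test_that("child seeds are reproducible and distinct", {
  expect_identical(child_seed(1, 0:3), child_seed(1, 0:3))
  expect_equal(length(unique(child_seed(123, 0:100))), 101)
  expect_true(all(child_seed(2^31 - 2, 0:10) >= 0))
})

test_that("stiff chains are straight and the tangent correlation matches theory", {
  stiff <- generate_wlc(1e11, 1e4, step_nm = 100, n_chains = 2, seed = 1)
  for (id in unique(stiff$filament_id)) {
    chain <- stiff[stiff$filament_id == id, ]
    seg <- cbind(diff(chain$x_nm), diff(chain$y_nm))
    ang <- atan2(seg[, 2], seg[, 1])
    expect_lt(max(ang) - min(ang), 1e-3)
  }

  # ensemble <cos theta(L)> vs exp(-L / 2Lp) within 3 binned SE
  suppressWarnings({
    trk <- generate_wlc(8000, 1e4, step_nm = 80, n_chains = 1000, seed = 2)
  })
  corr <- tangent_correlation(trk, bin_width = 400, smooth_window = 1)
  sel <- corr$L_nm > 0 & corr$count >= 1000
  theo <- exp(-corr$L_nm[sel] / 16000)
  # conservative SE: treat each of the 1000 chains as one effective sample
  se <- sqrt((1 - theo^2) / 1000) + 1e-4
  expect_true(all(abs(corr$mean_cos[sel] - theo) < 3.5 * se))
})

test_that("mean squared end-to-end distance matches the quadrature oracle", {
  Lp <- 4000; Lc <- 8000
  trk <- generate_wlc(Lp, Lc, n_chains = 600, seed = 8)
  ree2 <- sapply(split(trk, trk$filament_id), function(ch) {
    (ch$x_nm[nrow(ch)] - ch$x_nm[1])^2 + (ch$y_nm[nrow(ch)] - ch$y_nm[1])^2
  })
  theo <- 2 * integrate(function(s) (Lc - s) * exp(-s / (2 * Lp)),
                        0, Lc)$value
  expect_equal(mean(ree2), theo, tolerance = 3 * sd(ree2) / sqrt(600) / theo)
})

test_that("binding and aspiration generators hit their noiseless limits", {
  conc <- c(22, 44, 88, 176)
  bc <- generate_binding_curve(100, 88, 1, conc, cv = 0)
  expect_equal(bc$bound_per_um2, 100 / ((88 / conc) + 1))
  sig <- exp(seq(log(1e-6), log(5e-4), length.out = 6))
  pure_bend <- generate_aspiration_series(12, Inf, sig, noise_sd = 0)
  expect_equal(pure_bend$rel_area, log(sig / sig[1]) / (8 * pi * 12))
  expect_true(all(pure_bend$rel_volume == 0))
  pure_stretch <- generate_aspiration_series(Inf, 50, sig, noise_sd = 0)
  expect_equal(pure_stretch$rel_area, sig / 0.05)
})

test_that("spiky contour construction arithmetic and degenerate limits", {
  ct <- generate_spiky_contour(10, 0.9, 3.9, 1 / 1.1)
  expect_equal(attr(ct, "n_spikes"), 16)
  expect_equal(attr(ct, "realized_period_um"), 2 * pi * 10 / 16)
  r <- sqrt(ct$x_um^2 + ct$y_um^2)
  expect_equal(min(r), 10, tolerance = 1e-9)
  expect_equal(max(r), 10.9, tolerance = 1e-9)
  # amplitude zero: a plain circle, no spikes detected
  circ <- generate_spiky_contour(10, 0, 3.9, 1)
  expect_equal(measure_spikes(circ)$n_spikes, 0)
  expect_error(generate_spiky_contour(10, 10, 3.9, 1), "amplitude")
  expect_error(generate_spiky_contour(10, 0.9, 100, 1), "period")
})

test_that("wavy substrate curvature field has the analytic extrema and symmetry", {
  w <- generate_wavy_substrate(1e-4, 4, n_points = 1025)  # grid hits the crest
  k <- 2 * pi / 4
  expect_equal(w$c_crest_per_um, 1e-4 * k^2, tolerance = 1e-6)
  expect_equal(w$c_trough_per_um, -1e-4 * k^2, tolerance = 1e-6)
  # numeric differentiation agrees with the analytic curvature field
  wb <- generate_wavy_substrate(0.85, 3.8, n_points = 4001)
  pr <- wb$profile
  h <- diff(pr$x_um)[1]
  hp <- (pr$h_um[3:4001] - pr$h_um[1:3999]) / (2 * h)
  hpp <- (pr$h_um[3:4001] - 2 * pr$h_um[2:4000] + pr$h_um[1:3999]) / h^2
  cnum <- -hpp / (1 + hp^2)^1.5
  expect_equal(pr$curvature_per_um[2:4000], cnum, tolerance = 1e-4)
  # crest/trough antisymmetry of a pure sinusoid
  expect_equal(wb$c_crest_per_um, -wb$c_trough_per_um, tolerance = 1e-6)
  # zero amplitude: flat
  expect_true(all(generate_wavy_substrate(0, 4)$profile$curvature_per_um == 0))
})

test_that("wavy substrate extremes feed the orientation classifier", {
  p <- default_params()
  w <- generate_wavy_substrate(0.85, 3.8)
  crest <- classify_substrate_orientation(p, w$c_crest_per_um)
  trough <- classify_substrate_orientation(p, w$c_trough_per_um)
  expect_equal(crest$regime, "ALONG_AXIS")
  # the deep trough here is beyond the single-filament threshold
  expect_true(w$c_trough_per_um < threshold_curvature(p, 1))
  expect_equal(trough$regime, "ALONG_AXIS")
})
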