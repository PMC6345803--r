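test_that("neck geometry validates its shape classes", {
  expect_error(neck_geometry(0, -1), "nonzero")
  expect_error(neck_geometry(1, 0), "nonzero")
  expect_error(neck_geometry(-1, -2, "spherical"), "R_perp")
  expect_error(neck_geometry(Inf, -1, "spherical"), "finite")
  g <- neck_geometry(-2, -1, "spherical")
  expect_equal(g$sin_theta, 0.5)
  expect_equal(neck_geometry(Inf, -1, "oblong")$c_par_um, 0)
})

test_that("identical curvatures give identical energies and a degenerate tie", {
  p <- default_params()
  g <- neck_geometry(-2, -2, "spherical")
  dg <- neck_free_energies(p, g, 1)
  expect_equal(unname(dg["dg_par"]), unname(dg["dg_perp"]))
  pref <- preferred_orientation(p, g, 1)
  expect_equal(pref$preferred, "DEGENERATE")
  expect_equal(pref$gap, 0)
  expect_setequal(pref$orientations, c("PARALLEL", "PERPENDICULAR"))
})

test_that("spherical geometry is always radial, independent of binding terms", {
  # Eq.-14-type reduction: only persistence length and curvature magnitudes
  # matter, so randomised dg0 and a1 must never flip the preference.
  set.seed(42)
  for (i in 1:50) {
    p <- septin_params(a1_nm = runif(1, 1, 10), Lp1_nm = runif(1, 500, 8000),
                       dg1_flat = -runif(1, 0.05, 2))
    Rpar <- -runif(1, 1, 5)
    Rperp <- Rpar * runif(1, 0.05, 0.99)   # |R_perp| < |R_par|
    g <- neck_geometry(Rpar, Rperp, "spherical")
    for (n in c(1, 2, 5))
      expect_equal(preferred_orientation(p, g, n)$preferred, "PARALLEL")
  }
})

test_that("oblong gap is antisymmetric under swapping the two curvatures", {
  p <- default_params()
  set.seed(7)
  for (i in 1:25) {
    cpar <- runif(1, -3, 3); cperp <- runif(1, -3, 3)
    g1 <- neck_geometry(1 / cpar, 1 / cperp, "oblong")
    g2 <- neck_geometry(1 / cperp, 1 / cpar, "oblong")
    expect_equal(preferred_orientation(p, g1, 2)$gap,
                 -preferred_orientation(p, g2, 2)$gap, tolerance = 1e-15)
  }
})

test_that("transition condition reproduces the mixed single/double band", {
  p <- default_params()
  # c_par = -0.2, c_perp = -1.0 um^-1: single filaments circumferential ...
  expect_true(transition_condition(p, -0.2, -1.0, 1))
  # ... while paired filaments remain parallel (threshold halves with n)
  expect_false(transition_condition(p, -0.2, -1.0, 2))
  # boundary: product vanishes
  cthr <- threshold_curvature(p, 1)
  expect_false(transition_condition(p, cthr / 2, cthr / 2, 1))
})

test_that("transition condition sign equals the direct energy comparison", {
  p <- default_params()
  set.seed(11)
  for (i in 1:2000) {
    cpar <- runif(1, -3, 3); cperp <- runif(1, -3, 3)
    n <- sample(1:4, 1)
    g <- neck_geometry(1 / cpar, 1 / cperp, "oblong")
    gap <- preferred_orientation(p, g, n)$gap
    if (abs(gap) < 1e-12) next
    expect_equal(transition_condition(p, cpar, cperp, n), gap > 0)
  }
})

test_that("stage sequence follows the constriction bands and ring splitting", {
  p <- default_params()
  sph <- list(neck_geometry(-3, -2, "spherical"), neck_geometry(-2, -1, "spherical"))
  expect_true(all(stage_sequence(p, sph)$stage == "SPHERE_RADIAL"))

  path <- list(
    neck_geometry(1 / -0.8, 1 / -1.2, "oblong"),   # s = -2.0: all axial
    neck_geometry(1 / 0.2, 1 / -1.2, "oblong"),    # s = -1.0: mixed band
    neck_geometry(1 / 0.7, 1 / -1.2, "oblong"),    # s = -0.5: all circumferential
    neck_geometry(1 / 1.55, 1 / -2.0, "oblong"))   # |R_perp| = 0.5 um < R50_min
  st <- stage_sequence(p, path, n_list = c(1, 2), n_bundle = c(30, 50))
  expect_equal(st$stage, c("SPHERE_RADIAL", "CYLINDER_MIXED",
                           "NECK_CIRCUMFERENTIAL", "SPLIT_DOUBLE_RING"))
  expect_equal(st$perp_n1, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(st$perp_n2, c(FALSE, FALSE, TRUE, TRUE))
  # unordered path rejected
  expect_error(stage_sequence(p, rev(path)), "ordered")
})

test_that("stage band edges move as 1/n and the splitting radius as n^(3/4)", {
  p <- default_params()
  c1 <- threshold_curvature(p, 1)
  for (n in c(2, 4, 8)) {
    expect_equal(threshold_curvature(p, n), c1 / n, tolerance = 1e-12)
    expect_equal(max_curvature(p, n)$R_min_nm,
                 max_curvature(p, 1)$R_min_nm * n^0.75, tolerance = 1e-12)
  }
})

test_that("phase diagram reduces to pointwise preference and marks the boundary", {
  p <- default_params()
  one <- phase_diagram(p, -0.2, -1.0, 1)
  expect_equal(nrow(one), 1)
  g <- neck_geometry(1 / -0.2, 1 / -1.0, "oblong")
  expect_equal(one$preferred, preferred_orientation(p, g, 1)$preferred)
  expect_equal(one$gap_kT_per_nm, preferred_orientation(p, g, 1)$gap)

  diag <- phase_diagram(p, c(-1, 0.5), c(-1, 0.5), 1)
  expect_true(all(diag$preferred[diag$c_par_um == diag$c_perp_um] == "DEGENERATE"))

  # the sign boundary along a c_par scan lies where the product factor
  # crosses zero, within one grid cell
  grid <- seq(-3, 1, by = 0.01)
  row <- phase_diagram(p, grid, -1.0, 1)
  flips <- which(diff(row$gap_kT_per_nm > 0) != 0)
  cthr <- threshold_curvature(p, 1)
  analytic <- sort(c(cthr - (-1.0), -1.0))  # roots of (s - c1)(c_par - c_perp)
  expect_equal(length(flips), 2)
  expect_lt(max(abs(sort(grid[flips]) - analytic)), 0.011)

  expect_error(phase_diagram(p, numeric(0), 1), "non-empty")
})
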