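# Shared fixtures: parameter sets and brute-force oracles used across the
# model tests.

default_params <- function() septin_params()

# Random but physically sensible parameter sets for property tests.
random_params <- function(n_sets, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i)
    septin_params(a1_nm = runif(1, 2, 8),
                  Lp1_nm = runif(1, 500, 8000),
                  dg1_flat = -runif(1, 0.05, 1.5)))
}

# Two-stage grid minimiser of the adsorption free energy over curvature
# (independent of the closed-form optimum).  Returns the argmin in um^-1
# and the grid resolution of the refined stage.
brute_min_curvature <- function(params, n = 1, lo = -15, hi = 2) {
  grid <- seq(lo, hi, length.out = 10001)
  dg <- free_energy_per_length(params, grid, n)
  i <- which.min(dg)
  step <- grid[2] - grid[1]
  fine <- seq(grid[max(1, i - 2)], grid[min(length(grid), i + 2)],
              length.out = 20001)
  dgf <- free_energy_per_length(params, fine, n)
  list(c_um = fine[which.min(dgf)], resolution = fine[2] - fine[1])
}

# Root-bracketing oracle for the threshold curvature (nonzero root of the
# curved-vs-flat gap), anchored only on the brute-force argmin.
brute_threshold_curvature <- function(params, n = 1) {
  cstar <- brute_min_curvature(params, n)$c_um
  uniroot(function(c) curved_vs_flat_gap(params, c, n),
          interval = c(3 * cstar, 0.5 * cstar), tol = 1e-12)$root
}

# Root of the bending-vs-binding balance (contact-area term dropped).
brute_max_curvature <- function(params, n = 1) {
  b <- bundle_properties(params, n)
  f <- function(c_um) 0.5 * b$Lp_n * (c_um * 1e-3)^2 + b$dg_n_flat
  uniroot(f, interval = c(1e-9, 1e3), tol = 1e-12)$root
}
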