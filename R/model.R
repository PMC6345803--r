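# Curvature convention: c > 0 is a convex substrate (outside of a sphere,
# crest of a wavy pattern) as seen from the binding face; c < 0 is concave
# (valley, inside of a sphere).  Exported functions take curvature in um^-1;
# internally everything is in nm^-1 (exact factor 1e-3) and kT = 1.

um1_to_nm1 <- function(c_um) c_um * 1e-3
nm1_to_um1 <- function(c_nm) c_nm * 1e3

dg_bundle_nm <- function(b, c_nm) {
  b$dg_n_flat * (1 - 0.5 * b$a_n * c_nm) + 0.5 * b$Lp_n * c_nm^2
}

#' Adsorption free energy per unit length on a curved substrate
#'
#' Evaluates the per-unit-length free energy of an n-filament septin bundle
#' bound to a membrane of signed curvature c,
#' \deqn{\Delta g_n(c) = \Delta g_n^0 (1 - a_n c / 2) + L_{pn} c^2 / 2,}
#' in \eqn{k_bT\,nm^{-1}} with \eqn{k_bT = 1}.  The linear term is the change
#' of contact area with curvature (an incompressible filament gains contact
#' on a concave substrate); the quadratic term is the bending energy of a
#' worm-like filament of persistence length \eqn{L_{pn}}.
#'
#' @param params A [septin_params()] object.
#' @param c_um Signed substrate curvature(s), \eqn{\mu m^{-1}} (vectorised).
#' @param n Number of filaments in the bundle (default 1).
#' @return Free energy per unit length, \eqn{k_bT\,nm^{-1}}.
#' @examples
#' p <- septin_params()
#' free_energy_per_length(p, 0)                    # the flat value dg1_flat
#' free_energy_per_length(p, optimal_curvature(p)) # the minimum
#' @export
free_energy_per_length <- function(params, c_um, n = 1) {
  b <- bundle_properties(params, n)
  stopifnot(is.numeric(c_um), all(is.finite(c_um)))
  dg_bundle_nm(b, um1_to_nm1(c_um))
}

#' Optimal adsorption curvature of a filament bundle
#'
#' The curvature minimising [free_energy_per_length()],
#' \eqn{c_n^* = \Delta g_n^0 a_n / (2 L_{pn})}, always negative (concave) for
#' a bound state.  Scales as \eqn{c_n^* = c_1^*/n}.
#'
#' @inheritParams free_energy_per_length
#' @return Optimal curvature, \eqn{\mu m^{-1}} (negative).
#' @export
optimal_curvature <- function(params, n = 1) {
  b <- bundle_properties(params, n)
  nm1_to_um1(b$dg_n_flat * b$a_n / (2 * b$Lp_n))
}

#' Threshold curvature for curved-over-flat adsorption
#'
#' Curved adsorption is favoured over flat exactly for curvatures between
#' the threshold \eqn{c_n = 2 c_n^* = \Delta g_n^0 a_n / L_{pn}} and zero;
#' at the threshold the free energy equals the flat value.  Scales as
#' \eqn{c_n = c_1/n}, i.e. the threshold radius grows linearly with the
#' number of filaments.
#'
#' @inheritParams free_energy_per_length
#' @return Threshold curvature, \eqn{\mu m^{-1}} (negative).
#' @export
threshold_curvature <- function(params, n = 1) {
  2 * optimal_curvature(params, n)
}

#' Maximum curvature and minimum radius of adsorbed bundles
#'
#' Neglecting the (small) contact-area term, adsorption remains favourable
#' only while the bending penalty stays below the flat binding energy,
#' giving a maximum curvature magnitude
#' \eqn{c_n^{max} = \sqrt{-2\Delta g_n^0 / L_{pn}}} and a minimum radius of
#' curvature \eqn{R_n^{min} = 1/c_n^{max} = R_1^{min} n^{3/4}}.  With the
#' default parameters \eqn{R_1^{min} \approx 37} nm; tens of bundled
#' filaments raise the minimum radius to several hundred nm, the scale of
#' the septin double rings at the cytokinetic bridge.
#'
#' @inheritParams free_energy_per_length
#' @return A list with `c_max_um` (\eqn{\mu m^{-1}}, positive magnitude)
#'   and `R_min_nm` (nm).
#' @examples
#' max_curvature(septin_params(), 10)$R_min_nm  # ~ 208 nm
#' @export
max_curvature <- function(params, n = 1) {
  b <- bundle_properties(params, n)
  c_max_nm <- sqrt(-2 * b$dg_n_flat / b$Lp_n)
  list(c_max_um = nm1_to_um1(c_max_nm), R_min_nm = 1 / c_max_nm)
}

#' Free-energy gap between curved and flat adsorption
#'
#' \eqn{\Delta g_n(c) - \Delta g_n(0)}: zero at c = 0 and at the threshold
#' curvature, minimal at the optimal curvature where it equals
#' \eqn{-(\Delta g_n^0 a_n)^2 / (8 L_{pn})}.
#'
#' @inheritParams free_energy_per_length
#' @return Energy gap per unit length, \eqn{k_bT\,nm^{-1}} (vectorised).
#' @export
curved_vs_flat_gap <- function(params, c_um, n = 1) {
  b <- bundle_properties(params, n)
  c_nm <- um1_to_nm1(c_um)
  -0.5 * b$dg_n_flat * b$a_n * c_nm + 0.5 * b$Lp_n * c_nm^2
}

#' Orientation regime of filaments on a wavy substrate
#'
#' Classifies the expected orientation of an n-filament bundle on a
#' sinusoidally wavy substrate from the extremal signed curvature across the
#' wave (crest positive, valley negative).  Bands, with
#' \eqn{c_n < c_n^* < 0} the threshold and optimal curvatures:
#' \itemize{
#'   \item `c >= 0` (crest): `ALONG_AXIS` — filaments stay straight along
#'     the null-curvature wave axis (tilt 0), avoiding positive bending.
#'   \item `c_n^* <= c < 0`: `ACROSS_GROOVE` — fully bent across the valley
#'     (tilt 90 deg).
#'   \item `c_n < c < c_n^*`: `TILTED` — the filament tilts so that its
#'     normal curvature, \eqn{c\,\sin^2\varphi} by Euler's formula with
#'     principal curvatures (c, 0), equals the optimal value:
#'     \eqn{\sin^2\varphi = c_n^*/c}.
#'   \item `c <= c_n`: `ALONG_AXIS` — the valley is too tight; bent
#'     adsorption no longer beats flat and filaments stay along the axis.
#' }
#' Band-edge ties resolve toward the lower-tilt regime; the tilt angle is
#' continuous (90 deg) at \eqn{c = c_n^*}.
#'
#' @inheritParams free_energy_per_length
#' @param c_um Extremal signed curvature(s) across the wave,
#'   \eqn{\mu m^{-1}} (vectorised).
#' @return A data.frame with columns `c_um`, `regime` (character) and
#'   `tilt_deg` (0 for `ALONG_AXIS`, 90 for `ACROSS_GROOVE`).
#' @export
classify_substrate_orientation <- function(params, c_um, n = 1) {
  stopifnot(is.numeric(c_um), all(is.finite(c_um)))
  cstar <- optimal_curvature(params, n)
  cthr <- 2 * cstar
  regime <- character(length(c_um))
  tilt <- numeric(length(c_um))
  for (i in seq_along(c_um)) {
    c <- c_um[i]
    if (c >= 0 || c <= cthr) {
      regime[i] <- "ALONG_AXIS"; tilt[i] <- 0
    } else if (c >= cstar) {
      regime[i] <- "ACROSS_GROOVE"; tilt[i] <- 90
    } else {
      regime[i] <- "TILTED"
      tilt[i] <- asin(sqrt(cstar / c)) * 180 / pi
    }
  }
  data.frame(c_um = c_um, regime = regime, tilt_deg = tilt)
}
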