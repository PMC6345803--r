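# Axisymmetric bud-neck theory: radial (parallel to the mother-bud axis)
# versus circumferential (perpendicular) adsorption of septin filaments on
# the membrane of a dividing cell.  The neck is described pointwise at its
# waist by two signed radii of curvature; no meridian profile is computed.

#' Axisymmetric neck geometry
#'
#' Describes the local membrane geometry at (or near) the bud neck by the
#' signed radius of curvature along the mother-bud axis (`R_par_um`) and the
#' circumferential signed radius (`R_perp_um`), both measured on the face
#' the filaments bind (the cytosolic face: negative = concave).  Two shape
#' classes set the angle \eqn{\theta} between the plane of a circumferential
#' filament and the membrane: on a `"spherical"` cell
#' \eqn{\sin\theta = R_\perp / R_\parallel} (which requires
#' \eqn{|R_\perp| \le |R_\parallel|}), while on an elongated `"oblong"`
#' (barrel or neck) shape \eqn{\sin\theta = 1}.
#'
#' @param R_par_um Signed radius of curvature along the axis, µm (nonzero;
#'   use `Inf` for a cylinder's flat meridian).
#' @param R_perp_um Signed circumferential radius, µm (nonzero).
#' @param shape `"spherical"` or `"oblong"`.
#' @return An object of class `"neck_geometry"` with elements `R_par_um`,
#'   `R_perp_um`, `c_par_um`, `c_perp_um`, `shape` and `sin_theta`.
#' @export
neck_geometry <- function(R_par_um, R_perp_um, shape = c("spherical", "oblong")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(R_par_um), is.numeric(R_perp_um),
            length(R_par_um) == 1L, length(R_perp_um) == 1L)
  if (is.na(R_par_um) || R_par_um == 0)
    stop("'R_par_um' must be nonzero", call. = FALSE)
  if (is.na(R_perp_um) || !is.finite(R_perp_um) || R_perp_um == 0)
    stop("'R_perp_um' must be nonzero and finite", call. = FALSE)
  if (shape == "spherical") {
    if (!is.finite(R_par_um))
      stop("a spherical geometry needs a finite 'R_par_um'", call. = FALSE)
    if (abs(R_perp_um) > abs(R_par_um))
      stop("spherical geometry requires |R_perp| <= |R_par|", call. = FALSE)
    sin_theta <- R_perp_um / R_par_um
  } else {
    sin_theta <- 1
  }
  structure(
    list(R_par_um = R_par_um, R_perp_um = R_perp_um,
         c_par_um = 1 / R_par_um, c_perp_um = 1 / R_perp_um,
         shape = shape, sin_theta = sin_theta),
    class = "neck_geometry")
}

#' @export
print.neck_geometry <- function(x, ...) {
  cat(sprintf("Neck geometry (%s): R_par = %g um, R_perp = %g um, sin(theta) = %g\n",
              x$shape, x$R_par_um, x$R_perp_um, x$sin_theta))
  invisible(x)
}

#' Adsorption free energies of the two neck orientations
#'
#' Per-unit-length free energies of an n-filament bundle adsorbed parallel
#' (radial, bent along the meridian with curvature \eqn{c_\parallel}) or
#' perpendicular (circumferential, curvature \eqn{c_\perp}) at the given
#' geometry.  The contact-area term of the circumferential orientation is
#' projected by \eqn{\sin\theta}; its bending term is not.  On a sphere
#' \eqn{c_\perp \sin\theta = c_\parallel}, so the area terms cancel in the
#' comparison and only bending distinguishes the orientations.
#'
#' @param params A [septin_params()] object.
#' @param geom A [neck_geometry()] object.
#' @param n Number of filaments in the bundle.
#' @return Named numeric vector `c(dg_par, dg_perp)`, \eqn{k_bT\,nm^{-1}}.
#' @export
neck_free_energies <- function(params, geom, n = 1) {
  stopifnot(inherits(geom, "neck_geometry"))
  b <- bundle_properties(params, n)
  c_par_nm <- um1_to_nm1(geom$c_par_um)
  c_perp_nm <- um1_to_nm1(geom$c_perp_um)
  dg_par <- dg_bundle_nm(b, c_par_nm)
  dg_perp <- b$dg_n_flat * (1 - 0.5 * b$a_n * c_perp_nm * geom$sin_theta) +
    0.5 * b$Lp_n * c_perp_nm^2
  c(dg_par = dg_par, dg_perp = dg_perp)
}

#' Preferred filament orientation at an axisymmetric geometry
#'
#' Compares the parallel (radial) and perpendicular (circumferential)
#' adsorption free energies.  On a spherical geometry the difference reduces
#' to pure bending, \eqn{L_{pn}(c_\parallel^2 - c_\perp^2)/2}, so filaments
#' are always radial when \eqn{|c_\parallel| < |c_\perp|}, independently of
#' the binding energy and bundle width.
#'
#' @inheritParams neck_free_energies
#' @return A list of class `"orientation_preference"` with `preferred`
#'   (`"PARALLEL"`, `"PERPENDICULAR"` or `"DEGENERATE"`; a degenerate tie
#'   reports both orientations in `orientations`) and `gap`
#'   (\eqn{\Delta g_n(c_\parallel) - \Delta g_n(c_\perp)},
#'   \eqn{k_bT\,nm^{-1}}; positive favours perpendicular).
#' @export
preferred_orientation <- function(params, geom, n = 1) {
  dg <- neck_free_energies(params, geom, n)
  gap <- unname(dg["dg_par"] - dg["dg_perp"])
  preferred <- if (gap > 0) "PERPENDICULAR" else if (gap < 0) "PARALLEL" else "DEGENERATE"
  structure(
    list(preferred = preferred,
         orientations = if (preferred == "DEGENERATE")
           c("PARALLEL", "PERPENDICULAR") else preferred,
         gap = gap, n = n, shape = geom$shape),
    class = "orientation_preference")
}

#' @export
print.orientation_preference <- function(x, ...) {
  cat(sprintf("Preferred orientation (n = %d, %s shape): %s (gap = %.4g kT/nm)\n",
              x$n, x$shape, x$preferred, x$gap))
  invisible(x)
}

#' Parallel-to-circumferential transition condition (oblong geometry)
#'
#' For an oblong axisymmetric shape the circumferential orientation becomes
#' favourable exactly when
#' \deqn{(c_\perp + c_\parallel - c_n)(c_\parallel - c_\perp) > 0,}
#' with \eqn{c_n = c_1/n} the threshold curvature.  This is algebraically
#' the sign of the free-energy gap of [preferred_orientation()] in the
#' oblong approximation (the gap factorises as
#' \eqn{L_{pn}(c_\parallel - c_\perp)(c_\parallel + c_\perp - c_n)/2}).
#' Because the thresholds move as \eqn{1/n}, there is a constriction band in
#' which single filaments are already circumferential while paired filaments
#' are still axial.
#'
#' @param params A [septin_params()] object.
#' @param c_par_um,c_perp_um Signed curvatures, \eqn{\mu m^{-1}}
#'   (vectorised, recycled).
#' @param n Number of filaments in the bundle.
#' @return Logical: `TRUE` where circumferential adsorption is favoured.
#' @export
transition_condition <- function(params, c_par_um, c_perp_um, n = 1) {
  stopifnot(is.numeric(c_par_um), is.numeric(c_perp_um))
  c_n <- threshold_curvature(params, n)
  (c_perp_um + c_par_um - c_n) * (c_par_um - c_perp_um) > 0
}

#' Cytokinesis stage sequence along a constriction path
#'
#' Labels each geometry of an ordered constriction path with the predicted
#' septin arrangement.  Constriction moves the total curvature
#' \eqn{s = c_\parallel + c_\perp} upward through the thresholds
#' \eqn{c_1 < c_2 < 0}: spherical (or weakly constricted) geometries keep
#' all filaments radial/axial (`SPHERE_RADIAL`); in the band
#' \eqn{c_1 < s < c_2} single filaments turn circumferential while paired
#' filaments remain axial (`CYLINDER_MIXED`); for \eqn{s > c_2} all tracked
#' filament species are circumferential (`NECK_CIRCUMFERENTIAL`); and once
#' the neck radius drops below the minimum radius of curvature of a bundle
#' of `n_bundle` filaments, the ring is predicted to split into the double
#' ring flanking the bridge (`SPLIT_DOUBLE_RING`).
#'
#' @param params A [septin_params()] object.
#' @param path A list of [neck_geometry()] objects ordered by progressive
#'   constriction (non-decreasing \eqn{c_\parallel + c_\perp} among oblong
#'   geometries).
#' @param n_list Integer vector of filament counts tracked for the
#'   mixed/circumferential bands (default `c(1, 2)`).
#' @param n_bundle Bundle size(s) assumed at the splitting stage; bundling
#'   needs additional molecular players, so this is user-supplied (default
#'   the 30-50 filament band; splitting is flagged when the neck is tighter
#'   than the largest of their minimum radii).
#' @return A data.frame with one row per geometry: curvatures, total
#'   curvature `s_um`, per-species orientation columns (`perp_n1`, ...),
#'   and `stage`.
#' @export
stage_sequence <- function(params, path, n_list = c(1, 2), n_bundle = c(30, 50)) {
  if (!is.list(path) || length(path) == 0 ||
      !all(vapply(path, inherits, logical(1), "neck_geometry")))
    stop("'path' must be a non-empty list of neck_geometry objects", call. = FALSE)
  n_list <- vapply(n_list, check_n, integer(1))
  n_bundle <- vapply(n_bundle, check_n, integer(1))

  s <- vapply(path, function(g) g$c_par_um + g$c_perp_um, numeric(1))
  oblong <- vapply(path, function(g) g$shape == "oblong", logical(1))
  if (any(diff(s[oblong]) < -1e-12))
    stop("'path' is not ordered by progressive constriction ",
         "(c_par + c_perp must be non-decreasing)", call. = FALSE)

  R_split_nm <- max(vapply(n_bundle, function(n) max_curvature(params, n)$R_min_nm,
                           numeric(1)))
  perp <- sapply(n_list, function(n)
    vapply(seq_along(path), function(i) {
      g <- path[[i]]
      if (g$shape == "spherical") {
        preferred_orientation(params, g, n)$preferred == "PERPENDICULAR"
      } else {
        transition_condition(params, g$c_par_um, g$c_perp_um, n)
      }
    }, logical(1)))
  perp <- matrix(perp, nrow = length(path))

  stage <- character(length(path))
  for (i in seq_along(path)) {
    g <- path[[i]]
    if (abs(g$R_perp_um) * 1000 < R_split_nm) {
      stage[i] <- "SPLIT_DOUBLE_RING"
    } else if (all(perp[i, ])) {
      stage[i] <- "NECK_CIRCUMFERENTIAL"
    } else if (any(perp[i, ])) {
      stage[i] <- "CYLINDER_MIXED"
    } else {
      stage[i] <- "SPHERE_RADIAL"
    }
  }
  out <- data.frame(
    c_par_um = vapply(path, `[[`, numeric(1), "c_par_um"),
    c_perp_um = vapply(path, `[[`, numeric(1), "c_perp_um"),
    s_um = s,
    shape = vapply(path, `[[`, character(1), "shape"),
    stage = stage)
  for (k in seq_along(n_list))
    out[[paste0("perp_n", n_list[k])]] <- perp[, k]
  out
}

#' Orientation phase diagram over a curvature grid
#'
#' Evaluates the oblong-geometry orientation preference on the Cartesian
#' product of two curvature grids.
#'
#' @param params A [septin_params()] object.
#' @param c_par_grid,c_perp_grid Finite numeric curvature grids,
#'   \eqn{\mu m^{-1}}.
#' @param n Number of filaments in the bundle.
#' @return A data.frame with columns `c_par_um`, `c_perp_um`, `n`,
#'   `preferred` and `gap_kT_per_nm`.
#' @export
phase_diagram <- function(params, c_par_grid, c_perp_grid, n = 1) {
  if (length(c_par_grid) == 0 || length(c_perp_grid) == 0)
    stop("curvature grids must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(c_par_grid)), all(is.finite(c_perp_grid)))
  b <- bundle_properties(params, n)
  grid <- expand.grid(c_par_um = c_par_grid, c_perp_um = c_perp_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cp <- um1_to_nm1(grid$c_par_um)
  cq <- um1_to_nm1(grid$c_perp_um)
  gap <- -0.5 * b$dg_n_flat * b$a_n * (cp - cq) + 0.5 * b$Lp_n * (cp^2 - cq^2)
  grid$n <- n
  grid$preferred <- ifelse(gap > 0, "PERPENDICULAR",
                           ifelse(gap < 0, "PARALLEL", "DEGENERATE"))
  grid$gap_kT_per_nm <- gap
  grid
}
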