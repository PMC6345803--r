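# Binding-isotherm and micropipette-aspiration fits.

#' Fit a Hill binding isotherm
#'
#' Nonlinear least-squares fit of the saturation-binding (Hill) isotherm
#' \deqn{S(c) = S_{sat} / ((K_d / c)^{n_H} + 1)}
#' to a curve of bound surface density versus bulk concentration.  Starting
#' values: \eqn{S_{sat}} = maximum density, \eqn{K_d} = concentration
#' nearest the half-maximum, \eqn{n_H = 1}; parameters are bounded below by
#' zero via a Levenberg-Marquardt fit.
#'
#' @param curve A data.frame with columns `bulk_nM` and `bound_per_um2`
#'   (see [read_binding_curve()] / [generate_binding_curve()]).
#' @param fix_hill_n Optional fixed Hill coefficient; if supplied only
#'   \eqn{S_{sat}} and \eqn{K_d} are fitted.
#' @return A list of class `"hill_fit"`: `S_sat`, `Kd_nM`, `hill_n`, their
#'   standard errors in `se`, and the underlying `nls` fit.
#' @examples
#' bc <- generate_binding_curve(3500, 88, 2, conc_nM = c(10, 25, 50, 90, 150, 250),
#'                              cv = 0, seed = 1)
#' fit_hill(bc)$Kd_nM  # exact: 88
#' @export
fit_hill <- function(curve, fix_hill_n = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("bulk_nM", "bound_per_um2") %in% names(curve)))
  x <- curve$bulk_nM
  y <- curve$bound_per_um2
  if (any(x <= 0)) stop("bulk concentrations must be positive", call. = FALSE)
  if (length(x) < 4)
    warning("fewer than 4 points: Hill fit is poorly constrained")
  ymax <- max(y)
  if (!any(y < ymax / 2) || !any(y > ymax / 2))
    warning("densities do not span both sides of half-saturation")
  start <- list(S_sat = ymax, Kd = x[which.min(abs(y - ymax / 2))])
  if (is.null(fix_hill_n)) {
    start$h <- 1
    fit <- minpack.lm::nlsLM(
      y ~ S_sat / ((Kd / x)^h + 1), start = start,
      lower = c(S_sat = 1e-12, Kd = 1e-6, h = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    stopifnot(is.numeric(fix_hill_n), fix_hill_n > 0)
    h <- fix_hill_n
    fit <- minpack.lm::nlsLM(
      y ~ S_sat / ((Kd / x)^h + 1), start = start,
      lower = c(S_sat = 1e-12, Kd = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(
    list(S_sat = unname(cf["S_sat"]), Kd_nM = unname(cf["Kd"]),
         hill_n = if (is.null(fix_hill_n)) unname(cf["h"]) else fix_hill_n,
         se = se, fixed_n = !is.null(fix_hill_n), fit = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: S_sat = %.4g, Kd = %.4g nM, n = %.3g%s\n",
              x$S_sat, x$Kd_nM, x$hill_n, if (x$fixed_n) " (fixed)" else ""))
  invisible(x)
}

#' Bending modulus from low-tension micropipette aspiration
#'
#' In the entropic (thermal-fluctuation) regime the projected area of an
#' aspirated vesicle grows logarithmically with tension,
#' \deqn{\ln(\sigma/\sigma_0) \approx (8\pi\kappa / k_bT)\,\Delta A/A_0,}
#' so a linear regression of \eqn{\ln(\sigma/\sigma_0)} on the relative
#' projected area over the low-tension subset yields the bending modulus
#' \eqn{\kappa = slope/(8\pi)} in \eqn{k_bT}.  The choice of
#' \eqn{\sigma_0} only shifts the intercept.
#'
#' @param series A data.frame with columns `tension_N_per_m` and `rel_area`
#'   (see [read_aspiration_series()] / [generate_aspiration_series()]).
#' @param low_tension_cutoff Upper tension bound of the fluctuation regime,
#'   N/m.  Default 5e-4 (0.5 mN/m).
#' @return A list of class `"kappa_fit"`: `kappa_kT`, `se_kT`, `n_points`,
#'   `sigma0`, and the `lm` fit.
#' @export
fit_bending_modulus <- function(series, low_tension_cutoff = 5e-4) {
  stopifnot(is.data.frame(series),
            all(c("tension_N_per_m", "rel_area") %in% names(series)))
  sub <- series[series$tension_N_per_m <= low_tension_cutoff, ]
  if (nrow(sub) < 4)
    stop("need at least 4 points at or below the low-tension cutoff",
         call. = FALSE)
  if (any(sub$tension_N_per_m <= 0))
    stop("tensions must be positive", call. = FALSE)
  sigma0 <- attr(series, "sigma0")
  if (is.null(sigma0)) sigma0 <- min(sub$tension_N_per_m)
  fit <- stats::lm(log(tension_N_per_m / sigma0) ~ rel_area, data = sub)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("estimation failure: non-positive semi-log slope", call. = FALSE)
  se_slope <- summary(fit)$coefficients[2, 2]
  structure(
    list(kappa_kT = slope / (8 * pi), se_kT = se_slope / (8 * pi),
         n_points = nrow(sub), sigma0 = sigma0, fit = fit),
    class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("Bending modulus: %.3g kT (se %.2g) from %d low-tension points\n",
              x$kappa_kT, x$se_kT, x$n_points))
  invisible(x)
}

#' Stretching modulus from high-tension aspiration
#'
#' In the area-dilation regime the relative projected area grows linearly
#' with tension, \eqn{\Delta A/A_0 = \sigma/K_a + const}, so a linear fit
#' of `rel_area` against tension over the high-tension subset gives the
#' stretching (area-dilation) modulus \eqn{K_a = 1/slope}.
#'
#' @inheritParams fit_bending_modulus
#' @param high_tension_cutoff Lower tension bound of the dilation regime,
#'   N/m.  Default 1.5e-3 (1.5 mN/m, comfortably above the typical
#'   bending-to-stretching crossover).
#' @return A list of class `"ka_fit"`: `Ka_mN_per_m`, `se_mN_per_m`,
#'   `n_points`, and the `lm` fit.
#' @export
fit_stretching_modulus <- function(series, high_tension_cutoff = 1.5e-3) {
  stopifnot(is.data.frame(series),
            all(c("tension_N_per_m", "rel_area") %in% names(series)))
  sub <- series[series$tension_N_per_m >= high_tension_cutoff, ]
  if (nrow(sub) < 3)
    stop("need at least 3 points at or above the high-tension cutoff",
         call. = FALSE)
  sigma_mN <- sub$tension_N_per_m * 1e3
  fit <- stats::lm(sub$rel_area ~ sigma_mN)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("estimation failure: non-positive area-tension slope", call. = FALSE)
  se_slope <- summary(fit)$coefficients[2, 2]
  structure(
    list(Ka_mN_per_m = 1 / slope, se_mN_per_m = se_slope / slope^2,
         n_points = nrow(sub), fit = fit),
    class = "ka_fit")
}

#' @export
print.ka_fit <- function(x, ...) {
  cat(sprintf("Stretching modulus: %.3g mN/m (se %.2g) from %d points\n",
              x$Ka_mN_per_m, x$se_mN_per_m, x$n_points))
  invisible(x)
}

#' Membrane tension from micropipette aspiration
#'
#' Laplace-law tension of a vesicle held in a micropipette:
#' \deqn{\sigma = \Delta P\,R_p / (2 (1 - R_p/R_v)),}
#' with \eqn{\Delta P} the applied suction pressure, \eqn{R_p} the pipette
#' radius and \eqn{R_v} the vesicle radius.
#'
#' @param delta_P_Pa Suction pressure, Pa (vectorised, >= 0).
#' @param R_pipette_um Pipette radius, µm.
#' @param R_vesicle_um Vesicle radius, µm (must exceed the pipette radius).
#' @return Membrane tension, N/m.
#' @examples
#' tension_from_aspiration(100, 3, 15)  # 1.875e-4 N/m
#' @export
tension_from_aspiration <- function(delta_P_Pa, R_pipette_um, R_vesicle_um) {
  stopifnot(is.numeric(delta_P_Pa), is.numeric(R_pipette_um),
            is.numeric(R_vesicle_um))
  if (any(delta_P_Pa < 0)) stop("'delta_P_Pa' must be >= 0", call. = FALSE)
  if (any(R_pipette_um <= 0) || any(R_pipette_um >= R_vesicle_um))
    stop("need 0 < R_pipette < R_vesicle", call. = FALSE)
  delta_P_Pa * (R_pipette_um * 1e-6) / (2 * (1 - R_pipette_um / R_vesicle_um))
}
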