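# Seeded synthetic-data generators emulating the inputs of the estimators:
# 2D worm-like-chain conformations, Hill binding curves, two-regime
# aspiration series, spiky quasi-circular vesicle contours and sinusoidal
# wavy substrates.  Each generator is a pure function of its arguments and
# seed (identical seeds give identical output) and restores the caller's
# RNG state.

#' Simulate 2D worm-like-chain filament conformations
#'
#' Discrete tangent-angle random walk: along each chain the tangent angle
#' accumulates i.i.d. Gaussian increments of variance `step_nm / Lp_nm` per
#' step, which yields the 2D worm-like-chain tangent correlation
#' \eqn{\langle\cos\theta(L)\rangle = \exp(-L / (2 L_p))}.  Each chain is an
#' independent conformation (one frame, one filament id).
#'
#' @param Lp_nm Persistence length, nm.
#' @param contour_nm Contour length per chain, nm.
#' @param step_nm Discretisation step, nm.  Default `Lp_nm / 100`; a step
#'   above `Lp_nm / 10` triggers a discretisation-bias warning.
#' @param n_chains Number of independent conformations.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A data.frame of class `"filament_tracks"` with columns `frame`,
#'   `filament_id`, `point_index`, `x_nm`, `y_nm`.
#' @examples
#' trk <- generate_wlc(8000, 1e4, n_chains = 5, seed = 1)
#' fit_persistence_length(tangent_correlation(trk), min_count = 5)
#' @export
generate_wlc <- function(Lp_nm, contour_nm, step_nm = Lp_nm / 100,
                         n_chains = 1, seed = NULL) {
  stopifnot(Lp_nm > 0, contour_nm > 0, step_nm > 0, n_chains >= 1)
  if (step_nm >= Lp_nm / 10)
    warning("step_nm >= Lp_nm/10: tangent-angle discretisation bias")
  n_seg <- max(3L, as.integer(round(contour_nm / step_nm)))
  with_seed(seed, {
    pieces <- lapply(seq_len(n_chains), function(i) {
      theta0 <- stats::runif(1, 0, 2 * pi)
      ang <- theta0 + cumsum(c(0, stats::rnorm(n_seg - 1, 0,
                                               sqrt(step_nm / Lp_nm))))
      x <- cumsum(c(0, step_nm * cos(ang)))
      y <- cumsum(c(0, step_nm * sin(ang)))
      data.frame(frame = i, filament_id = i,
                 point_index = seq_along(x), x_nm = x, y_nm = y)
    })
    out <- do.call(rbind, pieces)
    class(out) <- c("filament_tracks", "data.frame")
    out
  })
}

#' Simulate a Hill binding curve with multiplicative noise
#'
#' Evaluates the Hill isotherm on a concentration grid and applies
#' multiplicative Gaussian noise of coefficient of variation `cv`,
#' truncated at zero.
#'
#' @param S_sat Saturation surface density, \eqn{\mu m^{-2}}.
#' @param Kd_nM Dissociation constant, nM.
#' @param hill_n Hill coefficient.
#' @param conc_nM Bulk-concentration grid, nM (strictly increasing).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.05; 0 gives the exact curve).
#' @param seed Integer seed.
#' @return A data.frame of class `"binding_curve"` with columns `bulk_nM`
#'   and `bound_per_um2`.
#' @export
generate_binding_curve <- function(S_sat, Kd_nM, hill_n = 1, conc_nM,
                                   cv = 0.05, seed = NULL) {
  stopifnot(S_sat > 0, Kd_nM > 0, hill_n > 0, cv >= 0,
            all(conc_nM > 0), all(diff(conc_nM) > 0))
  y0 <- S_sat / ((Kd_nM / conc_nM)^hill_n + 1)
  with_seed(seed, {
    y <- pmax(0, y0 * (1 + stats::rnorm(length(y0), 0, cv)))
    out <- data.frame(bulk_nM = conc_nM, bound_per_um2 = y)
    class(out) <- c("binding_curve", "data.frame")
    out
  })
}

#' Simulate a micropipette tension-area aspiration series
#'
#' Combines the low-tension entropic branch and the high-tension
#' area-dilation branch,
#' \deqn{\Delta A/A_0 = \frac{1}{8\pi\kappa}\ln(\sigma/\sigma_0)
#'   + \frac{\sigma}{K_a} + \varepsilon,}
#' with additive Gaussian area noise.  `Ka_mN_per_m = Inf` (the default)
#' generates the pure fluctuation regime assumed by
#' [fit_bending_modulus()]; `kappa_kT = Inf` gives the pure stretching law.
#' The volume channel is constant (aspiration conserves vesicle volume).
#'
#' @param kappa_kT Bending modulus, \eqn{k_bT}.
#' @param Ka_mN_per_m Stretching modulus, mN/m (default `Inf`).
#' @param sigma_N_per_m Sorted positive tension grid, N/m.
#' @param sigma0 Reference tension, N/m.  Default `min(sigma_N_per_m)`.
#' @param noise_sd Standard deviation of the additive area noise
#'   (dimensionless, on \eqn{\Delta A/A_0}).  Default 2e-4.
#' @param seed Integer seed.
#' @return A data.frame of class `"aspiration_series"` with columns
#'   `tension_N_per_m`, `rel_area`, `rel_volume` (all zero) and attribute
#'   `sigma0`.
#' @export
generate_aspiration_series <- function(kappa_kT, Ka_mN_per_m = Inf,
                                       sigma_N_per_m,
                                       sigma0 = min(sigma_N_per_m),
                                       noise_sd = 2e-4, seed = NULL) {
  stopifnot(kappa_kT > 0, Ka_mN_per_m > 0, noise_sd >= 0,
            all(sigma_N_per_m > 0), !is.unsorted(sigma_N_per_m),
            sigma0 > 0)
  bend <- if (is.finite(kappa_kT))
    log(sigma_N_per_m / sigma0) / (8 * pi * kappa_kT) else 0
  stretch <- if (is.finite(Ka_mN_per_m))
    sigma_N_per_m / (Ka_mN_per_m * 1e-3) else 0
  with_seed(seed, {
    rel_area <- bend + stretch +
      stats::rnorm(length(sigma_N_per_m), 0, noise_sd)
    out <- data.frame(tension_N_per_m = sigma_N_per_m,
                      rel_area = rel_area,
                      rel_volume = 0)
    attr(out, "sigma0") <- sigma0
    class(out) <- c("aspiration_series", "data.frame")
    out
  })
}

#' Generate a spiky quasi-circular vesicle contour
#'
#' Constructs a closed contour of a spiky vesicle as circular-arc valleys
#' of exactly the requested concave osculating radius, joined by straight
#' tangent flanks rising to sharp spike tips of exactly the requested
#' amplitude above the valley radius.  The spike count is
#' `round(2*pi*base_radius_um / period_um)`; the realised periodicity is
#' therefore the base circumference divided by that count.  Optional
#' radial Gaussian jitter emulates contour-digitisation noise.
#'
#' @param base_radius_um Valley (baseline) radius of the vesicle, µm.
#' @param amplitude_um Spike height above the baseline, µm (0 gives a
#'   plain circle).
#' @param period_um Target inter-spike distance along the base circle, µm.
#' @param concave_radius_um Osculating radius of the valley arcs, µm.
#' @param n_points Total number of contour points.  Default 2000.
#' @param jitter_sd Radial jitter standard deviation, µm.  Default 0.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @return A data.frame of class `"vesicle_contour"` with columns `x_um`,
#'   `y_um`, and attributes `n_spikes` and `realized_period_um`.
#' @examples
#' ct <- generate_spiky_contour(10, 0.9, 3.9, 1 / 1.1, seed = 7)
#' attr(ct, "n_spikes")  # 16
#' @export
generate_spiky_contour <- function(base_radius_um = 10, amplitude_um = 0.9,
                                   period_um = 3.9,
                                   concave_radius_um = 1 / 1.1,
                                   n_points = 2000, jitter_sd = 0,
                                   seed = NULL) {
  stopifnot(base_radius_um > 0, amplitude_um >= 0, period_um > 0,
            concave_radius_um > 0, n_points >= 64, jitter_sd >= 0)
  if (period_um >= 2 * pi * base_radius_um)
    stop("'period_um' must be smaller than the base circumference",
         call. = FALSE)
  if (amplitude_um >= base_radius_um)
    stop("'amplitude_um' must be smaller than the base radius", call. = FALSE)
  rv <- base_radius_um
  if (amplitude_um == 0) {
    ang <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    xy <- cbind(rv * cos(ang), rv * sin(ang))
    return(finish_contour(xy, 0L, NA_real_, jitter_sd, seed))
  }
  m <- max(2L, as.integer(round(2 * pi * rv / period_um)))
  delta <- 2 * pi / m
  Rc <- concave_radius_um
  rt <- rv + amplitude_um
  d <- rv + Rc
  tip <- c(rt, 0)
  ctr <- d * c(cos(delta / 2), sin(delta / 2))
  v <- tip - ctr
  L2 <- sqrt(sum(v^2))
  if (L2 <= Rc)
    stop("infeasible spike geometry: tip lies inside the valley circle",
         call. = FALSE)
  gam <- acos(Rc / L2)
  u <- v / L2
  rot <- function(w, a) c(cos(a) * w[1] - sin(a) * w[2],
                          sin(a) * w[1] + cos(a) * w[2])
  cand <- list(ctr + Rc * rot(u, gam), ctr + Rc * rot(u, -gam))
  ang_of <- function(p) atan2(p[2], p[1])
  # the correct tangent point sits between tip and valley directions and
  # below the tip radius (the flank must descend from the tip)
  ok <- vapply(cand, function(p) {
    a <- ang_of(p)
    a > 0 && a < delta / 2 && sqrt(sum(p^2)) < rt
  }, logical(1))
  if (!any(ok))
    stop("infeasible spike geometry: flanks and valley arcs cannot join",
         call. = FALSE)
  P <- cand[[which(ok)[1]]]
  M <- (d - Rc) * c(cos(delta / 2), sin(delta / 2))  # valley bottom
  aP <- ang_of(P - ctr)
  aM <- ang_of(M - ctr)
  sweep <- (aM - aP + pi) %% (2 * pi) - pi  # short way round
  # equal point budget for flank and valley arc: contour digitisation
  # concentrates samples where curvature is high, and it keeps the short
  # valley arcs well resolved for the osculating-circle measurement
  n_half <- max(8L, as.integer(round(n_points / (2 * m))))
  nf <- max(4L, as.integer(floor(n_half / 2)))
  na <- max(4L, n_half - nf)
  tf <- seq(0, 1, length.out = nf + 1)[-(nf + 1)]     # tip .. just before P
  flank <- cbind(tip[1] + tf * (P[1] - tip[1]),
                 tip[2] + tf * (P[2] - tip[2]))
  ta <- seq(0, 1, length.out = na + 1)[-(na + 1)]     # P .. just before M
  arc_ang <- aP + ta * sweep
  arc <- cbind(ctr[1] + Rc * cos(arc_ang), ctr[2] + Rc * sin(arc_ang))
  half1 <- rbind(flank, arc)
  # mirror about the mid-valley ray to build the second half-period
  ref <- matrix(c(cos(delta), sin(delta), sin(delta), -cos(delta)), 2, 2)
  half2 <- rbind(M, half1[nrow(half1):2, , drop = FALSE]) %*% ref
  period_pts <- rbind(half1, half2)
  xy <- do.call(rbind, lapply(seq_len(m) - 1, function(j) {
    a <- j * delta
    Rj <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2, byrow = TRUE)
    period_pts %*% t(Rj)
  }))
  finish_contour(xy, m, 2 * pi * rv / m, jitter_sd, seed)
}

finish_contour <- function(xy, n_spikes, realized_period, jitter_sd, seed) {
  if (jitter_sd > 0) {
    xy <- with_seed(seed, {
      r <- sqrt(rowSums(xy^2))
      jit <- stats::rnorm(nrow(xy), 0, jitter_sd)
      xy * (1 + jit / r)
    })
  }
  out <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
  attr(out, "n_spikes") <- n_spikes
  attr(out, "realized_period_um") <- realized_period
  class(out) <- c("vesicle_contour", "data.frame")
  out
}

#' Sinusoidal wavy substrate and its curvature field
#'
#' Height profile \eqn{h(x) = A_0 \sin(2\pi x / \lambda_0)} over one
#' period, with the signed curvature field
#' \eqn{c(x) = -h'' / (1 + h'^2)^{3/2}} so that crests (hills) are positive
#' and troughs (valleys) negative, matching the adsorption model's
#' convention.  In the small-slope limit the extremal curvature magnitude
#' is \eqn{A_0 (2\pi/\lambda_0)^2}.
#'
#' @param A0_um Amplitude, µm.
#' @param lambda0_um Period, µm.
#' @param n_points Number of sample points over one period.  Default 1024.
#' @return An object of class `"wavy_substrate"`: a list with the profile
#'   data.frame (`x_um`, `h_um`, `curvature_per_um`), the extremal
#'   curvatures `c_crest_per_um` / `c_trough_per_um`, and the inputs.
#' @export
generate_wavy_substrate <- function(A0_um, lambda0_um, n_points = 1024) {
  stopifnot(A0_um >= 0, lambda0_um > 0, n_points >= 16)
  x <- seq(0, lambda0_um, length.out = n_points)
  k <- 2 * pi / lambda0_um
  h <- A0_um * sin(k * x)
  hp <- A0_um * k * cos(k * x)
  hpp <- -A0_um * k^2 * sin(k * x)
  curv <- -hpp / (1 + hp^2)^1.5
  structure(
    list(profile = data.frame(x_um = x, h_um = h, curvature_per_um = curv),
         c_crest_per_um = max(curv), c_trough_per_um = min(curv),
         A0_um = A0_um, lambda0_um = lambda0_um),
    class = "wavy_substrate")
}

#' @export
print.wavy_substrate <- function(x, ...) {
  cat(sprintf("Wavy substrate: A0 = %g um, period = %g um, curvature %g to %g um^-1\n",
              x$A0_um, x$lambda0_um, x$c_trough_per_um, x$c_crest_per_um))
  invisible(x)
}
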