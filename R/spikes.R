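# Spike-geometry quantification of closed 2D vesicle contours: amplitude,
# inter-spike periodicity and concave osculating radius between spikes.

#' Measure spike geometry on a closed vesicle contour
#'
#' Unwraps a closed 2D contour into a polar radius profile about its
#' centroid, detects spikes as prominent local maxima, and quantifies the
#' deformation the way spiky septin-decorated vesicles are measured:
#' \itemize{
#'   \item amplitude `A` = mean over spikes of the peak radius minus the
#'     baseline (mean radius at the two flanking minima);
#'   \item periodicity `lambda` = mean inter-spike distance, taken as the
#'     angular separation of consecutive peaks times the median contour
#'     radius;
#'   \item concave radius `R` = mean osculating radius at the inter-spike
#'     minima, from a local quadratic (tangent-frame) curvature fit over a
#'     symmetric window of the smoothed contour.
#' }
#' The method requires the contour to be star-shaped about its centroid
#' (single-valued radius profile); the measurement is invariant to
#' rotation, translation and cyclic re-indexing of the points.
#'
#' @param contour A data.frame or two-column matrix of `x_um`, `y_um`
#'   points tracing the closed contour once (closure implied; >= 64 points).
#' @param smooth_window Circular moving-average window (points) applied to
#'   the radius profile and coordinates before peak detection.  Default 5.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   median radius.  Default 0.05.
#' @param fit_window Half-width (points) of the osculating-circle fit
#'   window at each inter-spike minimum.  The default (`NULL`) adapts to
#'   the local spike spacing: 40% of the gap to the nearest flanking peak,
#'   which keeps the window inside the concave valley while spanning
#'   enough of it to average out digitisation noise.
#' @return An object of class `"spike_stats"`: a list with `n_spikes`,
#'   `amplitude_um`, `period_um`, `concave_radius_um`,
#'   `concave_curvature_per_um` (mean reciprocal osculating radius) and the
#'   detected `peak_idx` / `valley_idx` (into the angular ordering).  With
#'   fewer than 2 detected spikes the geometric statistics are `NA`.
#' @examples
#' ct <- generate_spiky_contour(seed = 1)
#' measure_spikes(ct)
#' @export
measure_spikes <- function(contour, smooth_window = 5, prominence_frac = 0.05,
                           fit_window = NULL) {
  xy <- as.matrix(as.data.frame(contour)[, 1:2])
  storage.mode(xy) <- "double"
  if (nrow(xy) < 64)
    stop("contour must have at least 64 points", call. = FALSE)
  if (anyNA(xy)) stop("contour contains missing coordinates", call. = FALSE)
  ctr <- colMeans(xy)
  dx <- xy[, 1] - ctr[1]
  dy <- xy[, 2] - ctr[2]
  phi <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) stop("contour passes through its centroid", call. = FALSE)
  if (anyDuplicated(phi))
    stop("contour is not simple: duplicated polar angles about the centroid",
         call. = FALSE)
  # star-shapedness: traversing the original point order must wind exactly once
  dphi <- diff(c(phi, phi[1]))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  if (abs(abs(sum(dphi)) - 2 * pi) > 1e-6)
    stop("contour is not simple/star-shaped about its centroid", call. = FALSE)

  ord <- order(phi)
  phi <- phi[ord]; r <- r[ord]; xy <- xy[ord, , drop = FALSE]
  n <- length(r)
  rs <- circ_movavg(r, smooth_window)
  xs <- circ_movavg(xy[, 1], smooth_window)
  ys <- circ_movavg(xy[, 2], smooth_window)

  peaks <- find_circular_peaks(rs, prominence_frac * stats::median(rs))
  if (length(peaks) < 2) {
    return(structure(list(n_spikes = length(peaks), amplitude_um = NA_real_,
                          period_um = NA_real_, concave_radius_um = NA_real_,
                          concave_curvature_per_um = NA_real_,
                          peak_idx = peaks, valley_idx = integer(0)),
                     class = "spike_stats"))
  }
  peaks <- sort(peaks)
  k <- length(peaks)
  # deepest point between consecutive peaks (circular)
  valleys <- integer(k)
  for (j in seq_len(k)) {
    idx <- circ_between(peaks[j], peaks[if (j == k) 1L else j + 1L], n)
    if (length(idx) == 0) idx <- peaks[j]
    valleys[j] <- idx[which.min(rs[idx])]
  }
  # amplitude: peak radius minus mean of the two flanking valley radii
  amp <- vapply(seq_len(k), function(j) {
    left <- valleys[if (j == 1) k else j - 1]
    rs[peaks[j]] - 0.5 * (rs[left] + rs[valleys[j]])
  }, numeric(1))
  # periodicity: angular gaps between consecutive peaks times median radius
  dphi_pk <- diff(c(phi[peaks], phi[peaks[1]] + 2 * pi))
  lambda <- mean(dphi_pk) * stats::median(rs)
  # osculating circles at the inter-spike minima
  radii <- vapply(seq_len(k), function(j) {
    v <- valleys[j]
    w <- fit_window
    if (is.null(w)) {
      gap_next <- (peaks[if (j == k) 1L else j + 1L] - v) %% n
      gap_prev <- (v - peaks[j]) %% n
      w <- max(3L, as.integer(floor(0.4 * min(gap_prev, gap_next))))
    }
    idx <- ((v - w):(v + w) - 1L) %% n + 1L
    1 / local_curvature(cbind(xs[idx], ys[idx]))
  }, numeric(1))
  structure(
    list(n_spikes = k,
         amplitude_um = mean(amp),
         period_um = lambda,
         concave_radius_um = mean(radii),
         concave_curvature_per_um = mean(1 / radii),
         peak_idx = peaks, valley_idx = valleys),
    class = "spike_stats")
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf("Spike stats: %d spikes", x$n_spikes))
  if (x$n_spikes >= 2)
    cat(sprintf("; A = %.3g um, lambda = %.3g um, concave R = %.3g um (c = %.3g um^-1)",
                x$amplitude_um, x$period_um, x$concave_radius_um,
                x$concave_curvature_per_um))
  cat("\n")
  invisible(x)
}

# Indices strictly between a and b walking forward circularly (empty when
# adjacent).
circ_between <- function(a, b, n) {
  if (a == b) return(setdiff(seq_len(n), a))
  if (b > a) {
    if (b - a <= 1L) integer(0) else (a + 1L):(b - 1L)
  } else {
    c(if (a < n) (a + 1L):n else integer(0),
      if (b > 1L) 1:(b - 1L) else integer(0))
  }
}

# Circular local maxima filtered by topographic prominence.  Iteratively
# removes the least prominent peak until all survivors clear `min_prom`.
find_circular_peaks <- function(x, min_prom) {
  n <- length(x)
  xl <- x[c(n, 1:(n - 1))]
  xr <- x[c(2:n, 1)]
  cand <- which(x > xl & x >= xr)
  if (length(cand) == 0) return(integer(0))
  repeat {
    k <- length(cand)
    if (k == 0) return(integer(0))
    if (k == 1) {
      prom <- x[cand] - min(x)
      return(if (prom >= min_prom) cand else integer(0))
    }
    cand <- sort(cand)
    valmin <- vapply(seq_len(k), function(j) {
      idx <- circ_between(cand[j], cand[if (j == k) 1L else j + 1L], n)
      if (length(idx) == 0) x[cand[j]] else min(x[idx])
    }, numeric(1))
    prom <- vapply(seq_len(k), function(j) {
      left <- valmin[if (j == 1) k else j - 1]
      x[cand[j]] - max(left, valmin[j])
    }, numeric(1))
    if (all(prom >= min_prom)) return(cand)
    cand <- cand[-which.min(prom)]
  }
}
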