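# Persistence-length estimation from digitised 2D filament backbones:
# tangent-angle correlation <cos theta(L)> pooled over all ordered point
# pairs of all tracks, followed by a weighted semi-log fit.

split_tracks <- function(tracks) {
  if (is.data.frame(tracks)) {
    need <- c("x_nm", "y_nm")
    if (!all(need %in% names(tracks)))
      stop("track table must have columns 'x_nm' and 'y_nm'", call. = FALSE)
    key <- if (all(c("frame", "filament_id") %in% names(tracks)))
      interaction(tracks$frame, tracks$filament_id, drop = TRUE)
    else factor(rep(1, nrow(tracks)))
    if ("point_index" %in% names(tracks))
      tracks <- tracks[order(key, tracks$point_index), ]
    lapply(split(tracks[, c("x_nm", "y_nm")], key), as.matrix)
  } else if (is.list(tracks)) {
    lapply(tracks, function(m) {
      m <- as.matrix(m)
      stopifnot(ncol(m) == 2)
      m
    })
  } else stop("'tracks' must be a data.frame or a list of x/y matrices",
              call. = FALSE)
}

#' Tangent-angle correlation of filament tracks
#'
#' Computes the orientational correlation \eqn{\langle\cos\theta(L)\rangle}
#' between tangent vectors separated by arclength L, pooled with equal
#' weight over all ordered point pairs of all tracks and frames.  Tangents
#' are taken by central differences on each (optionally smoothed) polyline;
#' pairs are binned by arclength separation into bins of width `bin_width`
#' centred on multiples of it, so the first bin (L = 0, the self-pairs)
#' averages to 1 up to within-bin decorrelation.
#'
#' @param tracks Either a data.frame with columns `frame`, `filament_id`,
#'   `point_index`, `x_nm`, `y_nm` (see [read_tracks()]) or a list of
#'   two-column x/y matrices in nm, one per tracked filament conformation.
#' @param bin_width Arclength bin width, nm.
#' @param smooth_window Moving-average window (points) applied to the
#'   coordinates before differencing; 1 disables smoothing.  Smoothing and
#'   digitisation noise only rescale the correlation by a constant, which
#'   the fit's free intercept absorbs.
#' @return An object of class `"tangent_correlation"`: a data.frame with
#'   columns `L_nm` (bin centre), `mean_cos` and `count`.
#' @seealso [fit_persistence_length()]
#' @export
tangent_correlation <- function(tracks, bin_width = 100, smooth_window = 3) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  polylines <- split_tracks(tracks)
  sums <- numeric(0)
  counts <- numeric(0)
  used <- 0L
  for (pl in polylines) {
    if (nrow(pl) < 3 || any(rowSums(abs(diff(pl))) == 0)) {
      warning("skipping track with fewer than 3 distinct consecutive points")
      next
    }
    x <- movavg_open(pl[, 1], smooth_window)
    y <- movavg_open(pl[, 2], smooth_window)
    n <- length(x)
    # central-difference tangents at interior points
    tx <- x[3:n] - x[1:(n - 2)]
    ty <- y[3:n] - y[1:(n - 2)]
    nrm <- sqrt(tx^2 + ty^2)
    keep <- nrm > 0
    tx <- tx[keep] / nrm[keep]
    ty <- ty[keep] / nrm[keep]
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    s <- cumsum(c(0, seg))[2:(n - 1)][keep]
    m <- length(tx)
    if (m < 2) {
      warning("skipping track with fewer than 2 usable tangents")
      next
    }
    used <- used + 1L
    cosmat <- tcrossprod(tx) + tcrossprod(ty)      # t_i . t_j
    L <- abs(outer(s, s, "-"))
    iu <- upper.tri(L, diag = TRUE)
    bin <- as.integer(round(L[iu] / bin_width)) + 1L
    nb <- max(bin)
    if (nb > length(sums)) {
      sums <- c(sums, numeric(nb - length(sums)))
      counts <- c(counts, numeric(nb - length(counts)))
    }
    sums[seq_len(nb)] <- sums[seq_len(nb)] + tapply_sum(cosmat[iu], bin, nb)
    counts[seq_len(nb)] <- counts[seq_len(nb)] + tabulate(bin, nb)
  }
  if (used == 0L)
    stop("no usable tracks (all skipped)", call. = FALSE)
  keep <- counts > 0
  out <- data.frame(L_nm = (which(keep) - 1L) * bin_width,
                    mean_cos = sums[keep] / counts[keep],
                    count = counts[keep])
  class(out) <- c("tangent_correlation", "data.frame")
  out
}

tapply_sum <- function(v, idx, nbin) {
  out <- numeric(nbin)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Persistence length from a tangent correlation
#'
#' Fits \eqn{\ln\langle\cos\theta\rangle = b_0 - L/(2 L_p)} by weighted
#' least squares (weights = pair counts) over bins with positive, not yet
#' decorrelated signal, and returns \eqn{L_p = -(d-1)/(2\,slope)} for
#' filaments fluctuating in d = 2 dimensions.  The free intercept absorbs
#' the constant attenuation introduced by smoothing and tangent noise.
#'
#' @param corr A [tangent_correlation()] object.
#' @param min_cos Bins with `mean_cos` at or below this value are excluded
#'   (keeps the log well away from its noise floor).  Default 0.2.
#' @param min_count Minimum pair count per bin.  Default 50.
#' @param fit_range Optional numeric length-2 arclength interval (nm)
#'   overriding the automatic bin selection.
#' @return A list of class `"lp_fit"`: `Lp_nm`, `se_nm`, `slope`,
#'   `intercept`, `n_bins`, and the underlying `lm` fit.
#' @export
fit_persistence_length <- function(corr, min_cos = 0.2, min_count = 50,
                                   fit_range = NULL) {
  stopifnot(inherits(corr, "tangent_correlation") || is.data.frame(corr))
  sel <- corr$mean_cos > max(min_cos, 0) & corr$count >= min_count
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2)
    sel <- corr$L_nm >= fit_range[1] & corr$L_nm <= fit_range[2] &
      corr$mean_cos > 0
    if (any(corr$L_nm >= fit_range[1] & corr$L_nm <= fit_range[2] &
            corr$mean_cos <= 0)) {
      warning("bins with nonpositive mean_cos inside 'fit_range' dropped")
    }
  }
  if (sum(sel) < 3)
    stop("fewer than 3 usable bins for the persistence-length fit",
         call. = FALSE)
  d <- corr[sel, ]
  fit <- stats::lm(log(mean_cos) ~ L_nm, data = d, weights = d$count)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("estimation failure: non-negative semi-log slope (no decay); ",
         "tracks may be too straight or too short", call. = FALSE)
  se_slope <- summary(fit)$coefficients[2, 2]
  Lp <- -1 / (2 * slope)
  structure(
    list(Lp_nm = Lp, se_nm = se_slope / (2 * slope^2),
         slope = slope, intercept = unname(stats::coef(fit)[1]),
         n_bins = nrow(d), fit = fit),
    class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("Persistence length: %.1f nm (se %.1f nm) from %d bins\n",
              x$Lp_nm, x$se_nm, x$n_bins))
  invisible(x)
}
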