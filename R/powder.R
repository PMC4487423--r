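#' Locate and fit powder diffraction rings
#'
#' The camera length is best calibrated against the ring spacing of a
#' known powder pattern (gold, graphite).  This routine computes the
#' radial intensity profile about the given centre, picks the `n_rings`
#' most prominent peaks, extracts the azimuthal ridge of each ring by
#' per-sector radial centroiding, and fits an ellipse to the ridge
#' points.  The ellipticity of the fitted rings doubles as an
#' astigmatism check: a well-aligned microscope gives circles.
#'
#' @param image Numeric pixel matrix.
#' @param center Beam centre `(x, y)` in pixels.
#' @param n_rings Number of rings to look for.  Fewer may be found; the
#'   result reports how many.
#' @param sectors Number of azimuthal sectors for ridge extraction
#'   (default 256, balancing angular resolution against per-sector
#'   counts).
#' @param ridge_halfwidth Radial half-window around each peak used for
#'   centroiding, pixels.
#' @param min_radius Ignore peaks closer to the centre than this
#'   (direct-beam region), pixels.
#' @param min_prominence Peak prominence threshold in robust standard
#'   deviations of the detrended profile; rings weaker than this are
#'   not reported (a blank image yields zero rings, not an error).
#' @return A tibble of class `ring_fits`, sorted by mean radius, with
#'   columns `radius` (geometric mean of the semi-axes, px),
#'   `semi_major`, `semi_minor`, `ellipticity` (a/b >= 1), `center_x`,
#'   `center_y`, `angle` (major-axis azimuth, degrees), `residual` (RMS
#'   radial misfit, px), `n_points`, `failed`, `assigned_d` (NA until
#'   [calibrate_distance()]).
#' @export
fit_powder_rings <- function(image, center, n_rings, sectors = 256,
                             ridge_halfwidth = 10, min_radius = 10,
                             min_prominence = 8) {
  check_frame(image, "image")
  if (length(center) != 2L || any(center < 1) ||
      center[1] > nrow(image) || center[2] > ncol(image))
    me_stop("`center` must be (x, y) within the image", "invalid_argument")
  d <- dim(image)
  dx <- (seq_len(d[1]) - center[1])
  dy <- (seq_len(d[2]) - center[2])
  r <- sqrt(outer(dx^2, dy^2, `+`))
  theta <- atan2(rep(dy, each = d[1]), rep(dx, times = d[2]))
  rbin <- as.integer(round(r)) + 1L
  prof <- as.vector(tapply(as.vector(image), rbin, mean))
  radii_axis <- sort(unique(rbin)) - 1L
  # Detrend with a wide running median so only ring-scale peaks remain.
  k <- min(length(prof) - (1 - length(prof) %% 2), 51L)
  bg <- stats::runmed(prof, k)
  det <- prof - bg
  noise <- stats::mad(det)
  rmax_use <- max(r) - ridge_halfwidth  # rings may reach into the corners
  is_peak <- c(FALSE, det[-c(1, length(det))] >= det[-(1:2)] &
                 det[-c(1, length(det))] > det[-((length(det) - 1):length(det))],
               FALSE) &
    det > min_prominence * max(noise, 1e-6) &
    radii_axis > min_radius & radii_axis < rmax_use
  peaks <- radii_axis[is_peak]
  heights <- det[is_peak]
  # Greedy strongest-first selection with a minimum separation.
  sel <- integer(0)
  for (i in order(heights, decreasing = TRUE)) {
    if (length(sel) >= n_rings) break
    if (all(abs(peaks[i] - peaks[sel]) > ridge_halfwidth))
      sel <- c(sel, i)
  }
  peaks <- sort(peaks[sel])
  rows <- lapply(peaks, function(r0)
    fit_one_ring(image, center, r, theta, r0, sectors, ridge_halfwidth))
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    radius = numeric(0), semi_major = numeric(0), semi_minor = numeric(0),
    ellipticity = numeric(0), center_x = numeric(0), center_y = numeric(0),
    angle = numeric(0), residual = numeric(0), n_points = integer(0),
    failed = logical(0), assigned_d = numeric(0))
  out <- out[order(out$radius), ]
  class(out) <- c("ring_fits", class(out))
  out
}

fit_one_ring <- function(image, center, r, theta, r0, sectors, hw) {
  sel <- abs(r - r0) <= hw
  ring_r <- r[sel]; ring_t <- theta[sel]; ring_i <- image[sel]
  # Local background from the annulus edges, per the whole ring.
  edge <- abs(ring_r - r0) >= 0.7 * hw
  bg <- stats::median(ring_i[edge])
  w <- pmax(ring_i - bg, 0)
  sec <- pmin(floor((ring_t + pi) / (2 * pi) * sectors) + 1L, sectors)
  wsum <- tapply(w, sec, sum)
  rcent <- tapply(w * ring_r, sec, sum) / wsum
  ok <- is.finite(rcent) & wsum > 0
  sec_mid <- (as.numeric(names(wsum)) - 0.5) / sectors * 2 * pi - pi
  px <- center[1] + rcent[ok] * cos(sec_mid[ok])
  py <- center[2] + rcent[ok] * sin(sec_mid[ok])
  fit <- if (sum(ok) >= 8) try(fit_ellipse(px, py), silent = TRUE) else NULL
  if (is.null(fit) || inherits(fit, "try-error") || !is.list(fit)) {
    return(tibble::tibble(
      radius = r0, semi_major = NA_real_, semi_minor = NA_real_,
      ellipticity = NA_real_, center_x = NA_real_, center_y = NA_real_,
      angle = NA_real_, residual = NA_real_, n_points = sum(ok),
      failed = TRUE, assigned_d = NA_real_))
  }
  # RMS radial misfit of the ridge points against the fitted ellipse.
  tt <- atan2(py - fit$cy, px - fit$cx)
  rell <- ellipse_radius(fit, tt)
  res <- sqrt(mean((sqrt((px - fit$cx)^2 + (py - fit$cy)^2) - rell)^2))
  tibble::tibble(
    radius = sqrt(fit$a * fit$b), semi_major = fit$a, semi_minor = fit$b,
    ellipticity = fit$a / fit$b, center_x = fit$cx, center_y = fit$cy,
    angle = rad2deg(fit$phi), residual = res, n_points = sum(ok),
    failed = FALSE, assigned_d = NA_real_)
}

# Direct least-squares ellipse fit (Fitzgibbon-style, via the generalized
# eigenproblem of the quadratic/linear scatter blocks).
fit_ellipse <- function(x, y) {
  x0 <- mean(x); y0 <- mean(y)
  xs <- x - x0; ys <- y - y0
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # Apply inv(C) for constraint 4ac - b^2 = 1.
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  i <- which(cond > 0)
  if (!length(i)) stop("no elliptical solution")
  a1 <- V[, i[1]]
  coef <- c(a1, Tm %*% a1)  # A B C D E F in centred coordinates
  conic_to_ellipse(coef, x0, y0)
}

conic_to_ellipse <- function(k, x0, y0) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C          # < 0 for an ellipse
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  phi <- 0.5 * atan2(B, A - C)
  # Resolve the 90-degree axis ambiguity: the conic must vanish at the
  # major-axis endpoint (cx + a cos(phi), cy + a sin(phi)).
  conic_at <- function(p) {
    px <- cx + a * cos(p); py <- cy + a * sin(p)
    abs(A * px^2 + B * px * py + C * py^2 + D * px + E * py + F)
  }
  if (conic_at(phi + pi / 2) < conic_at(phi)) phi <- phi + pi / 2
  list(cx = cx + x0, cy = cy + y0, a = a, b = b,
       phi = ((phi + pi / 2) %% pi) - pi / 2)
}

ellipse_radius <- function(fit, theta) {
  ct <- cos(theta - fit$phi); st <- sin(theta - fit$phi)
  fit$a * fit$b / sqrt((fit$b * ct)^2 + (fit$a * st)^2)
}

#' Calibrate the virtual sample-detector distance from powder rings
#'
#' Each ring of known d-spacing observed at radius `r` gives an
#' independent camera length `D_i = r / tan(2 arcsin(lambda / 2 d))`.
#' Rings and d-spacings are matched in order (largest d to smallest
#' radius); the returned distance is the residual-weighted mean and the
#' per-ring relative residuals are reported.  A residual spread above
#' `warn_spread` raises a `calibration_inconsistent` warning — usually a
#' wrong d-spacing list or a badly wrong wavelength.
#'
#' @param rings A `ring_fits` tibble from [fit_powder_rings()], or a
#'   numeric vector of ring radii in pixels.
#' @param d_spacings Known lattice spacings in ångström, one per ring.
#' @param wavelength Electron wavelength in ångström.
#' @param pixel_size Pixel side length in millimetres.
#' @param warn_spread Relative residual spread that triggers the
#'   inconsistency warning (default 0.02).
#' @return Object of class `distance_calibration`: `distance` (mm),
#'   `per_ring` tibble (radius_px, d, distance_i, rel_residual),
#'   `wavelength`, `pixel_size`.
#' @export
calibrate_distance <- function(rings, d_spacings, wavelength, pixel_size,
                               warn_spread = 0.02) {
  radii_px <- if (inherits(rings, "ring_fits")) {
    ok <- !rings$failed
    rings$radius[ok]
  } else as.numeric(rings)
  residuals <- if (inherits(rings, "ring_fits")) rings$residual[!rings$failed]
    else rep(0, length(radii_px))
  check_scalar(wavelength, "wavelength", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (length(radii_px) != length(d_spacings))
    me_stop(sprintf(
      "cannot assign %d ring(s) to %d d-spacing(s); counts must match",
      length(radii_px), length(d_spacings)), "assignment_error")
  if (any(d_spacings <= wavelength / 2))
    me_stop("d-spacings at or below lambda/2 are unreachable",
            "unreachable_resolution")
  ord_r <- order(radii_px)
  ord_d <- order(d_spacings, decreasing = TRUE)  # largest d <-> smallest r
  radii_px <- radii_px[ord_r]; residuals <- residuals[ord_r]
  d_spacings <- d_spacings[ord_d]
  two_theta <- 2 * asin(wavelength / (2 * d_spacings))
  D_i <- radii_px * pixel_size / tan(two_theta)
  w <- 1 / (pmax(residuals, 0)^2 + 0.01^2)  # residual-weighted; px^2 floor
  D <- sum(w * D_i) / sum(w)
  rel <- D_i / D - 1
  if (max(abs(rel)) > warn_spread)
    me_warn(sprintf(
      "per-ring distances disagree (max relative residual %.3g > %.3g); check the d-spacing assignment",
      max(abs(rel)), warn_spread), "calibration_inconsistent")
  structure(
    list(distance = D,
         per_ring = tibble::tibble(radius_px = radii_px, d = d_spacings,
                                   distance_i = D_i, rel_residual = rel),
         wavelength = wavelength, pixel_size = pixel_size),
    class = "distance_calibration")
}

#' @export
print.distance_calibration <- function(x, ...) {
  cat(sprintf("<distance_calibration> D = %.3f mm from %d ring(s), max |rel res| %.2e\n",
              x$distance, nrow(x$per_ring), max(abs(x$per_ring$rel_residual))))
  invisible(x)
}
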