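#' Estimate the detector gain from background statistics
#'
#' After gain correction, processing programs treat detector noise as
#' Poisson, for which the variance equals the mean.  The gain is
#' therefore estimated as the ratio of the variance and the mean of the
#' intensities in a sufficiently large region of background pixels:
#' if the recorded value is `g` times an underlying Poisson count, the
#' statistic equals `g`.  The region must exclude Bragg spots (the
#' caller's responsibility, aided by the two-sided trimming switch).
#'
#' @param image Numeric pixel matrix.
#' @param region Rectangle `c(x0, y0, x1, y1)` in 1-based inclusive
#'   pixel coordinates, or `NULL` for the whole image.
#' @param trim Two-sided trimming fraction applied before the statistic
#'   (default 0.01), guarding against stray spots and zingers; set to 0
#'   to disable.
#' @param min_pixels Minimum region size (default 1e4); smaller regions
#'   give too noisy an estimate.
#' @return Object of class `gain_estimate` with fields `gain`, `mean`,
#'   `variance`, `n_pixels`, `region`, `trim`.
#' @export
estimate_gain <- function(image, region = NULL, trim = 0.01,
                          min_pixels = 1e4) {
  check_frame(image, "image")
  if (is.null(region)) region <- c(1, 1, nrow(image), ncol(image))
  if (length(region) != 4L || any(region < 1) ||
      region[3] > nrow(image) || region[4] > ncol(image) ||
      region[1] > region[3] || region[2] > region[4])
    me_stop("`region` must be c(x0, y0, x1, y1) within the image",
            "invalid_argument")
  vals <- as.vector(image[region[1]:region[3], region[2]:region[4]])
  if (length(vals) < min_pixels)
    me_stop(sprintf("region holds %d pixels; at least %d are required",
                    length(vals), min_pixels), "invalid_argument")
  correction <- 1
  if (trim > 0) {
    q <- stats::quantile(vals, c(trim, 1 - trim), names = FALSE)
    vals <- vals[vals >= q[1] & vals <= q[2]]
    # Symmetric trimming deflates the variance; at background count
    # levels the distribution is near-Gaussian, for which the exact
    # truncation factor is 1 - 2 z phi(z) / (1 - 2 alpha).
    z <- stats::qnorm(1 - trim)
    correction <- 1 - 2 * z * stats::dnorm(z) / (1 - 2 * trim)
  }
  m <- mean(vals)
  v <- stats::var(vals) / correction
  if (!is.finite(m) || m <= 0 || v == 0)
    me_stop(sprintf(
      "degenerate background region (mean %.4g, variance %.4g): cannot form variance/mean",
      m, v), "degenerate_input")
  structure(
    list(gain = v / m, region = region, n_pixels = length(vals),
         mean = m, variance = v, trim = trim),
    class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf(
    "<gain_estimate> g = %.4f (variance %.2f / mean %.2f over %d px)\n",
    x$gain, x$variance, x$mean, x$n_pixels))
  invisible(x)
}

#' Refine the direct-beam position from a single image
#'
#' A diffraction pattern is (to a good approximation) symmetric under
#' inversion through the direct beam — Friedel symmetry.  The refined
#' centre is the point `c` maximising the correlation between the image
#' and its copy rotated 180° about `c`.  The score for every candidate
#' on a half-pixel grid is obtained at once through the autoconvolution
#' identity `sum_x I(x) I(s - x)`, which peaks at `s = 2c`, computed by
#' FFT and normalised to a correlation; the maximum is then refined to
#' sub-pixel precision by quadratic interpolation of the score surface.
#'
#' @param image Numeric pixel matrix.
#' @param initial Initial centre estimate `(x, y)` in pixels (the image
#'   centre is a good starting point when the beam was centred on the
#'   screen).
#' @param search_radius Maximum allowed shift from `initial`, pixels.
#' @param mask Optional logical matrix of pixels to exclude (beam-stop
#'   shadow etc.).
#' @param min_score Minimum symmetry correlation below which the image
#'   is declared featureless.
#' @return Numeric `c(x, y)` sub-pixel centre, with attributes `score`
#'   (peak symmetry correlation) and `boundary` (`TRUE` when the
#'   maximum sat on the search boundary — enlarge `search_radius`).
#' @export
refine_beam_center <- function(image, initial, search_radius = 10,
                               mask = NULL, min_score = 0.15) {
  check_frame(image, "image")
  if (length(initial) != 2L || any(initial < 1) ||
      initial[1] > nrow(image) || initial[2] > ncol(image))
    me_stop("`initial` must be (x, y) within the image", "invalid_argument")
  check_scalar(search_radius, "search_radius", positive = TRUE)
  d <- dim(image)
  keep <- if (is.null(mask)) rep(TRUE, length(image)) else !as.vector(mask)
  J <- image - mean(image[keep])
  if (!is.null(mask)) J[mask] <- 0
  # Zero-pad to avoid circular wrap; s = x + x' lives on a (2n-1) grid.
  P <- 2 * d
  pad <- function(m) { z <- matrix(0, P[1], P[2]); z[1:d[1], 1:d[2]] <- m; z }
  F1 <- stats::fft(pad(J))
  num <- Re(stats::fft(F1 * F1, inverse = TRUE)) / prod(P)
  M <- matrix(as.numeric(keep), d[1], d[2])
  energy <- Re(stats::fft(stats::fft(pad(J^2 * M)) * stats::fft(pad(M)),
                          inverse = TRUE)) / prod(P)
  score <- num / pmax(energy, 1e-9)
  # Candidate centres c = s/2 with s (1-based array index) = x + x' - 1.
  s_idx <- function(c_, n) 2 * c_ - 1
  win <- list(
    x = pmax(2, floor(s_idx(initial[1] - search_radius))):
        pmin(2 * d[1] - 2, ceiling(s_idx(initial[1] + search_radius))),
    y = pmax(2, floor(s_idx(initial[2] - search_radius))):
        pmin(2 * d[2] - 2, ceiling(s_idx(initial[2] + search_radius))))
  sub <- score[win$x, win$y]
  peak <- arrayInd(which.max(sub), dim(sub))
  best <- max(sub)
  if (!is.finite(best) || best < min_score)
    me_stop(sprintf(
      "no inversion-symmetry signal (peak score %.3f < %.3f): featureless image?",
      best, min_score), "no_signal")
  ix <- win$x[peak[1]]; iy <- win$y[peak[2]]
  boundary <- peak[1] %in% c(1L, length(win$x)) ||
              peak[2] %in% c(1L, length(win$y))
  if (boundary)
    me_warn("symmetry maximum on the search boundary; consider a larger search_radius",
            "boundary_warning")
  # Quadratic (parabolic) sub-grid interpolation along each axis of s.
  interp <- function(a, b, c_) {
    den <- a - 2 * b + c_
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (a - c_) / den))
  }
  dx <- interp(score[ix - 1, iy], score[ix, iy], score[ix + 1, iy])
  dy <- interp(score[ix, iy - 1], score[ix, iy], score[ix, iy + 1])
  centre <- c(x = (ix + dx + 1) / 2, y = (iy + dy + 1) / 2)
  attr(centre, "score") <- best
  attr(centre, "boundary") <- boundary
  centre
}

#' Detect dead, hot and erratic pixels from temporal statistics
#'
#' The camera does not flag malfunctioning pixels, but a stack of frames
#' reveals them.  Per pixel, the temporal median and a robust spread
#' (scaled median absolute deviation) are computed; then
#' * **hot**: the pixel's median exceeds the detector-wide median by
#'   more than `hot_sigma` robust deviations, persistently (in >= 80%
#'   of the frames);
#' * **dead**: the pixel's median is at or below `dead_floor` while the
#'   detector-wide median is above it;
#' * **erratic**: the temporal spread exceeds `hot_sigma` times the
#'   Poisson spread expected from the local signal level,
#'   `sqrt(gain * median)`.
#'
#' The mask is reproducible given identical inputs and invariant under
#' frame order.
#'
#' @param stack A [frame_stack()] with at least 3 frames.
#' @param hot_sigma Threshold in robust standard deviations (default 6;
#'   conservative, and exposed because such cuts are inherently ad hoc).
#' @param dead_floor Counts at or below which a pixel is dead
#'   (default 0).
#' @param gain Detector gain used for the expected Poisson spread.
#' @return Object of class `bad_pixel_mask`: logical `mask` matrix,
#'   tibble `categories` (x, y, category), and the `params` used.
#' @export
detect_bad_pixels <- function(stack, hot_sigma = 6, dead_floor = 0,
                              gain = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n < 3L)
    me_stop(sprintf("temporal statistics need >= 3 frames (got %d)", n),
            "insufficient_data")
  d <- stack$native_dimensions
  npx <- prod(d)
  m <- vapply(stack$frames, as.vector, numeric(npx))
  med <- apply(m, 1L, stats::median)
  spread <- 1.4826 * apply(abs(m - med), 1L, stats::median)
  det_med <- stats::median(med)
  det_mad <- stats::mad(med)
  # Guard against a zero detector-wide MAD on noiseless synthetic input.
  scale <- max(det_mad, sqrt(max(det_med * gain, 1)) / sqrt(n), 1e-9)
  hot_thr <- det_med + hot_sigma * scale
  persist <- rowMeans(m > hot_thr)
  hot <- med > hot_thr & persist >= 0.8
  dead <- med <= dead_floor & det_med > dead_floor
  erratic <- spread > hot_sigma * sqrt(pmax(med, 1) * gain) & !hot & !dead
  hot <- hot & !dead
  flagged <- hot | dead | erratic
  mask <- matrix(flagged, d[1], d[2])
  idx <- which(flagged)
  categories <- tibble::tibble(
    x = ((idx - 1L) %% d[1]) + 1L,
    y = ((idx - 1L) %/% d[1]) + 1L,
    category = ifelse(hot[idx], "hot", ifelse(dead[idx], "dead", "erratic")))
  structure(
    list(mask = mask, categories = categories,
         params = list(hot_sigma = hot_sigma, dead_floor = dead_floor,
                       gain = gain, n_frames = n)),
    class = "bad_pixel_mask")
}

#' @export
print.bad_pixel_mask <- function(x, ...) {
  tab <- table(factor(x$categories$category,
                      levels = c("hot", "dead", "erratic")))
  cat(sprintf("<bad_pixel_mask> %d flagged of %d px (hot %d, dead %d, erratic %d)\n",
              sum(x$mask), length(x$mask), tab[["hot"]], tab[["dead"]],
              tab[["erratic"]]))
  invisible(x)
}

#' Write or read a pixel mask as an 8-bit image with provenance sidecar
#'
#' Masks travel as single-frame 8-bit TIFF images (0 = good,
#' 1 = excluded) plus a plain-text `.provenance.txt` sidecar recording
#' the parameters that produced them.
#'
#' @param mask Logical matrix, or a `bad_pixel_mask`.
#' @param path Output image path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  prov <- NULL
  if (inherits(mask, "bad_pixel_mask")) {
    prov <- mask$params
    mask <- mask$mask
  }
  tiff::writeTIFF(t(mask) * (1 / 255), path, bits.per.sample = 8L)
  side <- paste0(path, ".provenance.txt")
  lines <- c(sprintf("# microed %s mask", utils::packageVersion("microed")),
             sprintf("n_excluded=%d", sum(mask)))
  if (!is.null(prov))
    lines <- c(lines, sprintf("%s=%s", names(prov), unlist(prov)))
  writeLines(lines, side)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  t(m) > 0
}
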