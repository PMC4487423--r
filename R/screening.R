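#' Find Bragg spots on a diffraction image
#'
#' A simple robust spot finder supporting sweep screening: the local
#' background is estimated from per-tile medians, per-pixel significance
#' is computed under the gain-corrected Poisson model
#' (`sigma = sqrt(gain * background)`), pixels above `min_snr` are
#' grouped into connected regions, and regions of at least `min_pixels`
#' are reported with intensity-weighted centroids.
#'
#' @param image Numeric pixel matrix (or an [smv_image()]).
#' @param gain Detector gain (> 0) relating counts to quanta.
#' @param min_snr Per-pixel significance threshold (default 4).
#' @param min_pixels Minimum connected-region size (default 3) —
#'   isolated noise excursions are rejected.
#' @param mask Optional logical exclusion matrix (beam stop, bad
#'   pixels); `TRUE` pixels are ignored.
#' @param tile Tile size for the background grid, pixels.
#' @return Tibble with one row per spot: `x`, `y` (sub-pixel centroid),
#'   `intensity` (background-subtracted sum), `background` (counts per
#'   pixel), `n_pixels`, `max_snr`; sorted by intensity, strongest
#'   first.  Empty on a blank image — never an error.
#' @export
find_spots <- function(image, gain = 1, min_snr = 4, min_pixels = 3,
                       mask = NULL, tile = 32) {
  if (inherits(image, "smv_image")) image <- image$pixels
  check_frame(image, "image")
  check_scalar(gain, "gain", positive = TRUE)
  d <- dim(image)
  bg <- tile_background(image, tile)
  sig <- (image - bg) / sqrt(gain * pmax(bg, 1))
  cand <- sig > min_snr
  if (!is.null(mask)) cand[mask] <- FALSE
  if (!any(cand)) return(empty_spot_table())
  labels <- EBImage::bwlabel(matrix(as.numeric(cand), d[1], d[2]))
  idx <- which(cand)
  lab <- labels[idx]
  size <- tabulate(lab)
  keep_lab <- which(size >= min_pixels)
  if (!length(keep_lab)) return(empty_spot_table())
  xs <- ((idx - 1L) %% d[1]) + 1L
  ys <- ((idx - 1L) %/% d[1]) + 1L
  w <- pmax(image[idx] - bg[idx], 0)
  rows <- lapply(keep_lab, function(l) {
    s <- lab == l
    ws <- w[s]
    tibble::tibble(
      x = sum(ws * xs[s]) / sum(ws),
      y = sum(ws * ys[s]) / sum(ws),
      intensity = sum(ws),
      background = mean(bg[idx][s]),
      n_pixels = sum(s),
      max_snr = max(sig[idx][s]))
  })
  out <- do.call(rbind, rows)
  out[order(out$intensity, decreasing = TRUE), ]
}

empty_spot_table <- function() {
  tibble::tibble(x = numeric(0), y = numeric(0), intensity = numeric(0),
                 background = numeric(0), n_pixels = integer(0),
                 max_snr = numeric(0))
}

# Per-tile median background, expanded back to full resolution.
tile_background <- function(image, tile) {
  d <- dim(image)
  tx <- (seq_len(d[1]) - 1L) %/% tile + 1L
  ty <- (seq_len(d[2]) - 1L) %/% tile + 1L
  fx <- rep(tx, times = d[2])
  fy <- rep(ty, each = d[1])
  g <- tapply(as.vector(image), list(fx, fy), stats::median)
  matrix(g[cbind(as.character(fx), as.character(fy))], d[1], d[2])
}

#' Assess whether a sweep supports autoindexing
#'
#' Autoindexing needs the periodicity of the lattice to be apparent in
#' three dimensions: enough spots per image, and images spanning a wide
#' enough wedge of reciprocal space.  For continuous-rotation data a
#' practical rule is that five to ten images spanning a roughly 20°
#' wedge suffice without prior knowledge of the cell.  This check
#' operationalises that rule: `sufficient` when at least `min_frames`
#' frames each showing at least `min_spots` spots together span at
#' least `min_span` degrees; `marginal` when all criteria pass at
#' `marginal_factor` (default 80%) of their thresholds; `insufficient`
#' otherwise, with every failing criterion named.  The paper-scale
#' defaults (5 frames, 18°, 10 spots) are heuristics, not physics, and
#' are all exposed.
#'
#' @param spot_counts Integer vector of spots per frame (e.g.
#'   `nrow(find_spots(...))` per frame).
#' @param rotation A [rotation_model()].  Stills sweeps get
#'   `wedge_span = 0` and an explanatory reason.
#' @param timings A [frame_timings()] tibble aligned with
#'   `spot_counts`.
#' @param min_frames,min_span,min_spots,marginal_factor Thresholds as
#'   described above.
#' @return Object of class `wedge_assessment`: `n_frames` (qualifying
#'   at the strict spot threshold), `wedge_span` (degrees), `verdict`,
#'   `reasons`, `spots_per_frame`, `thresholds`.
#' @export
assess_indexability <- function(spot_counts, rotation, timings,
                                min_frames = 5, min_span = 18,
                                min_spots = 10, marginal_factor = 0.8) {
  stopifnot(inherits(rotation, "rotation_model"))
  if (length(spot_counts) != nrow(timings))
    me_stop("`spot_counts` and `timings` must be aligned", "invalid_argument")
  span_of <- function(qualify) {
    if (!any(qualify)) return(0)
    i <- range(which(qualify))
    abs(rotation$rate) * (timings$timestamp[i[2]] + timings$exposure[i[2]] -
                            timings$timestamp[i[1]])
  }
  verdict_at <- function(f_spots, f_frames, f_span) {
    qual <- spot_counts >= ceiling(f_spots * min_spots)
    n <- sum(qual)
    span <- span_of(qual)
    list(ok = n >= ceiling(f_frames * min_frames) & span >= f_span * min_span,
         n = n, span = span, qual = qual)
  }
  if (rotation$rate == 0) {
    strict <- verdict_at(1, 1, 1)
    return(new_wedge_assessment(
      strict$n, 0, spot_counts, "insufficient",
      "stills-mode sweep (rotation rate 0): no wedge is swept",
      min_frames, min_span, min_spots))
  }
  strict <- verdict_at(1, 1, 1)
  relaxed <- verdict_at(marginal_factor, marginal_factor, marginal_factor)
  reasons <- character(0)
  if (strict$n < min_frames)
    reasons <- c(reasons, sprintf(
      "only %d frame(s) with >= %d spots (need %d)",
      strict$n, min_spots, min_frames))
  if (strict$span < min_span)
    reasons <- c(reasons, sprintf(
      "qualifying frames span %.1f degrees (need %g)",
      strict$span, min_span))
  verdict <- if (strict$ok) "sufficient"
    else if (relaxed$ok) "marginal" else "insufficient"
  new_wedge_assessment(strict$n, strict$span, spot_counts, verdict,
                       reasons, min_frames, min_span, min_spots)
}

new_wedge_assessment <- function(n, span, counts, verdict, reasons,
                                 min_frames, min_span, min_spots) {
  structure(
    list(n_frames = n, wedge_span = span, spots_per_frame = counts,
         verdict = verdict, reasons = reasons,
         thresholds = list(min_frames = min_frames, min_span = min_span,
                           min_spots = min_spots)),
    class = "wedge_assessment")
}

#' @export
print.wedge_assessment <- function(x, ...) {
  cat(sprintf("<wedge_assessment> %s: %d qualifying frame(s), %.1f degree wedge\n",
              toupper(x$verdict), x$n_frames, x$wedge_span))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Extract the rocking curve of a reflection across a sweep
#'
#' A reflection rotating through its diffracting condition leaves a
#' unimodal intensity trace across successive frames.  Per frame the
#' intensity in a box around the spot is summed, the local background
#' (perimeter median times the box area) subtracted, and the Poisson
#' sigma propagated through the gain.  Each frame is placed at its
#' mid-exposure angle (symmetric under rotation reversal), and a
#' Gaussian with constant offset is fitted to give the peak position
#' and FWHM.
#'
#' @param frames List of pixel matrices or [smv_image()]s (>= 3).
#' @param location Spot position `(x, y)` in pixels.
#' @param box Half-width of the integration box, pixels (the box is
#'   `2 box + 1` on a side and must fit inside the frames).
#' @param rotation A [rotation_model()].
#' @param timings A [frame_timings()] tibble aligned with `frames`.
#' @param gain Detector gain; intensities are gain-corrected (quanta)
#'   and sigmas propagated through it.
#' @param mask Optional logical exclusion matrix; overlap with the box
#'   raises a `partial_coverage` warning.
#' @return Object of class `rocking_curve`: `curve` tibble
#'   (frame_index, phi_mid, intensity, sigma), `peak_phi`, `fwhm`,
#'   `flags` (may contain `"flat"` when no frame shows signal, or
#'   `"single_frame"` when only one does — the FWHM is then only
#'   upper-bounded by one frame's rotation range).
#' @export
extract_rocking_curve <- function(frames, location, box = 5, rotation,
                                  timings, gain = 1, mask = NULL) {
  stopifnot(inherits(rotation, "rotation_model"))
  frames <- lapply(frames, function(f)
    if (inherits(f, "smv_image")) f$pixels else f)
  if (length(frames) < 3L)
    me_stop("a rocking curve needs >= 3 frames", "insufficient_data")
  if (length(frames) != nrow(timings))
    me_stop("`frames` and `timings` must be aligned", "invalid_argument")
  d <- dim(frames[[1]])
  x0 <- round(location[1]); y0 <- round(location[2])
  if (x0 - box - 1 < 1 || x0 + box + 1 > d[1] ||
      y0 - box - 1 < 1 || y0 + box + 1 > d[2])
    me_stop("integration box (plus perimeter) does not fit inside the frames",
            "invalid_argument")
  xr <- (x0 - box):(x0 + box); yr <- (y0 - box):(y0 + box)
  xp <- (x0 - box - 1):(x0 + box + 1); yp <- (y0 - box - 1):(y0 + box + 1)
  if (!is.null(mask) && any(mask[xp, yp]))
    me_warn("integration box overlaps the exclusion mask; intensities are partial",
            "partial_coverage")
  n_box <- length(xr) * length(yr)
  rot <- frame_rotation(rotation, timings)
  vals <- vapply(frames, function(fr) {
    boxv <- fr[xr, yr]
    per <- fr[xp, yp]
    per_vals <- c(per[1, ], per[nrow(per), ], per[-c(1, nrow(per)), 1],
                  per[-c(1, nrow(per)), ncol(per)])
    bg <- stats::median(per_vals)
    # Gain-corrected: intensities in quanta, sigma by Poisson propagation.
    c((sum(boxv) - bg * n_box) / gain, sqrt(max(sum(boxv), 1) / gain))
  }, numeric(2))
  curve <- tibble::tibble(frame_index = timings$index,
                          phi_mid = rot$phi_mid,
                          intensity = vals[1, ], sigma = vals[2, ])
  flags <- character(0)
  signal <- curve$intensity > 3 * curve$sigma
  if (!any(signal)) {
    flags <- "flat"
    peak <- NA_real_; fwhm <- NA_real_
  } else if (sum(signal) == 1L) {
    flags <- "single_frame"
    peak <- curve$phi_mid[signal]
    fwhm <- abs(rot$osc_range[signal])  # upper bound: one frame's range
  } else {
    fit <- fit_gaussian_curve(curve$phi_mid, curve$intensity, curve$sigma)
    peak <- fit$mu
    fwhm <- 2 * sqrt(2 * log(2)) * fit$sd
  }
  structure(list(curve = curve, peak_phi = peak, fwhm = fwhm,
                 flags = flags),
            class = "rocking_curve")
}

# Gaussian + constant offset, weighted least squares; moment start
# values, nls refinement with a moment fallback.
fit_gaussian_curve <- function(phi, I, sigma) {
  w <- 1 / sigma^2
  off0 <- min(I)
  Ip <- pmax(I - off0, 0)
  mu0 <- sum(phi * Ip) / sum(Ip)
  sd0 <- sqrt(sum((phi - mu0)^2 * Ip) / sum(Ip))
  sd0 <- max(sd0, min(diff(sort(phi))) / 4)
  fit <- try(suppressWarnings(stats::nls(
    I ~ A * exp(-(phi - mu)^2 / (2 * s^2)) + c0,
    start = list(A = max(Ip), mu = mu0, s = sd0, c0 = off0),
    weights = w, control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (!inherits(fit, "try-error")) {
    p <- stats::coef(fit)
    if (is.finite(p[["mu"]]) && is.finite(p[["s"]]) && p[["s"]] > 0)
      return(list(mu = unname(p[["mu"]]), sd = abs(unname(p[["s"]]))))
  }
  list(mu = mu0, sd = sd0)
}

#' @export
print.rocking_curve <- function(x, ...) {
  if (length(x$flags) && x$flags[1] == "flat") {
    cat("<rocking_curve> flat: no frame shows significant signal\n")
  } else {
    cat(sprintf("<rocking_curve> peak at phi = %.3f deg, FWHM %.3f deg over %d frame(s)%s\n",
                x$peak_phi, x$fwhm, nrow(x$curve),
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}
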