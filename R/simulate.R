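#' Virtual crystal for the diffraction simulator
#'
#' A reciprocal lattice with an orientation in the stage frame, a
#' Gaussian rocking width (mosaicity), a resolution limit and an
#' overall intensity scale.  Reflection intensities are drawn from a
#' Wilson-like exponential distribution, which gives a realistic
#' dynamic range without computing structure factors — the simulator is
#' a geometry oracle, not a physics engine.
#'
#' The laboratory frame: beam along +z, stage tilt axis along +x, so an
#' untilted plate crystal grown with its c axis normal to the grid has
#' c along the beam (`orientation = diag(3)`).
#'
#' @param cell Unit cell `c(a, b, c, alpha, beta, gamma)` in ångström
#'   and degrees.
#' @param orientation 3x3 rotation matrix taking crystal axes into the
#'   stage frame.
#' @param mosaicity Gaussian rocking half-width (sd) in degrees.
#' @param resolution_limit Highest resolution simulated, ångström.
#' @param intensity_scale Mean full reflection intensity, counts.
#' @return Object of class `virtual_crystal` (with the reciprocal-space
#'   orthogonalisation matrix precomputed in `$B`).
#' @export
virtual_crystal <- function(cell = c(76, 76, 37, 90, 90, 90),
                            orientation = diag(3), mosaicity = 0.2,
                            resolution_limit = 3.0,
                            intensity_scale = 2000) {
  if (length(cell) != 6L || any(cell[1:3] <= 0) ||
      any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    me_stop("`cell` must be c(a, b, c, alpha, beta, gamma)", "invalid_argument")
  if (!all(dim(orientation) == c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    me_stop("`orientation` must be a 3x3 rotation matrix", "invalid_argument")
  check_scalar(mosaicity, "mosaicity", nonneg = TRUE)
  check_scalar(resolution_limit, "resolution_limit", positive = TRUE)
  check_scalar(intensity_scale, "intensity_scale", positive = TRUE)
  structure(
    list(cell = cell, orientation = orientation, mosaicity = mosaicity,
         resolution_limit = resolution_limit,
         intensity_scale = intensity_scale,
         B = reciprocal_basis(cell)),
    class = "virtual_crystal")
}

#' Rotation matrix from an axis and an angle
#'
#' Convenience for building crystal orientations: the right-handed
#' rotation by `angle_deg` about `axis` (Rodrigues formula).  A crystal
#' dropped on a grid sits in a generic orientation; simulating with the
#' identity instead leaves whole zones exactly in the Ewald plane at
#' phi = 0, which no real measurement ever sees.
#'
#' @param axis Length-3 rotation axis (need not be normalised).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle_deg) {
  if (length(axis) != 3L || all(axis == 0))
    me_stop("`axis` must be a non-zero length-3 vector", "invalid_argument")
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Busing-Levy B matrix: columns are a*, b*, c* in an orthonormal frame
# with c along z for right-angled cells.
reciprocal_basis <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  V <- a * b * cc * sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                           2 * cos(al) * cos(be) * cos(ga))
  as_ <- b * cc * sin(al) / V
  bs_ <- a * cc * sin(be) / V
  cs_ <- a * b * sin(ga) / V
  cos_bes <- (cos(al) * cos(ga) - cos(be)) / (sin(al) * sin(ga))
  cos_gas <- (cos(al) * cos(be) - cos(ga)) / (sin(al) * sin(be))
  sin_gas <- sqrt(1 - cos_gas^2)
  sin_bes <- sqrt(1 - cos_bes^2)
  matrix(c(as_, 0, 0,
           bs_ * cos_gas, bs_ * sin_gas, 0,
           cs_ * cos_bes, -cs_ * sin_bes * cos(al), 1 / cc),
         3, 3)
}

#' Simulation configuration
#'
#' Everything about the virtual experiment except the crystal.  The
#' seed is mandatory: the simulator has no implicit randomness, so a
#' given configuration is bit-reproducible.
#'
#' @param geometry An [experiment_geometry()].
#' @param rotation A [rotation_model()].
#' @param n_frames Number of frames in the sweep.
#' @param exposure Exposure per frame, seconds.
#' @param background_mean Mean background level in quanta per pixel
#'   (before gain).
#' @param gain Detector gain applied after Poisson noise.
#' @param seed Integer RNG seed (required).
#' @param spot_sigma Rendered spot width (Gaussian sd) in pixels.
#' @param min_partial Smallest partial fraction of a reflection that is
#'   still rendered and recorded in the ground truth.
#' @param low_res_limit Reflections at lower resolution than this (in
#'   ångström) are skipped: they would fall on the direct beam.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry, rotation, n_frames, exposure,
                              background_mean = 20, gain = 2, seed,
                              spot_sigma = 1.5, min_partial = 0.01,
                              low_res_limit = 25) {
  stopifnot(inherits(geometry, "experiment_geometry"),
            inherits(rotation, "rotation_model"))
  if (missing(seed) || !is_scalar_num(seed))
    me_stop("`seed` is mandatory: the simulator has no implicit randomness",
            "invalid_argument")
  if (!is_scalar_num(n_frames) || n_frames < 1)
    me_stop("`n_frames` must be >= 1", "invalid_argument")
  check_scalar(exposure, "exposure", positive = TRUE)
  check_scalar(background_mean, "background_mean", nonneg = TRUE)
  check_scalar(gain, "gain", positive = TRUE)
  structure(
    list(geometry = geometry, rotation = rotation,
         n_frames = as.integer(n_frames), exposure = exposure,
         background_mean = background_mean, gain = gain,
         seed = as.integer(seed), spot_sigma = spot_sigma,
         min_partial = min_partial, low_res_limit = low_res_limit),
    class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Reflections of `crystal` within the resolution shell, as a list of
# q vectors (3 x N, reciprocal angstrom, stage frame at phi = 0) and hkl.
enumerate_reflections <- function(crystal, low_res_limit = Inf) {
  dmin <- crystal$resolution_limit
  hmax <- ceiling(crystal$cell[1:3] / dmin)
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                               k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  q <- crystal$orientation %*% (crystal$B %*% t(hkl))
  qlen <- sqrt(colSums(q^2))
  keep <- qlen <= 1 / dmin & qlen >= 1 / low_res_limit
  list(hkl = hkl[keep, , drop = FALSE], q = q[, keep, drop = FALSE],
       qlen = qlen[keep])
}

# Tilt angles (degrees) at which a reflection crosses the flat Ewald
# plane q_z = 0 under rotation about the x (tilt) axis.  Two crossings
# per full turn; both are returned in (-180, 180].
crossing_angles <- function(q) {
  phi1 <- rad2deg(atan2(-q[3, ], q[2, ]))
  phi2 <- ((phi1 + 180) %% 360)
  phi2[phi2 > 180] <- phi2[phi2 > 180] - 360
  rbind(phi1, phi2)
}

# Effective Gaussian rocking width (sd, degrees): mosaicity combined in
# quadrature with the bandpass-equivalent angular width.
effective_rocking_sd <- function(crystal, beam, qlen) {
  theta <- asin(pmin(1, beam$wavelength * qlen / 2))
  band <- rad2deg(beam$bandpass * tan(theta))
  sqrt(crystal$mosaicity^2 + band^2)
}

#' Simulate a continuous-rotation diffraction sweep
#'
#' For each frame, every reciprocal-lattice point inside the resolution
#' shell whose flat-Ewald crossing angle falls (within the effective
#' rocking width — mosaicity and bandpass in quadrature) inside the
#' frame's rotation interval is projected onto the detector through the
#' small-angle flat-wedge geometry and rendered as a 2-D Gaussian spot.
#' The frame-integrated intensity of a reflection follows a Gaussian
#' rocking profile across phi, so its partial intensities over
#' contiguous frames sum to the full intensity.  Poisson noise is
#' applied to signal plus background and the result multiplied by the
#' gain, giving integer frames whose background obeys
#' variance/mean = gain.  Deterministic given the seed.
#'
#' The flat-Ewald (planar-wedge) projection is the appropriate model at
#' electron wavelengths: at 0.025 Å and 2 Å resolution the sphere
#' departs from the plane by far less than a pixel.
#'
#' @param crystal A [virtual_crystal()].
#' @param config A [simulation_config()].
#' @return List with `stack` (a [frame_stack()]) and `truth` (class
#'   `ground_truth`): per-frame spot records (`spots`: frame, hkl,
#'   detector position, pre-noise partial intensity, crossing angle),
#'   `full_intensities` per reflection, the applied geometry/rotation,
#'   and an empty `defect_map` (see [inject_defects()]).
#' @export
simulate_sweep <- function(crystal, config) {
  stopifnot(inherits(crystal, "virtual_crystal"),
            inherits(config, "simulation_config"))
  geom <- config$geometry; rot <- config$rotation
  timings <- frame_timings(config$n_frames, config$exposure,
                           readout_gap = rot$readout_gap)
  fr <- frame_rotation(rot, timings)
  phi_lo <- pmin(fr$osc_start, fr$osc_start + rot$rate * timings$exposure)
  phi_hi <- pmax(fr$osc_start, fr$osc_start + rot$rate * timings$exposure)
  if (max(abs(c(phi_lo, phi_hi))) > rot$tilt_limit)
    me_stop(sprintf(
      "sweep reaches %.1f degrees, beyond the +-%g degree stage limit",
      max(abs(c(phi_lo, phi_hi))), rot$tilt_limit), "stage_limit")
  refl <- enumerate_reflections(crystal, config$low_res_limit)
  nref <- ncol(refl$q)
  # Friedel mates share one intensity: I(hkl) = I(-h-k-l).
  key <- apply(refl$hkl, 1, paste, collapse = ",")
  key_mate <- apply(-refl$hkl, 1, paste, collapse = ",")
  canonical <- pmin(key, key_mate)
  uniq <- unique(canonical)
  with_seed(config$seed, {
    I_uniq <- crystal$intensity_scale * stats::rexp(length(uniq))
    I_full <- I_uniq[match(canonical, uniq)]
    sigma_phi <- effective_rocking_sd(crystal, geom$beam, refl$qlen)
    cross <- crossing_angles(refl$q)
    spot_rows <- list()
    expected <- vector("list", config$n_frames)
    lambda <- geom$beam$wavelength
    d <- geom$dimensions
    for (i in seq_len(config$n_frames)) {
      frame_exp <- matrix(config$background_mean, d[1], d[2])
      for (pass in 1:2) {
        phis <- cross[pass, ]
        partial <- stats::pnorm(phi_hi[i], phis, sigma_phi) -
          stats::pnorm(phi_lo[i], phis, sigma_phi)
        sel <- which(partial >= config$min_partial)
        if (!length(sel)) next
        pos <- project_flat_wedge(refl$q[, sel, drop = FALSE],
                                  phis[sel], geom)
        on_det <- pos$x > 3 & pos$x < d[1] - 2 & pos$y > 3 & pos$y < d[2] - 2
        sel <- sel[on_det]
        if (!length(sel)) next
        px <- pos$x[on_det]; py <- pos$y[on_det]
        counts <- I_full[sel] * partial[sel]
        frame_exp <- render_spots(frame_exp, px, py, counts,
                                  config$spot_sigma)
        spot_rows[[length(spot_rows) + 1L]] <- tibble::tibble(
          frame = i, h = refl$hkl[sel, 1], k = refl$hkl[sel, 2],
          l = refl$hkl[sel, 3], pass = pass, x = px, y = py,
          intensity = counts, partial = partial[sel],
          phi_star = phis[sel], d_spacing = 1 / refl$qlen[sel])
      }
      expected[[i]] <- frame_exp
    }
    frames <- lapply(expected, function(ex) {
      v <- config$gain * stats::rpois(length(ex), as.vector(ex))
      matrix(as.integer(pmin(v, 65535)), d[1], d[2])
    })
  })
  spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    tibble::tibble(frame = integer(0), h = integer(0), k = integer(0),
                   l = integer(0), pass = integer(0), x = numeric(0),
                   y = numeric(0), intensity = numeric(0),
                   partial = numeric(0), phi_star = numeric(0),
                   d_spacing = numeric(0))
  truth <- structure(
    list(spots = spots,
         full_intensities = tibble::tibble(
           h = refl$hkl[, 1], k = refl$hkl[, 2], l = refl$hkl[, 3],
           intensity = I_full, sigma_phi = sigma_phi,
           phi_cross_1 = cross[1, ], phi_cross_2 = cross[2, ],
           d_spacing = 1 / refl$qlen),
         geometry = geom, rotation = rot, timings = timings,
         config = config, defect_map = empty_defect_map()),
    class = "ground_truth")
  list(stack = frame_stack(frames, timings, bit_depth = 16,
                           source_format = "memory"),
       truth = truth)
}

# Project reflections onto the detector at their crossing angle.  In the
# flat-wedge geometry the in-plane scattering vector fixes the azimuth
# and |q| fixes 2theta; the radius is D tan(2theta).
project_flat_wedge <- function(q, phi_deg, geom) {
  p <- deg2rad(phi_deg)
  qx <- q[1, ]
  qy <- q[2, ] * cos(p) - q[3, ] * sin(p)
  qlen <- sqrt(colSums(q^2))
  two_theta <- 2 * asin(pmin(1, geom$beam$wavelength * qlen / 2))
  r_mm <- geom$distance * tan(two_theta)
  qperp <- pmax(sqrt(qx^2 + qy^2), 1e-12)
  list(x = geom$beam_center[1] + r_mm * qx / qperp / geom$pixel_size,
       y = geom$beam_center[2] + r_mm * qy / qperp / geom$pixel_size)
}

# Add Gaussian spots (total volume = counts) to an expectation image.
render_spots <- function(img, px, py, counts, sigma) {
  w <- ceiling(4 * sigma)
  d <- dim(img)
  for (s in seq_along(px)) {
    xr <- max(1, floor(px[s] - w)):min(d[1], ceiling(px[s] + w))
    yr <- max(1, floor(py[s] - w)):min(d[2], ceiling(py[s] + w))
    gx <- stats::dnorm(xr, px[s], sigma)
    gy <- stats::dnorm(yr, py[s], sigma)
    img[xr, yr] <- img[xr, yr] + counts[s] * outer(gx, gy)
  }
  img
}

empty_defect_map <- function() {
  tibble::tibble(x = integer(0), y = integer(0), type = character(0))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d spot record(s) over %d frame(s), %d reflections in shell\n",
    nrow(x$spots), x$config$n_frames, nrow(x$full_intensities)))
  invisible(x)
}

#' Empirical tilt-limited coverage of reciprocal space
#'
#' Measures, through the simulator's own crossing geometry, the fraction
#' of reflections that can ever reach a diffracting condition when the
#' stage tilt is limited to ±`tilt_limit` and all in-plane rotations
#' about the unique (c, beam-normal) axis are available: for each
#' reflection the crossing test is applied over a grid of azimuthal
#' pre-rotations and the union taken.  For a dense lattice this
#' converges to the closed-form `sin(alpha)` fraction — 94% at ±70°.
#'
#' @param crystal A [virtual_crystal()]; its c axis should be along the
#'   beam (identity orientation) for the plate-on-grid case.
#' @param tilt_limit Stage half-range in degrees.
#' @param azimuth_step Grid spacing of the in-plane rotations, degrees.
#' @return List with `fraction`, `n_reflections`, `tilt_limit`.
#' @export
reciprocal_coverage <- function(crystal, tilt_limit = 70,
                                azimuth_step = 1) {
  stopifnot(inherits(crystal, "virtual_crystal"))
  check_scalar(tilt_limit, "tilt_limit", positive = TRUE)
  refl <- enumerate_reflections(crystal)
  q <- refl$q
  observable <- rep(FALSE, ncol(q))
  for (kappa in seq(0, 180 - azimuth_step, by = azimuth_step)) {
    k <- deg2rad(kappa)
    qy <- -sin(k) * q[1, ] + cos(k) * q[2, ]  # rotate about z (beam/c axis)
    phi1 <- abs(rad2deg(atan2(-q[3, ], qy)))
    phi <- pmin(phi1, 180 - phi1)
    observable <- observable | phi <= tilt_limit
    if (all(observable)) break
  }
  list(fraction = mean(observable), n_reflections = ncol(q),
       tilt_limit = tilt_limit)
}

#' Simulate a powder diffraction image
#'
#' Renders azimuthally uniform rings at the radii implied by the
#' geometry ([radius_for_resolution()]) for the given d-spacings,
#' optionally stretched to an axis ratio (astigmatism emulation) about
#' a given azimuth while preserving the geometric-mean radius, with
#' Poisson noise.  Deterministic by seed.
#'
#' @param d_spacings Ring lattice spacings in ångström.
#' @param geometry An [experiment_geometry()].
#' @param ellipticity Axis ratio a/b >= 1 (1 = circular).
#' @param ring_intensity Peak ring intensity above background, counts
#'   (scalar or per ring).
#' @param background_mean Mean background counts per pixel.
#' @param seed Integer RNG seed (required).
#' @param ring_sigma Radial Gaussian width of the rings, pixels.
#' @param azimuth Major-axis azimuth of the stretch, degrees.
#' @return Integer pixel matrix `[fast, slow]`.
#' @export
simulate_powder_image <- function(d_spacings, geometry, ellipticity = 1,
                                  ring_intensity = 500,
                                  background_mean = 20, seed,
                                  ring_sigma = 2, azimuth = 0) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  if (missing(seed) || !is_scalar_num(seed))
    me_stop("`seed` is mandatory", "invalid_argument")
  if (ellipticity < 1)
    me_stop("`ellipticity` must be >= 1 (a/b)", "invalid_argument")
  radii_px <- radius_for_resolution(geometry, d_spacings) / geometry$pixel_size
  ring_intensity <- rep_len(ring_intensity, length(radii_px))
  d <- geometry$dimensions
  dx <- seq_len(d[1]) - geometry$beam_center[1]
  dy <- seq_len(d[2]) - geometry$beam_center[2]
  r <- sqrt(outer(dx^2, dy^2, `+`))
  theta <- atan2(matrix(dy, d[1], d[2], byrow = TRUE),
                 matrix(dx, d[1], d[2]))
  lam <- matrix(background_mean, d[1], d[2])
  az <- deg2rad(azimuth)
  for (i in seq_along(radii_px)) {
    a <- radii_px[i] * sqrt(ellipticity)
    b <- radii_px[i] / sqrt(ellipticity)
    ct <- cos(theta - az); st <- sin(theta - az)
    rho <- a * b / sqrt((b * ct)^2 + (a * st)^2)
    lam <- lam + ring_intensity[i] * exp(-(r - rho)^2 / (2 * ring_sigma^2))
  }
  with_seed(seed, {
    matrix(as.integer(stats::rpois(length(lam), as.vector(lam))),
           d[1], d[2])
  })
}

#' Inject detector defects into a frame stack
#'
#' Adds the defects a real camera exhibits but does not flag: hot
#' pixels (persistently at a multiple of the frame median), dead pixels
#' (persistently zero) and erratic pixels (resampled with inflated
#' variance about the frame median).  Positions are drawn without
#' replacement in the precedence order hot > dead > erratic, so a pixel
#' receives at most one category; the returned map is the oracle for
#' [detect_bad_pixels()].
#'
#' @param stack A [frame_stack()].
#' @param n_hot,n_dead,n_erratic Defect counts (together < 1% of the
#'   detector).
#' @param hot_multiplier Hot value as a multiple of the frame median.
#' @param erratic_factor Erratic variance inflation relative to the
#'   Poisson expectation.
#' @param seed Integer RNG seed (required).
#' @return List with `stack` (modified copy) and `map` (tibble x, y,
#'   type).  An empty specification returns the stack bit-identical.
#' @export
inject_defects <- function(stack, n_hot = 0, n_dead = 0, n_erratic = 0,
                           hot_multiplier = 10, erratic_factor = 5, seed) {
  stopifnot(inherits(stack, "frame_stack"))
  if (missing(seed) || !is_scalar_num(seed))
    me_stop("`seed` is mandatory", "invalid_argument")
  n_total <- n_hot + n_dead + n_erratic
  npx <- prod(stack$native_dimensions)
  if (n_total >= 0.01 * npx)
    me_stop("defect counts must stay below 1% of the detector",
            "invalid_argument")
  if (n_total == 0)
    return(list(stack = stack, map = empty_defect_map()))
  d <- stack$native_dimensions
  with_seed(seed, {
    idx <- sample.int(npx, n_total)
    type <- rep(c("hot", "dead", "erratic"), c(n_hot, n_dead, n_erratic))
    map <- tibble::tibble(x = ((idx - 1L) %% d[1]) + 1L,
                          y = ((idx - 1L) %/% d[1]) + 1L,
                          type = type)
    hot_i <- idx[type == "hot"]; dead_i <- idx[type == "dead"]
    err_i <- idx[type == "erratic"]
    stack$frames <- lapply(stack$frames, function(fr) {
      med <- stats::median(fr)
      fr[hot_i] <- as.integer(round(hot_multiplier * max(med, 1)))
      fr[dead_i] <- 0L
      if (length(err_i))
        fr[err_i] <- as.integer(pmax(0, round(stats::rnorm(
          length(err_i), med, erratic_factor * sqrt(max(med, 1))))))
      fr
    })
  })
  list(stack = stack, map = map)
}
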