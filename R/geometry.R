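#' Electron beam parameters
#'
#' Bundles the properties of the electron beam.  Exactly one of
#' `voltage` and `wavelength` is authoritative; the other is derived
#' through the relativistic de Broglie relation
#' (see [wavelength_from_voltage()]).
#'
#' @param voltage Acceleration voltage in kilovolts, or `NULL` if
#'   `wavelength` is supplied directly.
#' @param wavelength Electron wavelength in ångström, or `NULL` to derive
#'   it from `voltage`.
#' @param bandpass Relative energy spread ΔE/E of the source
#'   (dimensionless).  A field-emission gun at 200 kV has
#'   ΔE/E ≈ 5e-6; the default.  Metadata plus an input to the
#'   simulator's rocking-width model.
#' @param dose_rate Electron dose rate in e⁻·Å⁻²·s⁻¹ (metadata only).
#' @return An object of class `beam_parameters` with fields `voltage`
#'   (kV, may be `NA` when the wavelength was given), `wavelength` (Å),
#'   `bandpass` and `dose_rate`.
#' @examples
#' beam_parameters(voltage = 200)
#' @export
beam_parameters <- function(voltage = NULL, wavelength = NULL,
                            bandpass = 5e-6, dose_rate = NA_real_) {
  if (is.null(voltage) && is.null(wavelength))
    me_stop("one of `voltage` or `wavelength` is required", "invalid_argument")
  if (!is.null(voltage) && !is.null(wavelength))
    me_stop("supply only one of `voltage` or `wavelength`; the other is derived",
            "invalid_argument")
  check_scalar(bandpass, "bandpass", nonneg = TRUE)
  if (is.null(wavelength)) {
    check_scalar(voltage, "voltage", positive = TRUE)
    wavelength <- wavelength_from_voltage(voltage)
  } else {
    check_scalar(wavelength, "wavelength", positive = TRUE)
    voltage <- NA_real_
  }
  structure(
    list(voltage = voltage, wavelength = wavelength,
         bandpass = bandpass, dose_rate = dose_rate),
    class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf("<beam_parameters> %s lambda = %.6f A, dE/E = %g\n",
              if (is.na(x$voltage)) "(wavelength-defined)"
              else sprintf("%g kV,", x$voltage),
              x$wavelength, x$bandpass))
  invisible(x)
}

#' Relativistic electron wavelength from acceleration voltage
#'
#' The de Broglie wavelength of an electron accelerated through a
#' potential `V`, with the relativistic correction:
#' \deqn{\lambda = h / \sqrt{2 m_e e V (1 + eV / 2 m_e c^2)}}
#' using CODATA 2018 constants.  At 200 kV this gives 0.0251 Å
#' (conventionally quoted as 0.025 Å), roughly 50x shorter than
#' crystallographic X-rays — the reason the Ewald sphere is nearly flat
#' in electron diffraction.
#'
#' @param voltage Acceleration voltage in kilovolts (> 0).
#' @return Wavelength in ångström, at full precision.  Use
#'   `round(x, 3)` for the conventional display value.
#' @examples
#' round(wavelength_from_voltage(200), 3)  # 0.025
#' round(wavelength_from_voltage(300), 3)  # 0.020
#' @export
wavelength_from_voltage <- function(voltage) {
  if (!is.numeric(voltage) || length(voltage) < 1L || any(!is.finite(voltage)))
    me_stop("`voltage` must be finite and numeric", "invalid_argument")
  if (any(voltage <= 0))
    me_stop("`voltage` must be > 0 kilovolts", "invalid_argument")
  h  <- 6.62607015e-34   # Planck constant, J s
  me <- 9.1093837015e-31 # electron mass, kg
  qe <- 1.602176634e-19  # elementary charge, C
  cc <- 299792458        # speed of light, m/s
  V <- voltage * 1e3
  h / sqrt(2 * me * qe * V * (1 + qe * V / (2 * me * cc^2))) * 1e10
}

#' Continuous-rotation model of the goniometer stage
#'
#' Describes a constant-rate rotation sweep.  `rate = 0` denotes stills
#' mode (the historical MicroED collection mode where the crystal is held
#' stationary per exposure); it is represented explicitly rather than as
#' a tiny oscillation so downstream software is told the truth.
#'
#' The sign of `rate` is physically meaningful and hard to determine from
#' the data themselves: the stage can be tilted both ways and the short
#' wavelength hides the handedness, so it must be supplied (and can be
#' flipped with `flip_rotation_sign()`).
#'
#' @param rate Signed rotation rate in degrees per second.
#' @param start_angle Stage angle at sweep start, degrees.
#' @param tilt_limit Half-range of the stage tilt in degrees (the
#'   cryo-holder limits this to about 70).
#' @param readout_gap Detector dead time between consecutive frames, in
#'   seconds; rotation continues during the gap.
#' @return An object of class `rotation_model`.
#' @export
rotation_model <- function(rate, start_angle = 0, tilt_limit = 70,
                           readout_gap = 0) {
  check_scalar(rate, "rate")
  check_scalar(start_angle, "start_angle")
  check_scalar(tilt_limit, "tilt_limit")
  if (tilt_limit <= 0 || tilt_limit > 90)
    me_stop("`tilt_limit` must lie in (0, 90] degrees", "invalid_argument")
  check_scalar(readout_gap, "readout_gap", nonneg = TRUE)
  structure(
    list(rate = rate, start_angle = start_angle,
         tilt_limit = tilt_limit, readout_gap = readout_gap),
    class = "rotation_model")
}

#' @rdname rotation_model
#' @param model A `rotation_model`.
#' @export
flip_rotation_sign <- function(model) {
  stopifnot(inherits(model, "rotation_model"))
  model$rate <- -model$rate
  model
}

#' @export
print.rotation_model <- function(x, ...) {
  cat(sprintf("<rotation_model> rate %+g deg/s from %g deg (tilt limit +-%g deg%s)\n",
              x$rate, x$start_angle, x$tilt_limit,
              if (x$readout_gap > 0)
                sprintf(", readout gap %g s", x$readout_gap) else ""))
  invisible(x)
}

#' Per-frame exposure timing
#'
#' Timestamps are authoritative when the acquisition stream provides
#' them.  When absent they are reconstructed as
#' `index * (exposure + readout_gap)` — the best that can be done, at the
#' cost of letting any rotation-rate error compound over the sweep.
#'
#' @param n_frames Number of frames (>= 1).
#' @param exposure Exposure time per frame in seconds (scalar or one per
#'   frame).
#' @param readout_gap Dead time between frames in seconds, used only when
#'   reconstructing timestamps.
#' @param timestamps Optional measured timestamps (seconds relative to
#'   sweep start), strictly increasing; overrides reconstruction.
#' @return A tibble of class `frame_timings` with columns `index`
#'   (0-based), `timestamp` and `exposure`.
#' @export
frame_timings <- function(n_frames, exposure, readout_gap = 0,
                          timestamps = NULL) {
  if (!is_scalar_num(n_frames) || n_frames < 1)
    me_stop("`n_frames` must be >= 1", "invalid_argument")
  n_frames <- as.integer(n_frames)
  exposure <- rep_len(as.numeric(exposure), n_frames)
  if (any(exposure <= 0))
    me_stop("`exposure` must be > 0 seconds", "invalid_argument")
  if (is.null(timestamps)) {
    check_scalar(readout_gap, "readout_gap", nonneg = TRUE)
    timestamps <- (seq_len(n_frames) - 1) * (exposure + readout_gap)
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != n_frames)
      me_stop("`timestamps` length must equal `n_frames`", "invalid_argument")
    if (any(diff(timestamps) <= 0))
      me_stop("`timestamps` must be strictly increasing", "invalid_argument")
  }
  out <- tibble::tibble(index = seq_len(n_frames) - 1L,
                        timestamp = timestamps, exposure = exposure)
  class(out) <- c("frame_timings", class(out))
  out
}

#' Oscillation start and range of each frame
#'
#' The stage orientation of a frame is the product of the rotation rate
#' and the exposure timestamp relative to the sweep start:
#' `osc_start = start_angle + rate * timestamp`, and the oscillation
#' covered during the exposure is `rate * exposure`.  The sign of the
#' rate propagates: a negative rate yields decreasing `osc_start` values;
#' both the (positive) range magnitude and the direction are reported.
#'
#' @param model A [rotation_model()].  Stills mode (`rate = 0`) is
#'   flagged explicitly, never silently treated as rotation.
#' @param timings A [frame_timings()] tibble (or any data frame with
#'   `index`, `timestamp`, `exposure`).
#' @return A tibble with columns `index`, `osc_start`, `osc_range`
#'   (magnitude, degrees), `direction` (+1, -1, or 0 for stills),
#'   `phi_mid` (mid-exposure angle) and `stills` (logical).
#' @examples
#' m <- rotation_model(rate = -0.36)
#' frame_rotation(m, frame_timings(3, exposure = 1))
#' @export
frame_rotation <- function(model, timings) {
  stopifnot(inherits(model, "rotation_model"))
  if (!all(c("index", "timestamp", "exposure") %in% names(timings)))
    me_stop("`timings` needs columns index, timestamp, exposure",
            "invalid_argument")
  stills <- model$rate == 0
  osc_start <- model$start_angle + model$rate * timings$timestamp
  raw_range <- model$rate * timings$exposure
  tibble::tibble(
    index = timings$index,
    osc_start = osc_start,
    osc_range = abs(raw_range),
    direction = sign(model$rate),
    phi_mid = osc_start + raw_range / 2,
    stills = stills)
}

#' Resolution at a radius on the detector
#'
#' Bragg's law in virtual-detector geometry: a pixel at radial distance
#' `r` from the beam centre sees scattering angle `2θ = arctan(r / D)`
#' and thus resolution `d = λ / (2 sin θ)`.  Strictly decreasing in the
#' radius.
#'
#' @param geometry An [experiment_geometry()].
#' @param radius Radial distance from the beam centre in millimetres (> 0).
#' @return Resolution `d` in ångström.
#' @export
resolution_at_radius <- function(geometry, radius) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0))
    me_stop("`radius` must be > 0 mm (d is undefined at the direct beam)",
            "invalid_argument")
  two_theta <- atan(radius / geometry$distance)
  geometry$beam$wavelength / (2 * sin(two_theta / 2))
}

#' Detector radius at which a resolution diffracts
#'
#' Exact inverse of [resolution_at_radius()]:
#' `r = D tan(2 arcsin(λ / 2d))`.
#'
#' @param geometry An [experiment_geometry()].
#' @param d Resolution in ångström; must exceed λ/2 for the Bragg
#'   condition to be satisfiable.
#' @return Radius in millimetres.
#' @export
radius_for_resolution <- function(geometry, d) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  lambda <- geometry$beam$wavelength
  if (!is.numeric(d) || any(!is.finite(d)))
    me_stop("`d` must be finite", "invalid_argument")
  if (any(d <= lambda / 2))
    me_stop(sprintf(
      "resolution %g A is unreachable: Bragg condition requires d > lambda/2 = %g A",
      min(d), lambda / 2), "unreachable_resolution")
  geometry$distance * tan(2 * asin(lambda / (2 * d)))
}

#' Observable fraction of reciprocal space under a tilt-limited stage
#'
#' For a crystal with a preferred orientation (e.g. plates whose
#' crystallographic c axis is normal to the grid), a stage that can only
#' tilt through ±α leaves a missing cone of reciprocal space around the
#' unique axis.  Assuming all in-plane rotations about that axis can be
#' measured (many crystals, random azimuths), the observable fraction is
#' `sin(α)`: 94% at the ±70° limit of a typical cryo-holder.
#'
#' @param alpha Stage half-range α in degrees, in (0, 90].
#' @return Fraction of reciprocal space in `[0, 1]`.
#' @examples
#' observable_fraction(70)  # ~0.94
#' @export
observable_fraction <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha > 90))
    me_stop("`alpha` must lie in (0, 90] degrees", "invalid_argument")
  sin(deg2rad(alpha))
}

#' Experiment geometry for conversion and calibration
#'
#' Everything a downstream integrator needs to reconstruct the
#' measurement: beam, virtual sample-detector distance (the camera
#' length of the lensless-equivalent experiment), beam centre, pixel
#' size, detector dimensions and binning.
#'
#' @param beam A [beam_parameters()] object.
#' @param distance Virtual sample-detector distance D in millimetres.
#' @param beam_center Direct-beam position `(x, y)` in (binned) pixels,
#'   1-based, x along the fast axis.
#' @param pixel_size Side length of a (binned) pixel in millimetres.
#' @param dimensions Detector size `(fast, slow)` in pixels.
#' @param binning Binning factor already applied to the above (>= 1).
#' @return An object of class `experiment_geometry`.
#' @export
experiment_geometry <- function(beam, distance, beam_center, pixel_size,
                                dimensions, binning = 1) {
  stopifnot(inherits(beam, "beam_parameters"))
  check_scalar(distance, "distance", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (length(beam_center) != 2L || any(!is.finite(beam_center)))
    me_stop("`beam_center` must be (x, y) in pixels", "invalid_argument")
  if (length(dimensions) != 2L || any(dimensions < 1))
    me_stop("`dimensions` must be (fast, slow) pixel counts", "invalid_argument")
  dimensions <- as.integer(dimensions)
  if (any(beam_center < 1) || beam_center[1] > dimensions[1] ||
      beam_center[2] > dimensions[2])
    me_stop("`beam_center` must lie within the detector bounds", "invalid_argument")
  if (!is_scalar_num(binning) || binning < 1 || binning != round(binning))
    me_stop("`binning` must be an integer >= 1", "invalid_argument")
  structure(
    list(beam = beam, distance = distance,
         beam_center = as.numeric(beam_center), pixel_size = pixel_size,
         dimensions = dimensions, binning = as.integer(binning)),
    class = "experiment_geometry")
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_geometry> %d x %d px (bin %d), %.4f mm/px\n",
    "  D = %g mm, beam centre (%.2f, %.2f) px, lambda = %.6f A\n"),
    x$dimensions[1], x$dimensions[2], x$binning, x$pixel_size,
    x$distance, x$beam_center[1], x$beam_center[2], x$beam$wavelength))
  invisible(x)
}

# Geometry of a binned detector: pixels grow, dimensions and centre shrink.
bin_geometry <- function(geometry, factor) {
  if (factor == 1) return(geometry)
  experiment_geometry(
    beam = geometry$beam,
    distance = geometry$distance,
    beam_center = (geometry$beam_center - 0.5) / factor + 0.5,
    pixel_size = geometry$pixel_size * factor,
    dimensions = geometry$dimensions %/% as.integer(factor),
    binning = geometry$binning * factor)
}
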