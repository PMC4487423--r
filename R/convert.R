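#' Bin a frame by summing pixel blocks
#'
#' Each output pixel is the sum of a `factor x factor` block of input
#' pixels, so total counts are conserved and the Poisson variance/mean
#' relation that downstream integrators rely on after gain correction is
#' preserved (averaging would break it).  The effective pixel size grows
#' by `factor`.
#'
#' @param frame Numeric matrix `[fast, slow]`.
#' @param factor Integer binning factor; must divide both dimensions
#'   (no silent cropping).
#' @return Binned matrix of dimensions `dim(frame) / factor`.
#' @examples
#' bin_frame(matrix(1, 4, 4), 2)  # 2 x 2 matrix of fours
#' @export
bin_frame <- function(frame, factor) {
  check_frame(frame)
  if (!is_scalar_num(factor) || factor < 1 || factor != round(factor))
    me_stop("`factor` must be a positive integer", "invalid_argument")
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  d <- dim(frame)
  if (any(d %% factor != 0))
    me_stop(sprintf(
      "binning factor %d does not divide the %d x %d frame; refusing to crop",
      factor, d[1], d[2]), "binning_error")
  s1 <- colSums(array(frame, c(factor, d[1] %/% factor, d[2])))
  t(colSums(array(t(s1), c(factor, d[2] %/% factor, d[1] %/% factor))))
}

#' Clip counts into the unsigned 16-bit range with a pedestal
#'
#' Camera-side dark subtraction can leave small negative excursions;
#' these are clipped to zero, then a constant pedestal is added and the
#' result clipped at the saturation value.  In the low-dose regime of
#' rotation electron diffraction even the strongest reflections stay in
#' the linear range, so the high clip is a safety net that is expected
#' never to trigger; both clip counts are reported, never silent.
#'
#' @param frame Numeric matrix of counts.
#' @param pedestal Non-negative offset added to every pixel.
#' @param saturation Upper clip value (default 65535, the u16 maximum).
#' @return List with `pixels` (integer matrix), `n_clipped_low` (pixels
#'   negative before the pedestal) and `n_clipped_high`.
#' @export
prepare_pixels <- function(frame, pedestal = 512, saturation = 65535) {
  check_frame(frame)
  check_scalar(pedestal, "pedestal", nonneg = TRUE)
  n_low <- sum(frame < 0)
  frame[frame < 0] <- 0
  v <- round(frame + pedestal)
  n_high <- sum(v > saturation)
  v[v > saturation] <- saturation
  list(pixels = structure(as.integer(v), dim = dim(frame)),
       n_clipped_low = n_low, n_clipped_high = n_high)
}

#' Convert a rotation sweep to SMV images
#'
#' The main conversion pipeline: for every frame of the stack, apply the
#' optional exclusion mask, bin, add the pedestal and clip, assemble the
#' per-frame geometry header (oscillation start/range from the rotation
#' model and the frame's timestamp) and write one SMV file.  Output
#' files are named `<prefix>_NNNN.img` with 1-based zero-padded indices,
#' and a plain-text manifest records every parameter and per-frame
#' angle.  The conversion is deterministic: identical inputs give
#' byte-identical outputs.
#'
#' @param stack A [frame_stack()] with timings.
#' @param geometry [experiment_geometry()] of the *input* frames (the
#'   header is adjusted automatically when `bin_factor > 1`).
#' @param rotation A [rotation_model()].
#' @param output_dir Directory for the SMV files (created if needed).
#' @param prefix File-name prefix.
#' @param pedestal,bin_factor,mask,date,swap_beam_axes See
#'   [prepare_pixels()], [bin_frame()] and [build_smv_header()];
#'   `mask` is a logical matrix of pixels to zero out before binning.
#' @return Invisibly, a tibble manifest with one row per frame (file,
#'   index, timestamp, osc_start, osc_range, clipped pixel counts);
#'   also written as `<prefix>_manifest.txt`.
#' @export
convert_sweep <- function(stack, geometry, rotation, output_dir,
                          prefix = "frame", pedestal = 512, bin_factor = 1,
                          mask = NULL, date = "1970-01-01T00:00:00",
                          swap_beam_axes = FALSE) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(geometry, "experiment_geometry"),
            inherits(rotation, "rotation_model"))
  if (is.null(stack$timings))
    me_stop("the stack has no timings; attach them with frame_timings()",
            "invalid_argument")
  if (!all(geometry$dimensions == stack$native_dimensions))
    me_stop("geometry dimensions disagree with the stack", "invalid_argument")
  if (!is.null(mask) && !identical(dim(mask), dim(stack$frames[[1]])))
    me_stop("mask dimensions disagree with the frames", "invalid_argument")
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  out_geom <- bin_geometry(geometry, bin_factor)
  n <- length(stack$frames)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    timing <- stack$timings[i, ]
    fr <- stack$frames[[i]]
    if (!is.null(mask)) fr[mask] <- 0
    fr <- tryCatch(bin_frame(fr, bin_factor), error = function(e)
      me_stop(sprintf("frame %d: %s", i, conditionMessage(e)),
              "binning_error"))
    prep <- prepare_pixels(fr, pedestal = pedestal)
    header <- build_smv_header(out_geom, rotation, timing,
                               pedestal = pedestal, date = date,
                               swap_beam_axes = swap_beam_axes)
    file <- file.path(output_dir, sprintf("%s_%04d.img", prefix, i))
    write_smv(smv_image(header, prep$pixels), file)
    rot <- frame_rotation(rotation, timing)
    rows[[i]] <- tibble::tibble(
      file = basename(file), index = i,
      timestamp = timing$timestamp, exposure = timing$exposure,
      osc_start = rot$osc_start, osc_range = rot$osc_range,
      clipped_low = prep$n_clipped_low, clipped_high = prep$n_clipped_high)
  }
  manifest <- do.call(rbind, rows)
  total_rot <- rotation$rate *
    (stack$timings$timestamp[n] + stack$timings$exposure[n] -
       stack$timings$timestamp[1])
  mf <- file.path(output_dir, paste0(prefix, "_manifest.txt"))
  lines <- c(
    sprintf("# microed %s conversion manifest", utils::packageVersion("microed")),
    sprintf("prefix=%s", prefix),
    sprintf("n_frames=%d", n),
    sprintf("rotation_rate_deg_per_s=%.6f", rotation$rate),
    sprintf("start_angle_deg=%.6f", rotation$start_angle),
    sprintf("total_rotation_deg=%.6f", total_rot),
    sprintf("distance_mm=%.4f", out_geom$distance),
    sprintf("wavelength_A=%.6f", out_geom$beam$wavelength),
    sprintf("pixel_size_mm=%.4f", out_geom$pixel_size),
    sprintf("beam_center_px=%.4f,%.4f", out_geom$beam_center[1],
            out_geom$beam_center[2]),
    sprintf("bin_factor=%d", as.integer(bin_factor)),
    sprintf("pedestal=%d", as.integer(pedestal)),
    "",
    paste(colnames(manifest), collapse = "\t"),
    apply(manifest, 1, function(r) paste(r, collapse = "\t")))
  writeLines(lines, mf)
  invisible(manifest)
}

#' Read a flat key=value configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments are
#' ignored.  Keys mirror the command-line flags of the `microed-*`
#' scripts; command-line values override the file.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) me_stop(paste("no such file:", path), "format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    me_stop(paste("config line without '=':", lines[bad][1]), "parse_error")
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}
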