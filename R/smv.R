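#' SMV diffraction image
#'
#' The Super Marty View format: a fixed-length ASCII key/value header
#' block followed by row-major little-endian unsigned 16-bit pixel data.
#' Simple enough to be read by every crystallographic integration
#' package, which is the whole point.
#'
#' @param header Named character vector of header entries, in order
#'   (see [build_smv_header()]).
#' @param pixels Integer matrix `[fast, slow]`, values in 0..65535.
#' @return An object of class `smv_image`.
#' @export
smv_image <- function(header, pixels) {
  check_frame(pixels, "pixels")
  if (is.null(names(header)) || any(!nzchar(names(header))))
    me_stop("`header` must be a named character vector", "header_error")
  if (any(pixels < 0) || any(pixels > 65535))
    me_stop("SMV pixels must lie in 0..65535", "invalid_argument")
  s1 <- as.integer(header[["SIZE1"]] %||% NA)
  s2 <- as.integer(header[["SIZE2"]] %||% NA)
  if (is.na(s1) || is.na(s2) || s1 != nrow(pixels) || s2 != ncol(pixels))
    me_stop("header SIZE1/SIZE2 disagree with the pixel dimensions",
            "header_error")
  structure(list(header = header, pixels = pixels), class = "smv_image")
}

#' @export
print.smv_image <- function(x, ...) {
  cat(sprintf("<smv_image> %s x %s px, OSC_START %s, OSC_RANGE %s\n",
              x$header[["SIZE1"]], x$header[["SIZE2"]],
              x$header[["OSC_START"]] %||% "?",
              x$header[["OSC_RANGE"]] %||% "?"))
  invisible(x)
}

# Fixed numeric formats: bit-exact headers require deterministic rendering.
fmt_mm   <- function(x) sprintf("%.4f", x)
fmt_deg  <- function(x) sprintf("%.4f", x)
fmt_s    <- function(x) sprintf("%.4f", x)
fmt_wave <- function(x) sprintf("%.6f", x)

#' Assemble an SMV header
#'
#' SMV carries no detector model, so everything a downstream integrator
#' needs must be written into the header: dimensions, pixel size,
#' virtual detector distance, wavelength, beam centre, and the
#' oscillation start/range of the frame.  Numeric fields use fixed
#' decimal formats (4 places for mm/degrees/seconds, 6 for the
#' wavelength) so identical inputs give byte-identical headers.
#'
#' Beam-centre convention: `BEAM_CENTER_X` is the fast-axis (x) pixel
#' coordinate times `PIXEL_SIZE`, in mm from the image origin;
#' `BEAM_CENTER_Y` likewise on the slow axis.  Downstream packages
#' disagree about this dialect, so `swap_beam_axes` exchanges the two.
#'
#' @param geometry An [experiment_geometry()] describing the (binned)
#'   output image.
#' @param rotation A [rotation_model()].
#' @param timing A single-row slice of [frame_timings()] for the frame.
#' @param pedestal Constant offset added to the pixels (recorded as
#'   `IMAGE_PEDESTAL` so integrators can subtract it).
#' @param date Acquisition date string.  Defaults to a fixed placeholder
#'   so conversion is reproducible; pass the real acquisition time when
#'   known.
#' @param swap_beam_axes Exchange the X/Y beam-centre interpretation.
#' @param header_bytes Header block length (multiple of 512); promoted
#'   automatically on overflow by [write_smv()].
#' @return Ordered named character vector of header entries.
#' @export
build_smv_header <- function(geometry, rotation, timing, pedestal = 512,
                             date = "1970-01-01T00:00:00",
                             swap_beam_axes = FALSE, header_bytes = 512L) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  stopifnot(inherits(rotation, "rotation_model"))
  for (f in c("distance", "pixel_size", "beam_center", "dimensions"))
    if (is.null(geometry[[f]]) || any(is.na(geometry[[f]])))
      me_stop(paste("geometry field", f, "is missing"), "header_error")
  if (is.null(geometry$beam$wavelength) || is.na(geometry$beam$wavelength))
    me_stop("geometry field beam$wavelength is missing", "header_error")
  rot <- frame_rotation(rotation, timing)
  if (nrow(rot) != 1L)
    me_stop("`timing` must describe exactly one frame", "invalid_argument")
  bc_mm <- geometry$beam_center * geometry$pixel_size
  if (swap_beam_axes) bc_mm <- rev(bc_mm)
  c(HEADER_BYTES = sprintf("%d", header_bytes),
    DIM = "2",
    BYTE_ORDER = "little_endian",
    TYPE = "unsigned_short",
    SIZE1 = sprintf("%d", geometry$dimensions[1]),
    SIZE2 = sprintf("%d", geometry$dimensions[2]),
    PIXEL_SIZE = fmt_mm(geometry$pixel_size),
    BIN = sprintf("%d", geometry$binning),
    DISTANCE = fmt_mm(geometry$distance),
    WAVELENGTH = fmt_wave(geometry$beam$wavelength),
    BEAM_CENTER_X = fmt_mm(bc_mm[1]),
    BEAM_CENTER_Y = fmt_mm(bc_mm[2]),
    OSC_START = fmt_deg(rot$osc_start),
    OSC_RANGE = fmt_deg(rot$osc_range),
    PHI = fmt_deg(rot$osc_start),
    TIME = fmt_s(timing$exposure),
    TWOTHETA = fmt_deg(0),
    IMAGE_PEDESTAL = sprintf("%d", as.integer(pedestal)),
    ACC_VOLTAGE = if (is.na(geometry$beam$voltage)) "unknown"
                  else sprintf("%g", geometry$beam$voltage),
    DATE = date)
}

render_smv_header <- function(header) {
  body <- paste0(names(header), "=", unlist(header), ";\n", collapse = "")
  repeat {
    hb <- as.integer(header[["HEADER_BYTES"]])
    text <- paste0("{\n", body, "}\n")
    if (nchar(text, type = "bytes") <= hb) {
      return(paste0(text, strrep(" ", hb - nchar(text, type = "bytes"))))
    }
    # Overflow: promote to the next multiple of 512 and re-render.
    hb_new <- 512L * ceiling((nchar(text, type = "bytes") + 16L) / 512L)
    header[["HEADER_BYTES"]] <- sprintf("%d", hb_new)
    body <- paste0(names(header), "=", unlist(header), ";\n", collapse = "")
  }
}

#' Write and read SMV files
#'
#' On disk an SMV file is an ASCII block `{\n KEY=value;\n ... }\n`
#' padded with spaces to exactly `HEADER_BYTES` bytes (promoted to the
#' next multiple of 512 on overflow), followed by `SIZE1 x SIZE2`
#' little-endian unsigned 16-bit values, fast axis first.
#' `read_smv()` inverts `write_smv()` exactly.
#'
#' @param image An [smv_image()].
#' @param path File path (conventionally `.img`).
#' @return `write_smv()` returns `path` invisibly; `read_smv()` returns
#'   an `smv_image`.
#' @export
write_smv <- function(image, path) {
  stopifnot(inherits(image, "smv_image"))
  text <- render_smv_header(image$header)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  writeBin(u16_to_raw(as.vector(image$pixels)), con)
  invisible(path)
}

#' @rdname write_smv
#' @export
read_smv <- function(path) {
  if (!file.exists(path)) me_stop(paste("no such file:", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  head0 <- rawToChar(readBin(con, "raw", 512L))
  if (substr(head0, 1, 1) != "{")
    me_stop(paste0("not an SMV file (no '{' at byte 0): ", path), "parse_error")
  hb <- sub(".*HEADER_BYTES=\\s*(\\d+);.*", "\\1", head0)
  hb <- suppressWarnings(as.integer(hb))
  if (is.na(hb))
    me_stop("malformed SMV header: HEADER_BYTES not found (within byte 0..512)",
            "parse_error")
  seek(con, 0)
  text <- rawToChar(readBin(con, "raw", hb))
  m <- gregexpr("([A-Za-z0-9_]+)=([^;\n]*);", text)[[1]]
  if (m[1] == -1)
    me_stop("malformed SMV header: no KEY=value entries (byte 2 onward)",
            "parse_error")
  entries <- regmatches(text, gregexpr("([A-Za-z0-9_]+)=([^;\n]*);", text))[[1]]
  keys <- sub("=.*", "", entries)
  vals <- sub(";$", "", sub("^[A-Za-z0-9_]+=", "", entries))
  header <- stats::setNames(vals, keys)
  s1 <- as.integer(header[["SIZE1"]]); s2 <- as.integer(header[["SIZE2"]])
  if (is.na(s1) || is.na(s2))
    me_stop("malformed SMV header: SIZE1/SIZE2 missing", "parse_error")
  r <- readBin(con, "raw", 2L * s1 * s2)
  if (length(r) < 2L * s1 * s2)
    me_stop(sprintf("truncated SMV pixel data at byte %d",
                    hb + length(r)), "parse_error")
  smv_image(header, matrix(raw_to_u16(r), s1, s2))
}
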