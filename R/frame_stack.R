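#' Ordered stack of raw detector frames
#'
#' The conversion input: a list of same-sized integer pixel matrices with
#' per-frame timing.  Frame matrices are indexed `[fast, slow]` (first
#' index = x), so `as.vector()` yields the fast-axis-first order used on
#' disk.
#'
#' @param frames List of numeric matrices, all with identical dimensions.
#' @param timings A [frame_timings()] tibble with one row per frame, or
#'   `NULL` if unknown (must then be supplied before conversion).
#' @param bit_depth Native bit depth of the source (16 or 32).
#' @param source_format One of `"raw-internal"`, `"tiff-stack"`,
#'   `"mrc-stack"`, `"memory"`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timings = NULL, bit_depth = 16,
                        source_format = "memory") {
  if (!is.list(frames) || length(frames) < 1L)
    me_stop("`frames` must be a non-empty list of matrices", "invalid_argument")
  dims <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    check_frame(frames[[i]], sprintf("frames[[%d]]", i))
    if (!identical(dim(frames[[i]]), dims))
      me_stop(sprintf("frame %d dimensions differ from frame 1", i),
              "corrupt_stack")
  }
  if (!is.null(timings)) {
    if (nrow(timings) != length(frames))
      me_stop("`timings` must have one row per frame", "invalid_argument")
    if (any(diff(timings$timestamp) <= 0))
      me_stop("`timings` timestamps must be strictly increasing",
              "invalid_argument")
  }
  if (!bit_depth %in% c(16, 32))
    me_stop("`bit_depth` must be 16 or 32", "invalid_argument")
  structure(
    list(frames = frames, timings = timings,
         native_dimensions = dims, bit_depth = as.integer(bit_depth),
         source_format = source_format),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px, %d-bit, from %s\n",
              length(x$frames), x$native_dimensions[1], x$native_dimensions[2],
              x$bit_depth, x$source_format))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

## ---- internal raw stack format -------------------------------------------
## A documented lossless stand-in for proprietary camera streams:
##   bytes 0-7   magic "MEDRAW1\n"
##   6 x int32 LE: version (=1), nfast, nslow, nframes, bit_depth,
##                 has_timestamps (0/1)
##   if has_timestamps: nframes doubles (timestamps, s) then nframes
##                 doubles (exposures, s), LE
##   then nframes frames of nfast*nslow unsigned ints of bit_depth,
##                 fast axis first, LE

RAW_MAGIC <- charToRaw("MEDRAW1\n")

#' Read and write the internal raw stack format
#'
#' A fixed-layout lossless container (magic, dimensions, bit depth,
#' frame count, optional per-frame timestamp/exposure table, then
#' concatenated little-endian frames) used as the documented stand-in
#' for proprietary camera streams.  `write_raw_stack()` and
#' `read_raw_stack()` are exact inverses.
#'
#' @param stack A [frame_stack()].
#' @param path File path.
#' @return `read_raw_stack()` returns a `frame_stack`;
#'   `write_raw_stack()` returns `path` invisibly.
#' @export
write_raw_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(RAW_MAGIC, con)
  has_t <- !is.null(stack$timings)
  writeBin(as.integer(c(1L, stack$native_dimensions, length(stack$frames),
                        stack$bit_depth, has_t)),
           con, size = 4L, endian = "little")
  if (has_t) {
    writeBin(as.numeric(stack$timings$timestamp), con, size = 8L,
             endian = "little")
    writeBin(as.numeric(stack$timings$exposure), con, size = 8L,
             endian = "little")
  }
  size <- stack$bit_depth %/% 8L
  for (fr in stack$frames) {
    v <- as.vector(fr)
    if (any(v < 0) || any(v >= 2^stack$bit_depth))
      me_stop("pixel values exceed the stack bit depth", "invalid_argument")
    if (size == 2L) writeBin(u16_to_raw(v), con)
    else writeBin(as.integer(v), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_raw_stack
#' @export
read_raw_stack <- function(path) {
  if (!file.exists(path)) me_stop(paste("no such file:", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, RAW_MAGIC))
    me_stop(paste(path, "is not an internal raw stack (bad magic)"),
            "format_error")
  hdr <- readBin(con, "integer", 6L, size = 4L, endian = "little")
  if (length(hdr) < 6L || hdr[1] != 1L)
    me_stop("unsupported raw stack version", "format_error")
  nfast <- hdr[2]; nslow <- hdr[3]; nframes <- hdr[4]
  bit_depth <- hdr[5]; has_t <- hdr[6] == 1L
  timings <- NULL
  if (has_t) {
    ts <- readBin(con, "numeric", nframes, size = 8L, endian = "little")
    ex <- readBin(con, "numeric", nframes, size = 8L, endian = "little")
    if (length(ts) < nframes || length(ex) < nframes)
      me_stop("truncated raw stack: timestamp table incomplete", "corrupt_stack")
    timings <- frame_timings(nframes, exposure = ex, timestamps = ts)
  }
  npx <- nfast * nslow
  size <- bit_depth %/% 8L
  frames <- vector("list", nframes)
  for (i in seq_len(nframes)) {
    if (size == 2L) {
      r <- readBin(con, "raw", 2L * npx)
      if (length(r) < 2L * npx)
        me_stop(sprintf("truncated raw stack: frame %d incomplete", i),
                "corrupt_stack")
      v <- raw_to_u16(r)
    } else {
      v <- readBin(con, "integer", npx, size = 4L, endian = "little")
      if (length(v) < npx)
        me_stop(sprintf("truncated raw stack: frame %d incomplete", i),
                "corrupt_stack")
    }
    frames[[i]] <- matrix(v, nfast, nslow)
  }
  frame_stack(frames, timings, bit_depth = bit_depth,
              source_format = "raw-internal")
}

# 16-bit little-endian packing without writeBin's signed-integer limits.
u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

raw_to_u16 <- function(r) {
  i <- as.integer(r)
  i[c(TRUE, FALSE)] + 256L * i[c(FALSE, TRUE)]
}

## ---- TIFF / MRC stacks ----------------------------------------------------

read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  # TIFF is stored row-major (y, x); transpose into our (fast, slow) layout.
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of RGB sources
    t(m)
  })
  frame_stack(frames, NULL, bit_depth = 16, source_format = "tiff-stack")
}

write_tiff_stack <- function(stack, path) {
  imgs <- lapply(stack$frames, function(fr) t(fr) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

# Minimal MRC2014 subset: 1024-byte header, modes 1 (int16), 2 (float32)
# and 6 (uint16); no extended header is written, any present is skipped.
read_mrc_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 10L, size = 4L, endian = "little")
  if (length(hdr) < 10L) me_stop("truncated MRC header", "corrupt_stack")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (!mode %in% c(1L, 2L, 6L))
    me_stop(sprintf("unsupported MRC mode %d", mode), "format_error")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 1024 + nsymbt)
  npx <- nx * ny
  frames <- vector("list", nz)
  for (i in seq_len(nz)) {
    v <- switch(as.character(mode),
      "1" = readBin(con, "integer", npx, size = 2L, signed = TRUE,
                    endian = "little"),
      "2" = round(readBin(con, "numeric", npx, size = 4L, endian = "little")),
      "6" = {
        r <- readBin(con, "raw", 2L * npx)
        if (length(r) < 2L * npx) integer(0) else raw_to_u16(r)
      })
    if (length(v) < npx)
      me_stop(sprintf("truncated MRC stack: frame %d incomplete", i),
              "corrupt_stack")
    frames[[i]] <- matrix(v, nx, ny)  # MRC data are x-fastest already
  }
  frame_stack(frames, NULL, bit_depth = 16, source_format = "mrc-stack")
}

write_mrc_stack <- function(stack, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- stack$native_dimensions
  nz <- length(stack$frames)
  header <- raw(1024)
  put_i32 <- function(h, at, vals) {  # 'at' is a 0-based byte offset
    r <- writeBin(as.integer(vals), raw(), size = 4L, endian = "little")
    h[(at + 1):(at + length(r))] <- r
    h
  }
  header <- put_i32(header, 0, c(d[1], d[2], nz, 6L))   # nx ny nz mode
  header <- put_i32(header, 28, c(d[1], d[2], nz))      # mx my mz
  cell <- writeBin(as.numeric(c(d[1], d[2], nz, 90, 90, 90)), raw(),
                   size = 4L, endian = "little")
  header[41:(40 + length(cell))] <- cell
  header <- put_i32(header, 64, c(1L, 2L, 3L))          # mapc mapr maps
  header[209:212] <- charToRaw("MAP ")
  header[213:216] <- as.raw(c(0x44, 0x44, 0x00, 0x00))  # little-endian stamp
  writeBin(header, con)
  for (fr in stack$frames) writeBin(u16_to_raw(as.vector(fr)), con)
  invisible(path)
}

#' Read a detector frame stack
#'
#' Dispatches on format (by extension and magic bytes unless a hint is
#' given) to the internal raw reader, a TIFF stack reader or a minimal
#' MRC reader.  Pixel transfer is lossless for integer sources.  When the
#' container carries no timestamps they are reconstructed as
#' `index * (exposure + readout_gap)` from the supplied fallback exposure.
#'
#' @param path Input file.
#' @param format `"auto"` (default), `"raw"`, `"tiff"` or `"mrc"`.
#' @param exposure Fallback per-frame exposure in seconds, required when
#'   the container has no timing table.
#' @param readout_gap Detector dead time used in timestamp
#'   reconstruction, seconds.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, format = c("auto", "raw", "tiff", "mrc"),
                             exposure = NULL, readout_gap = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) me_stop(paste("no such file:", path), "format_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    magic <- readBin(path, "raw", 8L)
    format <- if (identical(magic, RAW_MAGIC)) "raw"
      else if (ext %in% c("tif", "tiff")) "tiff"
      else if (ext %in% c("mrc", "mrcs", "map")) "mrc"
      else me_stop(paste("cannot identify the format of", path), "format_error")
  }
  stack <- switch(format,
    raw  = read_raw_stack(path),
    tiff = read_tiff_stack(path),
    mrc  = read_mrc_stack(path))
  if (is.null(stack$timings)) {
    if (is.null(exposure))
      me_stop(paste("the container has no timestamps;",
                    "supply `exposure` to reconstruct them"),
              "invalid_argument")
    stack$timings <- frame_timings(length(stack$frames), exposure,
                                   readout_gap = readout_gap)
  }
  stack
}
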