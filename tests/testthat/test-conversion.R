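test_that("the internal raw stack format round-trips losslessly", {
  stk <- background_stack(n_frames = 4, dims = c(32, 48), mean = 40, seed = 1)
  path <- withr::local_tempfile(fileext = ".medraw")
  write_raw_stack(stk, path)
  back <- read_raw_stack(path)
  expect_identical(back$frames, stk$frames)
  expect_equal(back$timings$timestamp, stk$timings$timestamp)
  expect_equal(back$timings$exposure, stk$timings$exposure)

  # Truncation is detected and names the failing frame.
  raw <- readBin(path, "raw", file.size(path))
  tpath <- withr::local_tempfile(fileext = ".medraw")
  writeBin(raw[1:(length(raw) - 100)], tpath)
  expect_error(read_raw_stack(tpath), class = "corrupt_stack")
  expect_error(read_raw_stack(tpath), "frame 4")

  # A non-stack file is rejected by magic.
  junk <- withr::local_tempfile()
  writeBin(charToRaw("not a stack at all"), junk)
  expect_error(read_raw_stack(junk), class = "format_error")
  expect_error(read_frame_stack(junk), class = "format_error")
})

test_that("TIFF and MRC stacks are read with lossless pixel transfer", {
  stk <- background_stack(n_frames = 10, dims = c(40, 32), mean = 30, seed = 2)
  tp <- withr::local_tempfile(fileext = ".tif")
  microed:::write_tiff_stack(stk, tp)
  ts <- read_frame_stack(tp, exposure = 1.5)
  expect_length(ts$frames, 10)
  expect_equal(ts$native_dimensions, c(40L, 32L))
  expect_identical(lapply(ts$frames, as.integer),
                   lapply(stk$frames, as.integer))
  expect_equal(ts$timings$timestamp, (0:9) * 1.5)
  # Without a fallback exposure, timestamp reconstruction must refuse.
  expect_error(read_frame_stack(tp), class = "invalid_argument")

  mp <- withr::local_tempfile(fileext = ".mrc")
  microed:::write_mrc_stack(stk, mp)
  ms <- read_frame_stack(mp, exposure = 1)
  expect_identical(lapply(ms$frames, as.integer),
                   lapply(stk$frames, as.integer))
})

test_that("binning sums blocks, conserves counts and refuses to crop", {
  expect_equal(bin_frame(matrix(1, 4, 4), 2), matrix(4, 2, 2))
  m <- matrix(runif(64 * 64), 64, 64)
  expect_identical(bin_frame(m, 1), m)

  # Brute-force nested-loop oracle.
  b <- bin_frame(m, 2)
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32)
    oracle[i, j] <- sum(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(b, oracle, tolerance = 1e-12)
  expect_equal(sum(b), sum(m), tolerance = 1e-9)

  b4 <- bin_frame(m, 4)
  expect_equal(sum(b4), sum(m), tolerance = 1e-9)
  expect_equal(dim(b4), c(16L, 16L))

  expect_error(bin_frame(matrix(0, 10, 10), 3), class = "binning_error")
})

test_that("pixel preparation clips into u16 with a full report", {
  f <- matrix(c(-5, 0, 65100, 65535), 2, 2)
  p <- prepare_pixels(f, pedestal = 512)
  expect_equal(p$n_clipped_low, 1)
  expect_equal(p$n_clipped_high, 2)          # 65100 + 512 and 65535 + 512
  expect_true(all(p$pixels <= 65535) && all(p$pixels >= 0))

  z <- prepare_pixels(matrix(0, 4, 4), pedestal = 512)
  expect_true(all(z$pixels == 512))
  expect_equal(z$n_clipped_low + z$n_clipped_high, 0)

  # Low-dose simulated frame: nothing clips — the no-overload regime.
  stk <- background_stack(n_frames = 1, mean = 100, seed = 3)
  p2 <- prepare_pixels(stk$frames[[1]])
  expect_equal(p2$n_clipped_low + p2$n_clipped_high, 0)
})

test_that("the SMV header carries the full geometry with fixed formatting", {
  # 2x binning of 15.6 um native pixels -> PIXEL_SIZE 0.0312 mm.
  native <- experiment_geometry(std_beam(), 520, c(1014, 1024), 0.0156,
                                c(2028, 2048))
  binned <- microed:::bin_geometry(native, 2)
  rot <- rotation_model(rate = -0.36)
  tm <- frame_timings(3, exposure = 1)
  h <- build_smv_header(binned, rot, tm[2, ])
  expect_equal(h[["PIXEL_SIZE"]], "0.0312")
  expect_equal(h[["SIZE1"]], "1014")
  expect_equal(h[["BIN"]], "2")
  expect_equal(h[["DIM"]], "2")
  expect_equal(h[["TYPE"]], "unsigned_short")

  # Oscillation fields delegate to frame_rotation.
  fr <- frame_rotation(rot, tm[2, ])
  expect_equal(as.numeric(h[["OSC_START"]]), fr$osc_start, tolerance = 5e-5)
  expect_equal(as.numeric(h[["OSC_RANGE"]]), fr$osc_range, tolerance = 5e-5)
  expect_equal(h[["PHI"]], h[["OSC_START"]])

  # Determinism: the same inputs give an identical header.
  expect_identical(h, build_smv_header(binned, rot, tm[2, ]))

  # A gutted geometry is refused with the field named.
  broken <- binned
  broken$distance <- NA_real_
  expect_error(build_smv_header(broken, rot, tm[2, ]), "distance",
               class = "header_error")
})

test_that("SMV files round-trip bit-exactly and have the documented layout", {
  geom <- std_geometry(dims = c(64, 64), center = c(32, 32))
  rot <- rotation_model(rate = 0.5)
  set.seed(4)
  px <- matrix(as.integer(rpois(64 * 64, 500)), 64, 64)
  img <- smv_image(build_smv_header(geom, rot, frame_timings(1, 1)), px)
  path <- withr::local_tempfile(fileext = ".img")
  write_smv(img, path)

  expect_equal(file.size(path), 512 + 2 * 64 * 64)
  back <- read_smv(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$header, img$header)

  # Oversized headers are promoted to the next multiple of 512.
  big <- img
  big$header <- c(img$header,
                  stats::setNames(replicate(40, strrep("x", 40)),
                                  paste0("PAD", 1:40)))
  path2 <- withr::local_tempfile(fileext = ".img")
  write_smv(smv_image(big$header, px), path2)
  back2 <- read_smv(path2)
  expect_identical(back2$pixels, px)
  hb <- as.integer(back2$header[["HEADER_BYTES"]])
  expect_equal(hb %% 512, 0)
  expect_gt(hb, 512)
  expect_equal(file.size(path2), hb + 2 * 64 * 64)

  garbage <- withr::local_tempfile()
  writeBin(charToRaw("garbage"), garbage)
  expect_error(read_smv(garbage), class = "parse_error")
})

test_that("an SMV file from an independent minimal writer parses identically", {
  # Flat-footed writer sharing no code with write_smv().
  set.seed(5)
  vals <- as.integer(sample(0:65535, 16 * 8))
  hdr <- paste0("{\nHEADER_BYTES= 512;\nDIM=2;\nBYTE_ORDER=little_endian;\n",
                "TYPE=unsigned_short;\nSIZE1=16;\nSIZE2=8;\n",
                "PIXEL_SIZE=0.0312;\nDISTANCE=520.0000;\n}\n")
  path <- withr::local_tempfile(fileext = ".img")
  con <- file(path, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(strrep(" ", 512 - nchar(hdr))), con)
  for (v in vals) writeBin(as.raw(c(v %% 256, v %/% 256)), con)
  close(con)
  img <- read_smv(path)
  expect_equal(as.vector(img$pixels), vals)
  expect_equal(img$header[["DISTANCE"]], "520.0000")
  expect_equal(dim(img$pixels), c(16L, 8L))
})

test_that("sweep conversion emits one geometry-complete SMV per frame, deterministically", {
  sw <- sparse_sweep(seed = 9, n_frames = 10, rate = -0.36)
  out <- withr::local_tempdir()
  man <- convert_sweep(sw$stack, sw$geometry, sw$rotation, out,
                       prefix = "cat", bin_factor = 2)
  files <- list.files(out, pattern = "\\.img$", full.names = TRUE)
  expect_length(files, 10)
  expect_equal(basename(files[1]), "cat_0001.img")

  starts <- vapply(files, function(f)
    as.numeric(read_smv(f)$header[["OSC_START"]]), numeric(1))
  expect_equal(unname(diff(starts)), rep(-0.36, 9), tolerance = 5e-5)

  # Per-frame angles equal the rotation model applied to the simulator
  # truth timestamps.
  expect_equal(man$osc_start,
               sw$rotation$start_angle +
                 sw$rotation$rate * sw$truth$timings$timestamp,
               tolerance = 1e-9)

  # Manifest total rotation = rate x sweep duration.
  mf <- readLines(file.path(out, "cat_manifest.txt"))
  tot <- as.numeric(sub(".*=", "", grep("total_rotation", mf, value = TRUE)))
  expect_equal(tot, -0.36 * 10, tolerance = 1e-9)

  # Count conservation through binning + pedestal, with zero clipping.
  expect_equal(sum(man$clipped_low) + sum(man$clipped_high), 0)
  img1 <- read_smv(files[1])
  expect_equal(sum(img1$pixels) - 512 * length(img1$pixels),
               sum(sw$stack$frames[[1]]))

  # Byte-identical on a second run.
  out2 <- withr::local_tempdir()
  convert_sweep(sw$stack, sw$geometry, sw$rotation, out2,
                prefix = "cat", bin_factor = 2)
  for (f in basename(files))
    expect_identical(unname(tools::md5sum(file.path(out, f))),
                     unname(tools::md5sum(file.path(out2, f))))

  # Header geometry survives the round trip to formatting precision.
  h <- img1$header
  expect_equal(as.numeric(h[["DISTANCE"]]), sw$geometry$distance)
  expect_equal(as.numeric(h[["WAVELENGTH"]]),
               sw$geometry$beam$wavelength, tolerance = 1e-4)
  expect_equal(as.integer(h[["SIZE1"]]), sw$geometry$dimensions[1] %/% 2L)
  expect_equal(as.integer(h[["IMAGE_PEDESTAL"]]), 512L)
})

test_that("flat key=value config files parse with comments and blanks ignored", {
  p <- withr::local_tempfile()
  writeLines(c("# conversion defaults", "distance=520", "",
               "rotation-rate=-0.36  # signed", "prefix=cat"), p)
  cfg <- read_config(p)
  expect_equal(cfg$distance, "520")
  expect_equal(cfg$`rotation-rate`, "-0.36")
  expect_equal(cfg$prefix, "cat")
  p2 <- withr::local_tempfile()
  writeLines("no equals sign here", p2)
  expect_error(read_config(p2), class = "parse_error")
})
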