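# Independent brute-force oracle for the diffracting condition: build
# the reciprocal lattice from scratch, rotate it about the tilt axis on
# a dense angular grid, and count reflections whose Ewald-plane
# distance changes sign inside a frame's rotation interval.
oracle_frame_counts <- function(cell, U, dmin, low_res, phi_lo, phi_hi,
                                geom) {
  hmax <- ceiling(cell[1:3] / dmin)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  g <- g[rowSums(g != 0) > 0, ]
  q <- U %*% rbind(g$h / cell[1], g$k / cell[2], g$l / cell[3])
  qlen <- sqrt(colSums(q^2))
  keep <- qlen <= 1 / dmin & qlen >= 1 / low_res
  q <- q[, keep, drop = FALSE]; qlen <- qlen[keep]
  # On-detector restriction, same small-angle projection recomputed
  # longhand (radius from |q| only; azimuth irrelevant to the count if
  # margins are honoured by radius).
  lambda <- geom$beam$wavelength
  counts <- integer(length(phi_lo))
  for (i in seq_along(phi_lo)) {
    grid <- seq(phi_lo[i], phi_hi[i], length.out = 200)
    n <- 0L
    for (j in seq_len(ncol(q))) {
      qz <- q[2, j] * sin(grid * pi / 180) + q[3, j] * cos(grid * pi / 180)
      if (min(qz) < 0 && max(qz) > 0) {
        # crossed the plane: check the detector position at the crossing
        k0 <- which.min(abs(qz))
        p <- grid[k0] * pi / 180
        qx <- q[1, j]
        qy <- q[2, j] * cos(p) - q[3, j] * sin(p)
        r_mm <- geom$distance * tan(2 * asin(lambda * qlen[j] / 2))
        qp <- max(sqrt(qx^2 + qy^2), 1e-12)
        x <- geom$beam_center[1] + r_mm * qx / qp / geom$pixel_size
        y <- geom$beam_center[2] + r_mm * qy / qp / geom$pixel_size
        if (x > 3 && x < geom$dimensions[1] - 2 &&
            y > 3 && y < geom$dimensions[2] - 2)
          n <- n + 1L
      }
    }
    counts[i] <- n
  }
  counts
}

test_that("the simulator is bit-reproducible under a fixed seed", {
  sw1 <- sparse_sweep(seed = 4, n_frames = 3)
  sw2 <- sparse_sweep(seed = 4, n_frames = 3)
  expect_identical(sw1$stack$frames, sw2$stack$frames)
  expect_equal(sw1$truth$spots, sw2$truth$spots)
  sw3 <- sparse_sweep(seed = 5, n_frames = 3)
  expect_false(identical(sw1$stack$frames, sw3$stack$frames))
})

test_that("partial intensities of interior reflections sum to the full intensity", {
  geom <- std_geometry()
  rot <- rotation_model(rate = 0.36)
  cry <- virtual_crystal(cell = c(20, 22, 16, 90, 90, 90),
                         orientation = generic_orientation(),
                         mosaicity = 0.15, resolution_limit = 2.5,
                         intensity_scale = 20000)
  cfg <- simulation_config(geom, rot, n_frames = 8, exposure = 1,
                           background_mean = 20, gain = 2, seed = 12,
                           min_partial = 1e-9)
  sw <- simulate_sweep(cry, cfg)
  sp <- sw$truth$spots
  full <- sw$truth$full_intensities
  # Sweep covers [0, 2.88] deg; keep reflections whose rocking curve
  # lies well inside (6 sigma from either edge), so the whole curve is
  # recorded across contiguous frames.
  agg <- stats::aggregate(cbind(intensity = sp$intensity, part = sp$partial),
                          by = sp[, c("h", "k", "l", "pass", "phi_star")],
                          FUN = sum)
  m <- merge(agg, full, by = c("h", "k", "l"))
  interior <- abs(m$phi_star - 1.44) < 1.44 - 6 * m$sigma_phi
  expect_gt(sum(interior), 0)
  expect_lt(max(abs(m$part[interior] - 1)), 1e-6)
  expect_lt(max(abs(m$intensity.x[interior] / m$intensity.y[interior] - 1)),
            1e-6)
})

test_that("background statistics follow the gain-scaled Poisson model", {
  geom <- std_geometry(dims = c(128, 128))
  cfg <- simulation_config(geom, rotation_model(rate = 0.5), n_frames = 1,
                           exposure = 1, background_mean = 30, gain = 2.5,
                           seed = 8)
  # Crystal diffracting entirely off this small detector: background only.
  cry <- virtual_crystal(cell = c(8, 8, 6, 90, 90, 90),
                         resolution_limit = 2.5, intensity_scale = 1)
  fr <- simulate_sweep(cry, cfg)$stack$frames[[1]]
  expect_equal(mean(fr), 2.5 * 30, tolerance = 0.01)
  g <- estimate_gain(fr, trim = 0)
  expect_lt(abs(g$gain - 2.5) / 2.5, 0.05)
})

test_that("rotation reversal mirrors the frame phi intervals exactly", {
  rotf <- rotation_model(rate = 0.36, start_angle = 1)
  rotr <- rotation_model(rate = -0.36, start_angle = -1)
  tm <- frame_timings(10, exposure = 1)
  ff <- frame_rotation(rotf, tm)
  rr <- frame_rotation(rotr, tm)
  expect_equal(rr$osc_start, -ff$osc_start)
  expect_equal(rr$phi_mid, -ff$phi_mid)
  expect_equal(rr$osc_range, ff$osc_range)
})

test_that("per-frame ground-truth spot counts match the brute-force oracle at low mosaicity", {
  geom <- std_geometry()
  rot <- rotation_model(rate = 0.5, start_angle = 0)
  cell <- c(28, 32, 24, 90, 90, 90)
  U <- generic_orientation()
  cry <- virtual_crystal(cell = cell, orientation = U, mosaicity = 0.02,
                         resolution_limit = 2.6, intensity_scale = 1e5)
  cfg <- simulation_config(geom, rot, n_frames = 4, exposure = 2,
                           background_mean = 10, gain = 1, seed = 77,
                           min_partial = 0.5)
  sw <- simulate_sweep(cry, cfg)
  sim_counts <- tabulate(sw$truth$spots$frame, nbins = 4)
  fr <- frame_rotation(rot, sw$stack$timings)
  oracle <- oracle_frame_counts(cell, U, 2.6, cfg$low_res_limit,
                                fr$osc_start, fr$osc_start + 1, geom)
  expect_gt(sum(oracle), 0)
  expect_equal(sim_counts, oracle)
})

test_that("tilt-limited reciprocal coverage approaches sin(alpha)", {
  cry <- virtual_crystal(cell = c(40, 40, 30, 90, 90, 90),
                         resolution_limit = 3)
  cov90 <- reciprocal_coverage(cry, tilt_limit = 90, azimuth_step = 5)
  expect_equal(cov90$fraction, 1.0)
  cov30 <- reciprocal_coverage(cry, tilt_limit = 30, azimuth_step = 2)
  expect_lt(abs(cov30$fraction - 0.5), 0.02)
})

test_that("powder simulation closes the loop with distance calibration", {
  geom <- std_geometry(dims = c(512, 512), center = c(256, 256),
                       pixel_size = 0.0312)
  dsp <- c(2.35, 2.04, 1.66)
  img <- simulate_powder_image(dsp, geom, ring_intensity = 250,
                               background_mean = 15, seed = 19)
  rings <- fit_powder_rings(img, c(256, 256), 3)
  cal <- calibrate_distance(rings, dsp, geom$beam$wavelength,
                            geom$pixel_size)
  expect_lt(abs(cal$distance - 520) / 520, 0.005)

  # Unreachable resolution propagates from the geometry module.
  expect_error(simulate_powder_image(c(0.01), geom, seed = 1),
               class = "unreachable_resolution")
})

test_that("defect injection is book-kept exactly and a no-op when empty", {
  stk <- background_stack(n_frames = 5, dims = c(128, 128), seed = 2)
  out <- inject_defects(stk, n_hot = 50, n_dead = 30, seed = 6)
  expect_equal(nrow(out$map), 80)
  expect_equal(sum(out$map$type == "hot"), 50)
  expect_equal(anyDuplicated(out$map[, c("x", "y")]), 0)
  med <- median(stk$frames[[1]])
  hot1 <- out$map[out$map$type == "hot", ][1, ]
  expect_equal(out$stack$frames[[1]][hot1$x, hot1$y], round(10 * med))
  dead1 <- out$map[out$map$type == "dead", ][1, ]
  expect_equal(out$stack$frames[[3]][dead1$x, dead1$y], 0L)

  same <- inject_defects(stk, seed = 1)
  expect_identical(same$stack$frames, stk$frames)
  expect_equal(nrow(same$map), 0)

  expect_error(inject_defects(stk, n_hot = 5000, seed = 1),
               class = "invalid_argument")
})

test_that("sweeps beyond the stage tilt limit are refused", {
  geom <- std_geometry(dims = c(64, 64))
  rot <- rotation_model(rate = 2, start_angle = 60, tilt_limit = 70)
  cry <- virtual_crystal(cell = c(20, 20, 15, 90, 90, 90))
  cfg <- simulation_config(geom, rot, n_frames = 10, exposure = 1,
                           seed = 1)
  expect_error(simulate_sweep(cry, cfg), class = "stage_limit")
})
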