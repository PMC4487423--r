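# Shared synthetic fixtures.  Everything is generated in code under a
# fixed seed; no binary files are shipped.

std_beam <- function() beam_parameters(voltage = 200)

std_geometry <- function(dims = c(256, 256), center = dims / 2,
                         distance = 520, pixel_size = 0.0624) {
  experiment_geometry(std_beam(), distance = distance,
                      beam_center = center, pixel_size = pixel_size,
                      dimensions = dims)
}

# A single-frame Friedel-symmetric diffraction pattern with the direct
# beam at (cx, cy); moderate spot density, deterministic by seed.
friedel_pattern <- function(cx, cy, seed, dims = c(256, 256)) {
  geom <- experiment_geometry(std_beam(), 520, c(cx, cy), 0.0624, dims)
  rot <- rotation_model(rate = 1, start_angle = -1)
  cry <- virtual_crystal(cell = c(60, 60, 40, 90, 90, 90),
                         orientation = generic_orientation(),
                         mosaicity = 0.5, resolution_limit = 2.8,
                         intensity_scale = 8000)
  cfg <- simulation_config(geom, rot, n_frames = 1, exposure = 2,
                           background_mean = 20, gain = 2, seed = seed)
  simulate_sweep(cry, cfg)$stack$frames[[1]]
}

# Background-only stack for bad-pixel statistics.
background_stack <- function(n_frames = 20, dims = c(256, 256), mean = 50,
                             seed = 11) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i)
    matrix(rpois(prod(dims), mean), dims[1], dims[2]))
  frame_stack(frames, frame_timings(n_frames, exposure = 1))
}

# A frame with n strong, well-separated Gaussian spots at known
# positions on Poisson background; returns the frame and the truth.
spotted_frame <- function(n = 12, dims = c(256, 256), intensity = 30000,
                          bg = 20, gain = 2, sigma = 1.5, seed = 3) {
  set.seed(seed)
  repeat {
    xs <- runif(n, 20, dims[1] - 20)
    ys <- runif(n, 20, dims[2] - 20)
    if (n == 1 || min(dist(cbind(xs, ys))) > 20) break
  }
  lam <- matrix(bg, dims[1], dims[2])
  for (i in seq_len(n)) {
    xr <- floor(xs[i] - 8):ceiling(xs[i] + 8)
    yr <- floor(ys[i] - 8):ceiling(ys[i] + 8)
    lam[xr, yr] <- lam[xr, yr] +
      intensity * outer(dnorm(xr, xs[i], sigma), dnorm(yr, ys[i], sigma))
  }
  frame <- matrix(gain * rpois(length(lam), as.vector(lam)),
                  dims[1], dims[2])
  list(frame = frame, x = xs, y = ys, gain = gain)
}

# A generic crystal orientation (a crystal never lands on the grid
# with a zone axis exactly along the beam).
generic_orientation <- function() axis_angle_rotation(c(1, 0.6, 0.3), 25)

# Sparse sweep whose spots are isolated enough for clean box
# integration: small cell, low mosaicity, strong intensities.
sparse_sweep <- function(seed = 21, n_frames = 8, rate = 0.36,
                         start_angle = 0, mosaicity = 0.25,
                         orientation = generic_orientation()) {
  geom <- std_geometry()
  rot <- rotation_model(rate = rate, start_angle = start_angle)
  cry <- virtual_crystal(cell = c(20, 22, 16, 90, 90, 90),
                         orientation = orientation,
                         mosaicity = mosaicity, resolution_limit = 2.5,
                         intensity_scale = 20000)
  cfg <- simulation_config(geom, rot, n_frames = n_frames, exposure = 1,
                           background_mean = 20, gain = 2, seed = seed)
  c(simulate_sweep(cry, cfg), list(geometry = geom, rotation = rot,
                                   config = cfg, crystal = cry))
}

# Pick a ground-truth reflection pass whose detector neighbourhood is
# free of other spots on every frame (for clean rocking curves).
isolated_reflection <- function(truth, min_sep = 16, min_intensity = 5000) {
  sp <- truth$spots
  keys <- unique(sp[, c("h", "k", "l", "pass")])
  for (i in seq_len(nrow(keys))) {
    rows <- merge(sp, keys[i, ])
    if (sum(rows$intensity) < min_intensity) next
    x0 <- mean(rows$x); y0 <- mean(rows$y)
    others <- sp[!(sp$h == keys$h[i] & sp$k == keys$k[i] &
                     sp$l == keys$l[i] & sp$pass == keys$pass[i]), ]
    d2 <- (others$x - x0)^2 + (others$y - y0)^2
    if (all(d2 > min_sep^2)) return(rows[order(rows$frame), ])
  }
  NULL
}
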