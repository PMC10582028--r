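# Shared fixtures, built in code at test time.

fixture_template <- function(box = 32, lowpass = 6) {
  prepare_template(make_phantom("torus", box), 1, 1, lowpass = lowpass)
}

fixture_blob_template <- function(box = 32) {
  prepare_template(make_phantom("blob", box, seed = 5), 1, 1)
}

# Small noise-free simulated scene: specimen, tilt series, tomogram, truth.
fixture_scene <- function(shape = c(64, 64, 48), n = 2, seed = 7,
                          snr = Inf, min_dist = 24, border = 18) {
  phantom <- make_phantom("torus", 32, ring_radius = 6, tube_radius = 3)
  gt <- place_particles(shape, n, min_dist = min_dist, border = border,
                        seed = seed)
  spec <- render_specimen(gt, phantom, shape)
  sc <- tilt_scheme(-45, 45, 3)
  ts <- simulate_tilt_series(spec, sc, noise_sigma = 0, seed = seed)
  if (is.finite(snr)) ts$images <- degrade_to_snr(ts$images, snr, seed + 1)
  list(phantom = phantom, gt = gt, specimen = spec, scheme = sc, ts = ts)
}

# Rotation matrix -> unit quaternion (w, x, y, z), w >= 0 (Shepperd's
# method: branch on the largest diagonal term for numerical safety).
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(diag(R))) {
    s <- 2 * sqrt(1 + tr)
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- 2 * sqrt(max(1e-12, 1 + R[i, i] - R[j, j] - R[k, k]))
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) -q else q
}

expect_volumes_correlate <- function(a, b, min_cc) {
  cc <- cor(as.vector(a), as.vector(b))
  expect_gt(cc, min_cc)
  invisible(cc)
}
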