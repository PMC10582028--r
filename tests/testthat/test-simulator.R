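# Phantoms, particle placement, tilt-series simulation, SNR control.

test_that("tilt schemes have the right size and dose-symmetric order", {
  sc <- tilt_scheme(-45, 45, 3)
  expect_length(sc$angles, 31)
  # acquisition sequence: 0, +3, -3, -6, +6, +9, ... (groups of 2)
  acq <- sc$angles[order(sc$acquisition_order)]
  expect_equal(acq[1:8], c(0, 3, -3, -6, 6, 9, -9, -12))
  # sequential ordering is by angle
  ss <- tilt_scheme(-45, 45, 3, ordering = "sequential")
  expect_equal(ss$angles[order(ss$acquisition_order)], ss$angles)
  expect_error(tilt_scheme(45, -45, 3))
})

test_that("accumulated dose is non-decreasing and honors zero-tilt override", {
  sc <- tilt_scheme(-45, 45, 3, dose_per_tilt = 3, zero_tilt_dose = 15)
  ord <- order(sc$acquisition_order)
  expect_true(all(diff(sc$accumulated_dose[ord]) > 0))
  expect_equal(sc$dose[sc$angles == 0], 15)
  expect_equal(sc$accumulated_dose[sc$angles == 0], 15)
  expect_equal(max(sc$accumulated_dose), 15 + 30 * 3)
})

test_that("phantoms match their analytic geometry", {
  # torus: half-max volume vs 2 pi^2 R r^2 (radii large enough that the
  # voxelization error of the half-max surface stays small)
  R0 <- 12; r0 <- 5
  tor <- make_phantom("torus", 64, ring_radius = R0, tube_radius = r0)
  expect_equal(sum(tor >= 0.5), 2 * pi^2 * R0 * r0^2, tolerance = 0.05)
  expect_true(all(tor >= 0))
  expect_equal(max(tor[1, , ]), 0)  # zero at the box faces
  expect_error(make_phantom("torus", 32, ring_radius = 14, tube_radius = 4),
               "exceed")
  # sphere: invariant under 90-degree axis rotations (exact grid
  # permutations under the periodic rotation convention)
  sp <- make_phantom("sphere", 32, radius = 8)
  expect_equal(sp, aperm(sp, c(2, 1, 3)))
  r90 <- tomosta:::cpp_rotate3(as.numeric(sp), rep(32L, 3),
                               tomosta:::rot_x(90), c(0, 0, 0))
  expect_equal(array(r90, rep(32, 3)), sp, tolerance = 1e-12)
  # blob: deterministic given the seed, asymmetric
  b1 <- make_phantom("blob", 24, seed = 4)
  b2 <- make_phantom("blob", 24, seed = 4)
  expect_identical(b1, b2)
  expect_false(isTRUE(all.equal(b1, aperm(b1, c(2, 1, 3)))))
})

test_that("particle placement respects distances and is deterministic", {
  gt <- place_particles(c(256, 256, 256), 20, min_dist = 40, border = 20,
                        seed = 5)
  expect_equal(nrow(gt$positions), 20)
  dmat <- as.matrix(dist(gt$positions))
  expect_true(all(dmat[upper.tri(dmat)] >= 40))
  expect_true(all(gt$positions >= 20 & gt$positions <= 235))
  gt2 <- place_particles(c(256, 256, 256), 20, min_dist = 40, border = 20,
                         seed = 5)
  expect_identical(gt, gt2)
  expect_error(place_particles(c(64, 64, 64), 500, min_dist = 20, border = 8),
               "infeasible")
})

test_that("sampled orientations are uniform over rotation space", {
  set.seed(6)
  rots <- tomosta:::random_rotations(5000)
  m <- Reduce(`+`, rots) / length(rots)
  expect_lt(max(abs(m)), 0.05)
})

test_that("render_specimen places rotated phantoms and beads", {
  ph <- make_phantom("torus", 32, ring_radius = 6, tube_radius = 3)
  gt <- list(positions = matrix(c(32, 32, 32), 1),
             orientations = data.frame(tdrot = 0, tilt = 0, narot = 0),
             bead_positions = matrix(numeric(0), 0, 3))
  vol <- render_specimen(gt, ph, c(64, 64, 64))
  crop <- vol[17:48, 17:48, 17:48]
  expect_gt(cor(as.vector(crop), as.vector(ph)), 0.999)
  # beads: rendered suprathreshold diameter within 1 voxel of nominal
  gt2 <- list(positions = matrix(numeric(0), 0, 3),
              orientations = data.frame(tdrot = numeric(0),
                                        tilt = numeric(0),
                                        narot = numeric(0)),
              bead_positions = matrix(c(32, 32, 32), 1))
  volb <- render_specimen(gt2, ph, c(64, 64, 64), bead_diameter = 10,
                          bead_density_mult = 10)
  prof <- volb[, 33, 33]
  expect_equal(sum(prof >= max(volb) / 2), 10, tolerance = 1)
})

test_that("empty ground truth renders a zero volume", {
  ph <- make_phantom("sphere", 16, radius = 5)
  gt <- list(positions = matrix(numeric(0), 0, 3),
             orientations = data.frame(),
             bead_positions = matrix(numeric(0), 0, 3))
  expect_equal(max(abs(render_specimen(gt, ph, c(32, 32, 32)))), 0)
})

test_that("projections integrate the specimen along the beam", {
  set.seed(7)
  spec <- array(runif(32 * 32 * 24), c(32, 32, 24))
  sc <- tilt_scheme(-45, 45, 15)
  ts <- simulate_tilt_series(spec, sc, noise_sigma = 0)
  expect_equal(dim(ts$images)[3], length(sc$angles))
  # 0-degree projection equals the z sum exactly
  i0 <- which(ts$angles == 0)
  expect_equal(ts$images[, , i0], apply(spec, c(1, 2), sum),
               tolerance = 1e-12)
  # total projected mass is conserved at 0 degrees
  expect_equal(sum(ts$images[, , i0]), sum(spec), tolerance = 1e-6)
  expect_error(simulate_tilt_series(spec, sc, noise_sigma = -1))
  # deterministic given the seed
  ts2 <- simulate_tilt_series(spec, sc, noise_sigma = 0.5, seed = 3)
  ts3 <- simulate_tilt_series(spec, sc, noise_sigma = 0.5, seed = 3)
  expect_identical(ts2$images, ts3$images)
})

test_that("CTF modulation enters the simulated images", {
  spec <- make_phantom("sphere", 32, radius = 8)
  sc <- tilt_scheme(-15, 15, 15)
  cp <- ctf_params(defocus_um = 3, pixel_size = 2)
  ts0 <- simulate_tilt_series(spec, sc, ctf = NULL, noise_sigma = 0)
  ts1 <- simulate_tilt_series(spec, sc, ctf = cp, noise_sigma = 0)
  expect_false(isTRUE(all.equal(ts0$images, ts1$images)))
  expect_equal(ts1$defocus_um, rep(3, 3))
})

test_that("degrade_to_snr hits the target signal-to-noise ratio", {
  set.seed(8)
  sig <- array(rnorm(64 * 64 * 8), c(64, 64, 8))  # unit-variance signal
  out <- degrade_to_snr(sig, 1, seed = 1)
  expect_equal(var(as.vector(out - sig)), 1, tolerance = 0.02)
  expect_identical(degrade_to_snr(sig, 1e7), sig)
  expect_error(degrade_to_snr(array(0, c(4, 4, 4)), 1), "zero-variance")
  for (snr in c(0.1, 0.5, 2)) {
    out <- degrade_to_snr(sig, snr, seed = 2)
    measured <- var(as.vector(sig)) / var(as.vector(out - sig))
    expect_equal(measured, snr, tolerance = 0.02)  # relative 2%
  }
})

test_that("tilt series round trip through MRC + JSON sidecar", {
  sc <- tilt_scheme(-30, 30, 15, zero_tilt_dose = 15)
  spec <- make_phantom("sphere", 24, radius = 7)
  ts <- simulate_tilt_series(spec, sc, noise_sigma = 0.1, seed = 2)
  ts$pixel_size <- 2.62
  f <- withr::local_tempfile(fileext = ".mrc")
  write_tilt_series(ts, f)
  rb <- read_tilt_series(f)
  expect_equal(rb$images, ts$images, tolerance = 1e-6)
  expect_equal(rb$angles, ts$angles)
  expect_equal(rb$dose, ts$dose)
  expect_equal(rb$pixel_size, 2.62, tolerance = 1e-6)
})
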