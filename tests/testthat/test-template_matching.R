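# Template preparation, the matching engine, CC-map cleanup, peak extraction.

test_that("prepare_template normalizes, resamples and low-passes", {
  ph <- make_phantom("blob", 32, seed = 5)
  # equal voxel sizes, no low-pass: only normalization under the mask
  p <- prepare_template(ph, 2, 2)
  nm <- sum(p$mask)
  expect_equal(sum(p$mask * p$template) / nm, 0, tolerance = 1e-9)
  expect_equal(sum(p$mask * p$template^2) / nm, 1, tolerance = 1e-9)
  # resampling 2 -> 4 A/voxel halves the box
  p2 <- prepare_template(ph, 2, 4)
  expect_equal(p2$box, 16)
  # low-pass removes nearly all power above the cutoff
  p3 <- prepare_template(ph, 2, 2, lowpass = 12)
  sp <- Mod(fft(p3$template))^2
  r <- tomosta:::radius_grid(rep(32, 3))
  cutoff <- 32 * 2 / 12
  frac <- sum(sp[r > cutoff + 2]) / sum(sp)
  expect_lt(frac, 0.01)
  expect_error(prepare_template(ph, 2, 2, lowpass = 3), "Nyquist")
})

test_that("matching finds position and orientation of a pasted template", {
  prep <- fixture_blob_template(32)
  grid <- generate_grid(20, 0, 20, 360, "C1")
  b <- 32; cb <- 16; pos <- c(30, 25, 20)
  paste_at <- function(vol, x) {
    vol[pos[1] - cb + 1:b, pos[2] - cb + 1:b, pos[3] - cb + 1:b] <-
      vol[pos[1] - cb + 1:b, pos[2] - cb + 1:b, pos[3] - cb + 1:b] + x
    vol
  }
  tomo <- paste_at(array(0, c(64, 64, 48)), prep$template)
  res <- match_template(tomo, prep$template, prep$mask, grid)
  i <- which.max(res$cc_map)
  expect_equal(as.integer(arrayInd(i, dim(res$cc_map)) - 1L), pos)
  expect_gte(res$cc_map[i], 0.999)
  expect_equal(res$orient_map[i], 1L)
  expect_true(all(res$cc_map >= -1 & res$cc_map <= 1))

  # template pasted rotated by an exact grid rotation
  R7 <- euler_to_matrix(as.numeric(grid[7, 1:3]))
  rot <- tomosta:::cpp_rotate3(as.numeric(prep$template), rep(32L, 3), R7,
                               c(0, 0, 0))
  tomo2 <- paste_at(array(0, c(64, 64, 48)), array(rot, rep(32, 3)))
  res2 <- match_template(tomo2, prep$template, prep$mask, grid)
  i2 <- which.max(res2$cc_map)
  expect_equal(as.integer(arrayInd(i2, dim(res2$cc_map)) - 1L), pos)
  expect_equal(res2$orient_map[i2], 7L)
})

test_that("chunked matching equals unchunked matching", {
  set.seed(4)
  prep <- fixture_blob_template(32)
  grid <- generate_grid(20, 0, 20, 360, "C1")
  tomo <- array(rnorm(64 * 64 * 48, 0, 0.1), c(64, 64, 48))
  rot <- tomosta:::cpp_rotate3(as.numeric(prep$template), rep(32L, 3),
                               euler_to_matrix(as.numeric(grid[5, 1:3])),
                               c(0, 0, 0))
  tomo[15 + 1:32, 20 + 1:32, 8 + 1:32] <-
    tomo[15 + 1:32, 20 + 1:32, 8 + 1:32] + rot
  full <- match_template(tomo, prep$template, prep$mask, grid)
  chunked <- match_template(tomo, prep$template, prep$mask, grid, chunk = 48)
  expect_lt(max(abs(full$cc_map - chunked$cc_map)), 1e-5)
  expect_error(match_template(tomo, prep$template, prep$mask, grid,
                              chunk = 16), "smaller than the template")
})

test_that("matching is translation-equivariant in the chunk interior", {
  set.seed(5)
  prep <- fixture_blob_template(32)
  grid <- generate_grid(20, 0, 120, 360, "C1")  # few orientations
  tomo <- array(rnorm(64 * 64 * 48, 0, 0.1), c(64, 64, 48))
  tomo[15 + 1:32, 15 + 1:32, 8 + 1:32] <-
    tomo[15 + 1:32, 15 + 1:32, 8 + 1:32] + prep$template
  r1 <- match_template(tomo, prep$template, prep$mask, grid)
  shifted <- tomo[c(61:64, 1:60), , ]  # +4 voxels in x, periodic
  r2 <- match_template(shifted, prep$template, prep$mask, grid)
  # cc2(x) = cc1(x - 4), so un-shifting r2 recovers r1
  expect_equal(r2$cc_map[c(5:64, 1:4), , ], r1$cc_map, tolerance = 1e-5)
})

test_that("wedge-filtered matching still peaks at the particle", {
  angles <- seq(-45, 45, 3)
  prep <- fixture_template(32)
  grid <- generate_grid(25, 0, 25, 360, "C1")
  wm <- wedge_mask(angles, rep(32, 3))
  rot <- prep$template
  filt <- Re(fft(fft(rot) * wm, inverse = TRUE)) / 32^3
  tomo <- array(rnorm(64 * 64 * 48, 0, 0.05), c(64, 64, 48))
  tomo[15 + 1:32, 15 + 1:32, 8 + 1:32] <-
    tomo[15 + 1:32, 15 + 1:32, 8 + 1:32] + filt
  res <- match_template(tomo, prep$template, prep$mask, grid, wedge = angles)
  i <- which.max(res$cc_map)
  expect_equal(as.integer(arrayInd(i, dim(res$cc_map)) - 1L), c(31, 31, 24))
  expect_gt(res$cc_map[i], 0.9)
})

test_that("an all-constant region yields CC 0, never NaN", {
  prep <- fixture_blob_template(32)
  grid <- generate_grid(20, 0, 360, 360, "C1")
  tomo <- array(1, c(48, 48, 48))
  res <- match_template(tomo, prep$template, prep$mask, grid)
  expect_true(all(is.finite(res$cc_map)))
  expect_equal(max(abs(res$cc_map)), 0)
})

test_that("postprocess_cc removes large islands but keeps point peaks", {
  set.seed(6)
  cc <- array(rnorm(48^3, 0, 0.01), rep(48, 3))
  cc[24 + 0:1, 24, 24] <- 0.9                       # point-like peak
  cc[5:14, 5:34, 5:14] <- 0.8                       # ~3000-voxel ridge
  out <- postprocess_cc(cc, island_max_size = 100)
  expect_equal(out[24, 24, 24], 0.9)
  expect_equal(max(out[5:14, 5:34, 5:14]), 0)
  expect_identical(postprocess_cc(cc, Inf), cc)
  # all-noise map stays unchanged (no suprathreshold component that large)
  noise <- array(rnorm(32^3, 0, 0.01), rep(32, 3))
  expect_identical(postprocess_cc(noise, 100), noise)
})

test_that("peak extraction applies sigma threshold, cap and suppression", {
  set.seed(7)
  cc <- array(rnorm(48^3), rep(48, 3))
  cc <- cc / sd(cc) - mean(cc)
  spots <- rbind(c(10, 10, 10), c(30, 12, 20), c(20, 35, 30), c(40, 40, 12),
                 c(12, 28, 40))
  amps <- c(12, 11.5, 11, 10.5, 10)
  for (i in 1:5) cc[spots[i, 1] + 1, spots[i, 2] + 1, spots[i, 3] + 1] <- amps[i]
  mr <- structure(list(cc_map = cc,
                       orient_map = array(1L, dim(cc)),
                       grid = generate_grid(20, 0, 360, 360, "C1")),
                  class = "match_result")
  tbl <- extract_peaks(mr, threshold_sigma = 7, exclusion_radius = 4)
  expect_equal(nrow(tbl), 5)
  expect_equal(tbl$cc, sort(tbl$cc, decreasing = TRUE))
  expect_equal(as.matrix(tbl[, c("x", "y", "z")]), spots,
               ignore_attr = TRUE)
  # cap semantics
  tbl3 <- extract_peaks(mr, threshold_sigma = 3, max_particles = 3,
                        exclusion_radius = 4)
  expect_equal(nrow(tbl3), 3)
  expect_equal(tbl3$cc, amps[1:3], tolerance = 1e-9)
  # two nearby spikes collapse under suppression
  cc2 <- array(0, rep(32, 3))
  cc2[15, 15, 15] <- 1; cc2[17, 15, 15] <- 0.9
  mr2 <- mr; mr2$cc_map <- cc2; mr2$orient_map <- array(1L, rep(32, 3))
  t2 <- extract_peaks(mr2, threshold_sigma = 7, exclusion_radius = 4)
  expect_equal(nrow(t2), 1)
  # monotonicity in threshold and exclusion radius
  n_thr <- vapply(c(3, 5, 7), function(s)
    nrow(extract_peaks(mr, threshold_sigma = s, exclusion_radius = 4)),
    integer(1))
  expect_true(all(diff(n_thr) <= 0))
  expect_error(extract_peaks(mr, NULL, NULL, 4), "at least one")
})

test_that("gold beads are erased to background statistics", {
  set.seed(8)
  img <- matrix(rnorm(256 * 256), 256, 256)
  beads <- rbind(c(60, 60), c(200, 80), c(120, 180), c(40, 220), c(220, 220))
  ax <- -8:8
  disc <- tomosta:::soft_edge(sqrt(outer(ax^2, ax^2, `+`)), 4.5, 1) * 30
  for (i in 1:5)
    img[beads[i, 1] + ax + 1, beads[i, 2] + ax + 1] <-
      img[beads[i, 1] + ax + 1, beads[i, 2] + ax + 1] + disc
  out <- erase_gold(img, bead_diameter_px = 10, positions = beads)
  for (i in 1:5)
    expect_lt(abs(out$image[beads[i, 1] + 1, beads[i, 2] + 1]), 3)
  # auto-detection finds the beads and erases them
  auto <- erase_gold(img, bead_diameter_px = 10)
  expect_gte(nrow(auto$positions), 4)
  for (i in seq_len(nrow(auto$positions))) {
    d <- sqrt(rowSums(sweep(beads, 2, auto$positions[i, ])^2))
    expect_lt(min(d), 3)
  }
  # null image: at most one false detection, untouched elsewhere
  clean <- matrix(rnorm(256 * 256), 256, 256)
  nul <- erase_gold(clean, bead_diameter_px = 10)
  expect_lte(nrow(nul$positions), 1)
  # explicit empty positions -> identity
  idn <- erase_gold(img, 10, positions = matrix(numeric(0), 0, 2))
  expect_identical(idn$image, img)
})

test_that("grid edges are erased only when touching the border", {
  set.seed(9)
  img <- matrix(rnorm(128 * 128, mean = 10), 128, 128)
  img[90:128, ] <- img[90:128, ] * 0.05          # dark right third (grid bar)
  res <- erase_grid_edge(img, intensity_drop_threshold = 0.5)
  dark <- matrix(FALSE, 128, 128); dark[90:128, ] <- TRUE
  expect_gt(sum(res$mask & dark) / sum(dark), 0.95)
  expect_lt(sum(res$mask & !dark) / sum(!dark), 0.02)
  expect_equal(mean(res$image[90:128, ]), 10, tolerance = 1)
  # uniform image -> empty mask, identity
  uni <- matrix(10, 64, 64)
  r0 <- erase_grid_edge(uni)
  expect_false(any(r0$mask))
  expect_identical(r0$image, uni)
  # interior dark blob is not a grid edge
  img2 <- matrix(rnorm(128 * 128, mean = 10), 128, 128)
  img2[50:70, 50:70] <- 0.01
  r2 <- erase_grid_edge(img2, intensity_drop_threshold = 0.5)
  expect_false(any(r2$mask[50:70, 50:70]))
})

test_that("edge tapering blends to the mean and spares the interior", {
  set.seed(10)
  img <- matrix(rnorm(64 * 64, 3), 64, 64)
  expect_identical(taper_edges(img, 0), img)
  tp <- taper_edges(img, 8)
  expect_equal(tp[1, 1], mean(img), tolerance = 1e-6)
  expect_identical(tp[9:56, 9:56], img[9:56, 9:56])
  vol <- array(rnorm(24^3), rep(24, 3))
  tv <- taper_edges(vol, 4)
  expect_equal(tv[1, 1, 1], mean(vol), tolerance = 1e-6)
  expect_identical(tv[5:20, 5:20, 5:20], vol[5:20, 5:20, 5:20])
})
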