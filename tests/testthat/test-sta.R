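# Extraction, noise traps, alignment, classification, averaging, FSC.

test_that("extraction recenters by folding shifts into positions", {
  sc <- fixture_scene(shape = c(96, 96, 64), n = 2, seed = 7,
                       min_dist = 24, border = 30)
  tomo <- wbp_reconstruct(sc$ts, 64)
  tbl <- particle_table(2)
  tbl$tag <- 1:2
  tbl$x <- sc$gt$positions[, 1]; tbl$y <- sc$gt$positions[, 2]
  tbl$z <- sc$gt$positions[, 3]
  tbl$dx <- c(0.4, 3.7); tbl$dy <- c(-0.3, 0); tbl$dz <- 0
  st <- extract_particles(tomo, tbl, 16, recenter = TRUE)
  expect_equal(st$table$x, tbl$x + c(0, 4))
  expect_equal(st$table$dx, c(0.4, -0.3), tolerance = 1e-12)
  expect_equal(st$table$dy, c(-0.3, 0))
  expect_length(st$boxes, 2)
  expect_error(extract_particles(tomo, particle_table(0), 16), "empty")
})

test_that("orientation randomization replaces Euler triplets uniformly", {
  sc <- fixture_scene(shape = c(96, 96, 64), n = 2, seed = 7,
                       min_dist = 24, border = 30)
  tomo <- wbp_reconstruct(sc$ts, 64)
  tbl <- particle_table(2)
  tbl$tag <- 1:2
  tbl$x <- sc$gt$positions[, 1]; tbl$y <- sc$gt$positions[, 2]
  tbl$z <- sc$gt$positions[, 3]
  s1 <- extract_particles(tomo, tbl, 16, randomize_orientations = TRUE,
                          seed = 3)
  s2 <- extract_particles(tomo, tbl, 16, randomize_orientations = TRUE,
                          seed = 3)
  expect_equal(s1$table$tdrot, s2$table$tdrot)
  expect_false(all(s1$table$tilt == 0))
})

test_that("crop-mode and direct-reconstruction extraction agree", {
  sc <- fixture_scene(shape = c(96, 96, 64), n = 2, seed = 7,
                       min_dist = 24, border = 30)
  tomo <- wbp_reconstruct(sc$ts, 64)
  tbl <- particle_table(2)
  tbl$tag <- 1:2
  tbl$x <- sc$gt$positions[, 1]; tbl$y <- sc$gt$positions[, 2]
  tbl$z <- sc$gt$positions[, 3]
  crop <- extract_particles(tomo, tbl, 32)
  direct <- extract_particles(sc$ts, tbl, 32, thickness = 64)
  for (i in 1:2)
    expect_volumes_correlate(crop$boxes[[i]], direct$boxes[[i]], 0.99)
})

test_that("noise traps are shaped like the template but independent", {
  prep <- fixture_template(32)
  trap1 <- make_noise_trap(prep$template, prep$mask, seed = 1)
  trap2 <- make_noise_trap(prep$template, prep$mask, seed = 2)
  nm <- sum(prep$mask)
  mu <- sum(prep$mask * trap1) / nm
  s <- sqrt(sum(prep$mask * (trap1 - mu)^2) / nm)
  expect_lt(abs(mu), 1e-6 * s)
  # in-mask sd matches the template
  ts_ <- sqrt(sum(prep$mask * prep$template^2) / nm)
  expect_equal(s, ts_, tolerance = 1e-6)
  # spectral power above the cutoff < 1%
  sp <- Mod(fft(trap1))^2
  r <- tomosta:::radius_grid(rep(32, 3), relative = TRUE)
  expect_lt(sum(sp[r > 0.3 * 0.5 + 0.05]) / sum(sp), 0.01)
  # traps from different seeds are uncorrelated in the mask
  cc <- cor(as.vector(trap1 * prep$mask), as.vector(trap2 * prep$mask))
  expect_lt(abs(cc), 0.1)
})

test_that("alignment recovers exact pose, shift and separates noise", {
  prep <- fixture_blob_template(32)
  tpl <- prep$template; msk <- prep$mask
  grid <- generate_grid(15, 45, 15, 45, "C1")
  al <- align_particle(tpl, tpl, msk, grid, shift_limit = 4)
  expect_gte(al$cc, 0.999)
  expect_equal(as.numeric(al$euler), c(0, 0, 0))
  expect_lt(max(abs(al$shift)), 0.05)
  # rotated by a grid rotation, wedge-filtered and shifted
  angles <- seq(-45, 45, 3)
  Rg <- euler_to_matrix(as.numeric(grid[10, 1:3]))
  part <- tomosta:::cpp_rotate3(as.numeric(tpl), rep(32L, 3), Rg,
                                c(2.5, 0, 0))
  wm <- wedge_mask(angles, rep(32, 3))
  part <- Re(fft(fft(array(part, rep(32, 3))) * wm, inverse = TRUE)) / 32^3
  al2 <- align_particle(part, tpl, msk, grid, wedge = angles, shift_limit = 4)
  expect_equal(tomosta:::rotation_distance(euler_to_matrix(al2$euler), Rg), 0,
               tolerance = 1e-6)
  expect_lt(max(abs(al2$shift - c(2.5, 0, 0))), 0.25)
  # noise vs structure separability
  set.seed(9)
  noise_cc <- replicate(5, align_particle(array(rnorm(32^3), rep(32, 3)),
                                          tpl, msk, grid, shift_limit = 4)$cc)
  expect_gt(al2$cc, mean(noise_cc) + 3 * sd(noise_cc))
  expect_error(align_particle(tpl, tpl, array(0, rep(32, 3)), grid),
               "empty alignment mask")
})

test_that("MRA classifies identical particles trivially and reports", {
  prep <- fixture_blob_template(32)
  n <- 4
  tbl <- particle_table(n); tbl$tag <- 1:n
  stack <- structure(list(boxes = replicate(n, prep$template,
                                            simplify = FALSE),
                          table = tbl, wedge = NULL, box = 32),
                     class = "particle_stack")
  refs <- list(prep$template,
               make_noise_trap(prep$template, prep$mask, seed = 1))
  grid <- generate_grid(20, 30, 20, 30, "C1")
  out <- classify_mra(stack, refs, c(FALSE, TRUE), prep$mask,
                      n_iterations = 2, local_grid = grid, shift_limit = 2)
  expect_true(all(out$assignments == 1))
  expect_equal(nrow(out$report), 2)
  expect_equal(out$report$class1, c(4, 4))
})

test_that("wedge-compensated averaging recovers the full structure", {
  prep <- fixture_template(32)
  tpl <- prep$template
  # single particle, identity pose, full sampling: average == particle
  tbl <- particle_table(1); tbl$tag <- 1L
  stack <- structure(list(boxes = list(tpl), table = tbl, wedge = NULL,
                          box = 32), class = "particle_stack")
  avg <- average_particles(stack)
  expect_lt(sqrt(mean((avg - tpl)^2)), 1e-5 * sd(as.vector(tpl)))
  expect_error(average_particles(
    structure(list(boxes = list(), table = particle_table(0), wedge = NULL),
              class = "particle_stack")), "zero particles")

  # two copies with complementary wedges (rotated 90 deg about the tilt
  # axis) fill Fourier space and recover the ground truth
  angles <- seq(-45, 45, 3)
  wm <- wedge_mask(angles, rep(32, 3))
  R90 <- tomosta:::rot_y(90)
  p1 <- Re(fft(fft(tpl) * wm, inverse = TRUE)) / 32^3
  rot <- tomosta:::cpp_rotate3(as.numeric(tpl), rep(32L, 3), R90, c(0, 0, 0))
  p2 <- Re(fft(fft(array(rot, rep(32, 3))) * wm, inverse = TRUE)) / 32^3
  e2 <- matrix_to_euler(R90)
  tbl2 <- particle_table(2); tbl2$tag <- 1:2
  tbl2$tdrot <- c(0, e2[1]); tbl2$tilt <- c(0, e2[2]); tbl2$narot <- c(0, e2[3])
  stack2 <- structure(list(boxes = list(p1, p2), table = tbl2,
                           wedge = angles, box = 32),
                      class = "particle_stack")
  avg2 <- average_particles(stack2)
  # Fourier coverage of the union of the two rotated wedges
  wrot <- tomosta:::ifftshift3(array(
    tomosta:::cpp_rotate3(as.numeric(tomosta:::fftshift3(wm)), rep(32L, 3),
                          t(R90), c(0, 0, 0)), rep(32, 3)))
  expect_gt(mean(pmax(wm, wrot) >= 0.5), 0.95)
  expect_volumes_correlate(avg2 * prep$mask, tpl * prep$mask, 0.95)

  # C4 symmetrization does not hurt the torus average
  cc_plain <- cor(as.vector(avg2 * prep$mask), as.vector(tpl * prep$mask))
  avg4 <- average_particles(stack2, symmetry = "C4")
  cc_sym <- cor(as.vector(avg4 * prep$mask), as.vector(tpl * prep$mask))
  expect_gte(cc_sym, cc_plain - 0.01)
})

test_that("half-set splitting is disjoint, exhaustive and balanced", {
  tbl <- particle_table(4490); tbl$tag <- 1:4490
  h <- split_half_sets(tbl)
  expect_equal(nrow(h[[1]]), 2245)
  expect_equal(nrow(h[[2]]), 2245)
  expect_length(intersect(h[[1]]$tag, h[[2]]$tag), 0)
  expect_setequal(c(h[[1]]$tag, h[[2]]$tag), tbl$tag)
  expect_equal(unique(h[[1]]$half_set), 1L)
  t5 <- particle_table(5); t5$tag <- 1:5
  h5 <- split_half_sets(t5)
  expect_equal(sort(c(nrow(h5[[1]]), nrow(h5[[2]]))), c(2, 3))
  r1 <- split_half_sets(t5, "random", seed = 9)
  r2 <- split_half_sets(t5, "random", seed = 9)
  expect_identical(r1[[1]]$tag, r2[[1]]$tag)
  expect_error(split_half_sets(particle_table(1)), "at least 2")
})

test_that("FSC is 1 for identical volumes and small for independent noise", {
  set.seed(11)
  v <- array(rnorm(32^3), rep(32, 3))
  f <- compute_fsc(v, v)
  expect_true(all(abs(f$fsc - 1) < 1e-9))
  res <- resolution_at(f, 32, 2)
  expect_false(res$crossed)
  expect_equal(res$resolution_A, 4)   # Nyquist bound
  # two independent noise volumes stay inside the null envelope
  a <- array(rnorm(32^3), rep(32, 3))
  b <- array(rnorm(32^3), rep(32, 3))
  fn <- compute_fsc(a, b)
  ok <- abs(fn$fsc[fn$shell > 0]) < 3 / sqrt(fn$n_voxels[fn$shell > 0])
  expect_gte(mean(ok), 0.95)
  expect_error(compute_fsc(a, array(0, c(16, 16, 16))), "box mismatch")
})

test_that("resolution interpolation follows N*a/s", {
  # synthetic curve crossing 0.143 exactly at shell 16
  f <- data.frame(shell = 0:20, fsc = 1 - (0:20) * ((1 - 0.143) / 16),
                  n_voxels = 1)
  class(f) <- c("fsc_curve", "data.frame")
  res <- resolution_at(f, 64, 2.0)
  expect_equal(res$resolution_A, 64 * 2 / 16, tolerance = 1e-9)
})

test_that("half-set averages combine linearly to the full average", {
  # identity poses and a common wedge: the wedge denominators cancel
  prep <- fixture_template(32)
  set.seed(12)
  n <- 6
  boxes <- lapply(1:n, function(i) prep$template +
                    array(rnorm(32^3, 0, 0.5), rep(32, 3)))
  tbl <- particle_table(n); tbl$tag <- 1:n
  stack <- structure(list(boxes = boxes, table = tbl,
                          wedge = seq(-45, 45, 3), box = 32),
                     class = "particle_stack")
  h <- split_half_sets(tbl)
  sub <- function(tags) {
    s <- stack; s$boxes <- stack$boxes[tags]; s$table <- tbl[tags, ]; s
  }
  a1 <- average_particles(sub(h[[1]]$tag))
  a2 <- average_particles(sub(h[[2]]$tag))
  full <- average_particles(stack)
  expect_equal((a1 + a2) / 2, full, tolerance = 1e-6)
})

test_that("FSC curves are written as text plus JSON summary", {
  set.seed(13)
  v <- array(rnorm(16^3), rep(16, 3))
  f <- compute_fsc(v, v + array(rnorm(16^3, 0, 2), rep(16, 3)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fsc(f, 16, 2, path)
  txt <- read.table(path)
  expect_equal(nrow(txt), nrow(f))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_true(is.numeric(js$resolution_A))
})
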