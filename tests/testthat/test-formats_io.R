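# MRC, particle-table, STAR and JSON-config I/O.

test_that("MRC round trip is lossless and keeps the voxel size", {
  f <- withr::local_tempfile(fileext = ".mrc")
  v <- array(0, c(16, 16, 16))
  write_mrc(v, f, voxel_size = 1)
  rb <- read_mrc(f)
  expect_equal(as.numeric(rb$data), as.numeric(v))
  expect_equal(rb$header$shape, c(16L, 16L, 16L))

  # float32 payloads survive exactly when representable in single precision
  set.seed(1)
  v <- array(runif(12 * 10 * 8), c(12, 10, 8))
  v32 <- array(readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
                       n = length(v), size = 4L), dim(v))
  write_mrc(v, f, voxel_size = 1.378)
  rb <- read_mrc(f)
  expect_identical(as.numeric(rb$data), as.numeric(v32))
  expect_equal(rb$header$voxel_size, 1.378, tolerance = 1e-6)
})

test_that("MRC reader rejects broken files with a format error", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), f)
  expect_error(read_mrc(f), "header")
  # truncated data section
  write_mrc(array(1, c(8, 8, 8)), f)
  bin <- readBin(f, "raw", n = file.info(f)$size)
  writeBin(bin[1:1500], f)
  expect_error(read_mrc(f), "truncated")
  expect_error(write_mrc(array(NaN, c(4, 4, 4)), f), "non-finite")
})

test_that("particle-table round trip preserves fields and row order", {
  set.seed(2)
  n <- 10
  tbl <- particle_table(n)
  tbl$tag <- seq_len(n)
  tbl$cc <- round(runif(n, -1, 1), 6)
  tbl$x <- sample(0:199, n); tbl$y <- sample(0:199, n); tbl$z <- sample(0:99, n)
  tbl$dx <- runif(n, -0.5, 0.5); tbl$dy <- runif(n, -0.5, 0.5)
  tbl$dz <- runif(n, -0.5, 0.5)
  tbl$tdrot <- runif(n, 0, 360); tbl$tilt <- runif(n, 0, 180)
  tbl$narot <- runif(n, 0, 360)
  tbl$class_id <- sample(0:3, n, TRUE); tbl$tomogram_id <- sample(1:2, n, TRUE)
  tbl$half_set <- sample(0:2, n, TRUE)
  f <- withr::local_tempfile(fileext = ".tbl")
  write_table(tbl, f)
  rb <- read_table(f)
  expect_equal(nrow(rb), n)
  for (col in names(tbl))
    expect_equal(rb[[col]], tbl[[col]], tolerance = 1e-6, label = col)
  # cc values written exactly at 6 decimals survive textual round trip
  expect_identical(rb$cc, tbl$cc)
  # on-disk positions are 1-based
  raw1 <- as.numeric(strsplit(trimws(readLines(f)[1]), "\\s+")[[1]])
  expect_equal(raw1[3], tbl$x[1] + 1)
})

test_that("malformed table rows raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".tbl")
  good <- paste(rep("1", 14), collapse = " ")
  writeLines(c(good, "1 2 3", good), f)
  expect_error(read_table(f), "line 2")
  writeLines(c(good, paste(good, "99 98")), f)
  expect_warning(rb <- read_table(f), "extra trailing")
  expect_equal(nrow(rb), 2)
})

test_that("STAR export writes particles, tomograms and uneven dose", {
  tbl <- particle_table(3)
  tbl$tag <- 1:3
  tbl$x <- c(10, 20, 30); tbl$y <- c(11, 21, 31); tbl$z <- c(5, 6, 7)
  tbl$tomogram_id <- 1L
  td <- data.frame(tomogram_id = 1L, name = "tomo_001", nx = 200L, ny = 200L,
                   nz = 100L, pixel_size = 2.62)
  # hybrid scheme: high-dose zero tilt, 3 e/A^2 elsewhere
  sc <- tilt_scheme(-6, 6, 3, dose_per_tilt = 3, zero_tilt_dose = 15)
  dt <- data.frame(tomogram_id = 1L, tilt_angle = sc$angles,
                   acquisition_order = sc$acquisition_order, dose = sc$dose)
  f <- withr::local_tempfile(fileext = ".star")
  export_star(tbl, td, dt, f)
  txt <- readLines(f)
  expect_length(grep("^tomo_001 ", txt), 1 + nrow(dt) + nrow(tbl))
  # pre-exposure is cumulative in acquisition order and non-uniform
  tilts <- txt[grep("data_tilts", txt) + seq_len(nrow(dt)) + 5]
  pre <- as.numeric(vapply(strsplit(tilts, " "), `[`, "", 3))
  ord <- order(sc$acquisition_order)
  expect_equal(sort(pre)[1], 0)                       # first acquired image
  expect_equal(pre[which(sc$angles == 0)], 0)         # zero tilt acquired first
  expect_equal(max(pre), sum(sc$dose) - sc$dose[ord][length(ord)])
  expect_gt(diff(range(diff(sort(pre)))), 0)          # uneven increments
  # identity orientation exports as all-zero angles
  prow <- strsplit(txt[grep("^tomo_001 10 ", txt)], " ")[[1]]
  expect_equal(as.numeric(prow[5:7]), c(0, 0, 0))
  # coordinates round trip exactly
  back <- read_star_particles(f)
  expect_equal(back$rlnCoordinateX, tbl$x + tbl$dx)
  expect_equal(back$rlnCoordinateZ, tbl$z + tbl$dz)
  # missing description is a reference error
  tbl2 <- tbl; tbl2$tomogram_id <- 2L
  expect_error(export_star(tbl2, td, dt, f), "no tomogram description")
})

test_that("STAR Euler mapping preserves the rotation operator", {
  set.seed(3)
  for (i in 1:20) {
    eul <- c(runif(1, 0, 360), runif(1, 1, 179), runif(1, 0, 360))
    zyz <- tomosta:::zxz_to_zyz(eul)
    a <- zyz[1] * pi / 180; b <- zyz[2] * pi / 180; c <- zyz[3] * pi / 180
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    expect_equal(Rz(a) %*% Ry(b) %*% Rz(c), euler_to_matrix(eul),
                 tolerance = 1e-10)
  }
})

test_that("config merging follows defaults < general < user, fails fast", {
  defaults <- default_config()
  expect_equal(defaults$ExtractParticles$threshold_sigma, 5)
  cfg <- merge_config(defaults,
                      list(general = list(pixel_size = 2.62),
                           ExtractParticles = list(threshold_sigma = 7)))
  m <- cfg$modules[[1]]
  expect_equal(m$params$threshold_sigma, 7)
  expect_equal(m$params$pixel_size, 2.62)      # general flows into modules
  expect_equal(cfg$provenance$ExtractParticles[["threshold_sigma"]], "user")

  # omitted params -> defaults verbatim
  cfg2 <- merge_config(defaults, list(general = list(pixel_size = 1),
                                      Reconstruct = list()))
  expect_equal(cfg2$modules[[1]]$params$filter,
               defaults$Reconstruct$filter)

  expect_error(merge_config(defaults, list(general = list(pixel_size = 1),
                                           Reconstruct = list(bogus_key = 1))),
               "bogus_key")
  expect_error(merge_config(defaults, list(general = list(pixel_size = 1),
                                           NoSuchModule = list())),
               "unknown module")
  expect_error(merge_config(defaults, list(Reconstruct = list())),
               "general")
  expect_error(merge_config(defaults, list(general = list(pixel_size = -1))),
               "pixel_size")
  expect_error(merge_config(defaults,
                            list(general = list(pixel_size = 1),
                                 Reconstruct = list(filter = 42))),
               "type mismatch")
})

test_that("config merging is idempotent", {
  cfg <- merge_config(default_config(),
                      list(general = list(pixel_size = 2.0, seed = 9),
                           Simulate = list(n_particles = 5),
                           Reconstruct = list(thickness = 64)))
  again <- merge_config(default_config(), tomosta:::config_as_user(cfg))
  expect_equal(again$general, cfg$general)
  for (i in seq_along(cfg$modules))
    expect_equal(again$modules[[i]]$params, cfg$modules[[i]]$params)
})
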