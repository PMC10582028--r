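#' Tilt scheme description
#'
#' Describes a single-axis acquisition: angular range, increment, dose per
#' image and acquisition ordering.  The dose-symmetric ordering alternates
#' groups of `group_size` tilts between the positive and negative branches
#' starting on the positive side (`0, +3, -3, -6, +6, +9, ...` for a 3-degree
#' increment with groups of 2), so the least-exposed images are the low
#' tilts.  An optional `zero_tilt_dose` override emulates hybrid schemes
#' with a high-dose zero-tilt image.
#'
#' @param start,stop,increment tilt range in degrees (`start < stop`,
#'   `increment > 0`).
#' @param ordering `"dose-symmetric"` or `"sequential"`.
#' @param dose_per_tilt electrons/A^2 per image (scalar, or one per image in
#'   acquisition order).
#' @param zero_tilt_dose optional dose override for the 0-degree image.
#' @param group_size tilts per branch group in the dose-symmetric ordering.
#' @return list of class `tilt_scheme` with `angles` (sorted, the on-disk
#'   stack order), `acquisition_order` (rank of each image in time),
#'   `dose` and `pre_exposure` per image (stack order).
#' @examples
#' sc <- tilt_scheme(-45, 45, 3)
#' length(sc$angles) # 31
#' @export
tilt_scheme <- function(start = -45, stop = 45, increment = 3,
                        ordering = c("dose-symmetric", "sequential"),
                        dose_per_tilt = 3, zero_tilt_dose = NULL,
                        group_size = 2) {
  stopifnot(start < stop, increment > 0)
  ordering <- match.arg(ordering)
  n <- round((stop - start) / increment) + 1L
  angles <- start + increment * (seq_len(n) - 1L)
  acq_angles <- switch(ordering,
    "sequential" = angles,
    "dose-symmetric" = dose_symmetric_order(angles, group_size))
  acq_rank <- match(angles, acq_angles)   # per stack-ordered image
  dose <- rep_len(dose_per_tilt, n)       # in acquisition order
  if (!is.null(zero_tilt_dose)) {
    i0 <- which.min(abs(acq_angles))
    dose[i0] <- zero_tilt_dose
  }
  pre <- cumsum(c(0, dose))[seq_len(n)]   # before each acquisition
  structure(list(start = start, stop = stop, increment = increment,
                 ordering = ordering, group_size = group_size,
                 angles = angles, acquisition_order = acq_rank,
                 dose = dose[acq_rank], pre_exposure = pre[acq_rank],
                 accumulated_dose = (pre + dose)[acq_rank]),
            class = "tilt_scheme")
}

# Hagen-style ordering: zero first, then alternating branch groups starting
# positive.  The initial positive group includes the zero tilt.
dose_symmetric_order <- function(angles, group_size = 2) {
  i0 <- which.min(abs(angles))
  pos <- sort(angles[angles > angles[i0]])
  neg <- sort(angles[angles < angles[i0]], decreasing = TRUE)
  out <- angles[i0]
  take_pos <- group_size - 1L  # zero counts into the first positive group
  side <- "pos"
  while (length(pos) || length(neg)) {
    k <- if (side == "pos") take_pos else group_size
    take_pos <- group_size
    if (side == "pos") {
      k <- min(k, length(pos))
      if (k > 0) { out <- c(out, pos[seq_len(k)]); pos <- pos[-seq_len(k)] }
      side <- "neg"
      if (!length(neg)) side <- "pos"
    } else {
      k <- min(k, length(neg))
      if (k > 0) { out <- c(out, neg[seq_len(k)]); neg <- neg[-seq_len(k)] }
      side <- "pos"
      if (!length(pos)) side <- "neg"
    }
  }
  out
}

#' Density phantoms
#'
#' Builds a centered, non-negative density that vanishes at the box faces.
#' `"torus"` is a bagel-shaped density (Gaussian tube cross-section whose
#' half-maximum surface is the torus of ring radius `ring_radius` and tube
#' radius `tube_radius` about the z axis), a stand-in with apoferritin-like
#' dimensions; `"sphere"` a soft-edged ball; `"blob"` a seeded sum of
#' displaced Gaussians with no symmetry.
#'
#' @param kind `"torus"`, `"sphere"` or `"blob"`.
#' @param box cube side in voxels (>= 16).
#' @param ring_radius,tube_radius torus radii in voxels.
#' @param radius sphere radius in voxels.
#' @param n_blobs,blob_sigma,seed blob parameters.
#' @return cubic array `box^3`.
#' @export
make_phantom <- function(kind = c("torus", "sphere", "blob"), box = 48,
                         ring_radius = box / 5, tube_radius = box / 10,
                         radius = box / 4, n_blobs = 6,
                         blob_sigma = box / 12, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(box >= 16)
  ax <- seq_len(box) - 1 - box %/% 2
  if (kind == "torus") {
    if (ring_radius + tube_radius >= box / 2 - 1)
      stop("torus radii exceed box/2")
    sigma <- tube_radius / sqrt(2 * log(2))  # half-max at tube_radius
    rho <- sqrt(outer(ax^2, ax^2, `+`))      # in-plane radius
    d2 <- outer((rho - ring_radius)^2, ax^2, `+`)
    vol <- array(exp(-d2 / (2 * sigma^2)), c(box, box, box))
  } else if (kind == "sphere") {
    if (radius >= box / 2 - 1) stop("sphere radius exceeds box/2")
    r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
    vol <- array(soft_edge(r, radius - 2, 4), c(box, box, box))
  } else {
    withr_seed <- function(expr) { # local deterministic RNG
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed); expr
    }
    centers <- withr_seed(matrix(stats::runif(3 * n_blobs, -box / 5, box / 5),
                                 n_blobs, 3))
    g <- expand.grid(x = ax, y = ax, z = ax)
    v <- numeric(nrow(g))
    for (i in seq_len(n_blobs)) {
      d2 <- (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 +
        (g$z - centers[i, 3])^2
      v <- v + exp(-d2 / (2 * blob_sigma^2))
    }
    vol <- array(v, c(box, box, box))
  }
  vol[vol < 1e-4 * max(vol)] <- 0
  vol
}

#' Place particles (and optional gold beads) in a volume
#'
#' Uniform random positions with a minimum pairwise distance and a border
#' margin; orientations are uniform over rotation space (quaternion
#' sampling).  Fully deterministic given the seed.
#'
#' @param volume_shape integer length-3.
#' @param n number of particles.
#' @param min_dist minimum pairwise center distance, voxels.
#' @param border margin to every volume face, voxels.
#' @param seed RNG seed.
#' @param n_beads optional gold-bead count (same placement rules, half the
#'   particle min distance to particles).
#' @return list of class `ground_truth`: `positions` (n x 3, 0-based integer
#'   voxels), `orientations` (data.frame tdrot/tilt/narot), `bead_positions`,
#'   `seed`.
#' @export
place_particles <- function(volume_shape, n, min_dist, border, seed = 1,
                            n_beads = 0L) {
  volume_shape <- as.integer(volume_shape)
  lo <- border
  hi <- volume_shape - 1 - border
  if (any(hi <= lo)) stop("border leaves no placeable volume")
  placeable <- prod(hi - lo + 1)
  # coarse feasibility guard: exclusion spheres overlap, spill over the
  # border and are clipped by thin slabs, so only reject clearly absurd
  # requests; the bounded-attempts error below is the authoritative check
  excl <- prod(pmin(min_dist, hi - lo + 1))  # slab-clipped exclusion box
  if (n * excl / 2 > 2 * placeable)
    stop("infeasible packing: ", n, " particles at min_dist ", min_dist,
         " exceed the placeable volume")
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n)
      stop("placement failed after ", attempts,
           " attempts (min_dist = ", min_dist, ")")
    cand <- floor(stats::runif(3, lo, hi + 1))
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_dist)
      pts <- rbind(pts, cand)
  }
  rots <- random_rotations(n)
  ori <- do.call(rbind, lapply(rots, matrix_to_euler))
  beads <- matrix(NA_real_, 0, 3)
  while (nrow(beads) < n_beads) {
    attempts <- attempts + 1L
    if (attempts > 1000L * (n + n_beads)) stop("bead placement failed")
    cand <- floor(stats::runif(3, lo, hi + 1))
    ok_p <- min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_dist / 2
    ok_b <- nrow(beads) == 0 ||
      min(sqrt(rowSums(sweep(beads, 2, cand)^2))) >= min_dist / 2
    if (ok_p && ok_b) beads <- rbind(beads, cand)
  }
  structure(list(positions = unname(pts),
                 orientations = as.data.frame(ori),
                 bead_positions = unname(beads),
                 volume_shape = volume_shape, seed = seed),
            class = "ground_truth")
}

#' Render a specimen volume from ground truth
#'
#' Sums rotated phantom copies at the ground-truth positions (overlap adds)
#' and adds gold beads as solid spheres of the stated diameter at a density
#' multiple of the phantom maximum.
#'
#' @param ground_truth a [place_particles()] result.
#' @param phantom cubic density array.
#' @param volume_shape integer length-3.
#' @param bead_diameter bead diameter in voxels.
#' @param bead_density_mult bead density as a multiple of `max(phantom)`.
#' @return array of dimension `volume_shape`.
#' @export
render_specimen <- function(ground_truth, phantom, volume_shape,
                            bead_diameter = 10, bead_density_mult = 10) {
  volume_shape <- as.integer(volume_shape)
  vol <- array(0, volume_shape)
  b <- vol_dims(phantom)[1]
  cb <- b %/% 2
  gt <- ground_truth
  for (i in seq_len(nrow(gt$positions))) {
    R <- euler_to_matrix(as.numeric(gt$orientations[i, ]))
    rot <- cpp_rotate3(as.numeric(phantom), c(b, b, b), R, c(0, 0, 0))
    p <- gt$positions[i, ]
    xs <- (p[1] - cb):(p[1] - cb + b - 1) + 1
    ys <- (p[2] - cb):(p[2] - cb + b - 1) + 1
    zs <- (p[3] - cb):(p[3] - cb + b - 1) + 1
    okx <- xs >= 1 & xs <= volume_shape[1]
    oky <- ys >= 1 & ys <= volume_shape[2]
    okz <- zs >= 1 & zs <= volume_shape[3]
    vol[xs[okx], ys[oky], zs[okz]] <-
      vol[xs[okx], ys[oky], zs[okz]] + rot[okx, oky, okz]
  }
  if (nrow(gt$bead_positions) > 0) {
    dens <- bead_density_mult * max(phantom)
    r <- bead_diameter / 2
    rr <- ceiling(r)
    ax <- -rr:rr
    ball <- array(soft_edge(sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`)),
                            r - 0.5, 1), rep(2 * rr + 1, 3)) * dens
    for (i in seq_len(nrow(gt$bead_positions))) {
      p <- gt$bead_positions[i, ]
      xs <- (p[1] - rr):(p[1] + rr) + 1
      ys <- (p[2] - rr):(p[2] + rr) + 1
      zs <- (p[3] - rr):(p[3] + rr) + 1
      okx <- xs >= 1 & xs <= volume_shape[1]
      oky <- ys >= 1 & ys <= volume_shape[2]
      okz <- zs >= 1 & zs <= volume_shape[3]
      vol[xs[okx], ys[oky], zs[okz]] <-
        vol[xs[okx], ys[oky], zs[okz]] + ball[okx, oky, okz]
    }
  }
  vol
}

#' Simulate a tilt series
#'
#' Parallel-beam line integrals of the specimen along the beam for every
#' scheme angle (tilt about y), optional CTF modulation at the per-image
#' defocus, and additive Gaussian noise.  Images are stored sorted by tilt
#' angle; acquisition order, accumulated dose and defocus ride along as
#' metadata.
#'
#' @param specimen 3D array.
#' @param scheme a [tilt_scheme()].
#' @param ctf a [ctf_params()] or `NULL` for no CTF.
#' @param noise_sigma additive Gaussian noise sd (>= 0).
#' @param seed RNG seed.
#' @param defocus_jitter_um per-image defocus spread (uniform, micrometer).
#' @return list of class `tilt_series`: `images` (nx x ny x n), `angles`,
#'   `acquisition_order`, `dose`, `pre_exposure`, `defocus_um`,
#'   `pixel_size`, `scheme`.
#' @export
simulate_tilt_series <- function(specimen, scheme, ctf = NULL,
                                 noise_sigma = 0, seed = 1,
                                 defocus_jitter_um = 0) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  d <- vol_dims(specimen)
  set.seed(seed)
  proj <- cpp_project_tilts(as.numeric(specimen), d, scheme$angles)
  n <- length(scheme$angles)
  defocus <- rep(if (!is.null(ctf)) ctf$defocus_um else NA_real_, n)
  if (!is.null(ctf) && defocus_jitter_um > 0)
    defocus <- defocus + stats::runif(n, -defocus_jitter_um, defocus_jitter_um)
  images <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    img <- matrix(proj[, i], d[1], d[2])
    if (!is.null(ctf)) {
      fg <- freq_grid_2d(d[1], d[2], ctf$pixel_size)
      tf <- ctf_value(ctf, fg, defocus[i])
      img <- Re(stats::fft(stats::fft(img) * tf, inverse = TRUE)) / length(img)
    }
    images[, , i] <- img
  }
  if (noise_sigma > 0)
    images <- images + array(stats::rnorm(length(images), 0, noise_sigma),
                             dim(images))
  structure(list(images = images, angles = scheme$angles,
                 acquisition_order = scheme$acquisition_order,
                 dose = scheme$dose, pre_exposure = scheme$pre_exposure,
                 defocus_um = defocus,
                 pixel_size = if (!is.null(ctf)) ctf$pixel_size else 1,
                 scheme = scheme),
            class = "tilt_series")
}

#' Degrade images to a target signal-to-noise ratio
#'
#' Adds white Gaussian noise scaled so that
#' `var(signal) / var(added noise) = target_snr`.
#'
#' @param images numeric array (any shape).
#' @param target_snr target SNR (> 0); values above `1e6` return the input.
#' @param seed RNG seed.
#' @export
degrade_to_snr <- function(images, target_snr, seed = 1) {
  stopifnot(target_snr > 0)
  if (target_snr >= 1e6) return(images)
  sv <- stats::var(as.vector(images))
  if (sv == 0) stop("zero-variance input")
  set.seed(seed)
  images + array(stats::rnorm(length(images), 0, sqrt(sv / target_snr)),
                 dim(images))
}

#' Write a tilt series as an MRC stack plus JSON metadata sidecar
#'
#' @param ts a `tilt_series`.
#' @param path output MRC path; metadata goes to `<path>.json`.
#' @export
write_tilt_series <- function(ts, path) {
  write_mrc(ts$images, path, voxel_size = ts$pixel_size)
  meta <- list(angles = ts$angles, acquisition_order = ts$acquisition_order,
               dose = ts$dose, pre_exposure = ts$pre_exposure,
               defocus_um = ts$defocus_um, pixel_size = ts$pixel_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(path) {
  vol <- read_mrc(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(images = vol$data, angles = meta$angles,
                 acquisition_order = meta$acquisition_order,
                 dose = meta$dose, pre_exposure = meta$pre_exposure,
                 defocus_um = meta$defocus_um, pixel_size = meta$pixel_size,
                 scheme = NULL),
            class = "tilt_series")
}
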