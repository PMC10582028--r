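#' Weighted back-projection reconstruction
#'
#' Each image is 1D-filtered along x (perpendicular to the y tilt axis)
#' with a ramp `|k|` (optionally apodized by a Hamming window), then smeared
#' back along its tilt direction by voxel-driven gathering with bilinear
#' interpolation.  The ramp zeroes the DC component, so ramp-filtered
#' reconstructions have (near) zero mean.
#'
#' @param tilt_series a `tilt_series` (see [simulate_tilt_series()]).
#' @param thickness output z extent in voxels.
#' @param filter `"ramp"`, `"ramp-hamming"` or `"none"`.
#' @param binning Fourier-crop factor applied to the images before
#'   reconstruction (power of 2; thickness is in binned voxels).
#' @return a `tomogram`: list with `volume`, `voxel_size`, `binning`,
#'   `thickness`, `provenance`.
#' @export
wbp_reconstruct <- function(tilt_series, thickness,
                            filter = c("ramp", "ramp-hamming", "none"),
                            binning = 1) {
  filter <- match.arg(filter)
  ts <- tilt_series
  if (length(ts$angles) == 1L)
    warning("single-image stack: reconstruction is a degenerate smear")
  images <- ts$images
  if (binning > 1) images <- fourier_crop(images, binning, stack = TRUE)
  d <- dim(images)
  filt <- filter_stack(images, filter)
  flat <- matrix(filt, d[1] * d[2], d[3])
  vol <- cpp_backproject(flat, d[1:2], ts$angles, as.integer(thickness),
                         matrix(0, 2, d[3]), c(0, 0, 0), d[1:2])
  vol <- vol * pi / (2 * length(ts$angles))
  # the ramp filter zeroes the DC of every projection, so the volume DC is
  # undefined; any residual mean is discretization artifact and is removed
  if (filter != "none") vol <- vol - mean(vol)
  structure(list(volume = vol, voxel_size = ts$pixel_size * binning,
                 binning = binning, thickness = as.integer(thickness),
                 provenance = list(angles = ts$angles, filter = filter,
                                   ctf_corrected = isTRUE(ts$ctf_corrected))),
            class = "tomogram")
}

# Ramp-filter a stack along x (dimension 1).
filter_stack <- function(images, filter) {
  if (filter == "none") return(images)
  d <- dim(images)
  f <- abs(fft_freq(d[1]))
  if (filter == "ramp-hamming")
    f <- f * (0.54 + 0.46 * cos(2 * pi * f))  # Hamming taper to Nyquist
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    sp <- stats::mvfft(images[, , i]) * f
    out[, , i] <- Re(stats::mvfft(sp, inverse = TRUE)) / d[1]
  }
  out
}

#' Fourier-crop binning
#'
#' Downsamples by keeping the centered low-frequency block of the Fourier
#' transform.  The mean (DC) is preserved exactly; the voxel size scales by
#' the factor.
#'
#' @param x 3D array (volume), or image stack with `stack = TRUE` (cropping
#'   x and y only).
#' @param factor positive power of 2 dividing into the dimensions.
#' @param stack treat the third dimension as images, not a spatial axis.
#' @return binned array.
#' @export
fourier_crop <- function(x, factor, stack = FALSE) {
  if (factor == 1) return(x)
  if (factor < 1 || log2(factor) %% 1 != 0)
    stop("binning factor must be a positive power of 2")
  d <- dim(x)
  crop_dims <- if (stack) d[1:2] else d
  if (any(crop_dims < factor)) stop("factor larger than a dimension")
  if (stack) {
    out <- array(0, c(d[1:2] %/% factor, d[3]))
    for (i in seq_len(d[3])) out[, , i] <- fourier_crop_nd(x[, , i], factor)
    out
  } else {
    fourier_crop_nd(x, factor)
  }
}

fourier_crop_nd <- function(x, factor) {
  d <- dim(x)
  nd <- d %/% factor
  sp <- stats::fft(x)
  idx <- lapply(seq_along(d), function(i) {
    n <- d[i]; m <- nd[i]
    c(1:(m - m %/% 2), (n - m %/% 2 + 1):n)
  })
  cropped <- do.call(`[`, c(list(sp), idx, list(drop = FALSE)))
  Re(stats::fft(cropped, inverse = TRUE)) / prod(d)
}

#' Reconstruct a single particle directly from tilt projections
#'
#' For each tilt the particle's projected 2D location follows from the tilt
#' geometry; a substack window is cut, optionally phase-flipped at the
#' height-aware per-particle defocus, ramp-filtered and back-projected into
#' a `box^3` subtomogram centered on the particle.  This avoids
#' reconstructing (and storing) a full unbinned tomogram.  A particle whose
#' window falls off any image is skipped (`NULL` returned) with the reason
#' attached.
#'
#' @param tilt_series a `tilt_series`.
#' @param position 0-based voxel position `c(x, y, z)` in the tomogram frame
#'   (`thickness` gives the tomogram z extent the position refers to).
#' @param box output cube side, voxels (even).
#' @param thickness tomogram thickness the z coordinate refers to.
#' @param ctf optional [ctf_params()] enabling per-particle phase flipping.
#' @param handedness defocus handedness for the height correction.
#' @param filter reconstruction filter (see [wbp_reconstruct()]).
#' @return `box^3` array, or `NULL` (with a message naming the offending
#'   image) if the particle's window falls off any image.
#' @export
reconstruct_particle <- function(tilt_series, position, box, thickness,
                                 ctf = NULL, handedness = 1,
                                 filter = "ramp") {
  ts <- tilt_series
  d <- dim(ts$images)
  stopifnot(box %% 2 == 0)
  nimg <- d[3]
  # window large enough for tilted rays through the box
  win <- good_fft_size(ceiling(box * 1.6))
  cw <- win %/% 2
  cvol <- c(d[1] %/% 2, d[2] %/% 2, thickness %/% 2)
  offs <- matrix(0, 2, nimg)
  wins <- array(0, c(win, win, nimg))
  dpos <- position - cvol
  for (i in seq_len(nimg)) {
    th <- ts$angles[i] * pi / 180
    # image position of the particle center under tilt i
    px <- cos(th) * dpos[1] + sin(th) * dpos[3] + d[1] %/% 2
    py <- dpos[2] + d[2] %/% 2
    x0 <- round(px) - cw; y0 <- round(py) - cw
    if (x0 < 0 || y0 < 0 || x0 + win > d[1] || y0 + win > d[2]) {
      message(sprintf("particle skipped: window off image %d (center %.1f, %.1f)",
                      i, px, py))
      return(NULL)
    }
    w <- ts$images[x0 + seq_len(win), y0 + seq_len(win), i]
    if (!is.null(ctf)) {
      zoff <- sin(-th) * dpos[1] + cos(th) * dpos[3]
      dz <- particle_defocus(ts$defocus_um[i] %||% ctf$defocus_um, zoff,
                             ctf$pixel_size, handedness)
      p2 <- ctf; p2$defocus_um <- dz
      w <- phase_flip_const(w, p2, dz)
    }
    wins[, , i] <- w
    offs[, i] <- c(px - round(px), py - round(py))
  }
  filt <- filter_stack(wins, filter)
  flat <- matrix(filt, win * win, nimg)
  vol <- cpp_backproject(flat, c(win, win), ts$angles, as.integer(box),
                         offs, c(0, 0, 0), c(win, win))
  vol <- vol * pi / (2 * nimg)
  if (filter != "none") vol <- vol - mean(vol)
  ctr <- win %/% 2
  b2 <- box %/% 2
  sel <- (ctr - b2 + 1):(ctr - b2 + box)
  vol[sel, sel, ]
}

#' Edge-stopping (Perona-Malik) anisotropic diffusion denoising
#'
#' Scalar nonlinear anisotropic diffusion with conductivity
#' `g = 1 / (1 + (|grad| / kappa)^2)` and a conservative flux
#' discretization, so the total voxel sum is preserved (zero-flux
#' boundaries) and variance never increases.
#'
#' @param volume 3D array.
#' @param kappa gradient scale of the edge-stopping function (intensity
#'   units).
#' @param n_iterations iterations (>= 0).
#' @param dt time step; must be <= 0.15 for 3D stability.
#' @return denoised array.
#' @export
nad_denoise <- function(volume, kappa, n_iterations, dt = 0.1) {
  stopifnot(n_iterations >= 0)
  if (dt > 0.15) stop("unstable dt (", dt, "); 3D stability requires <= 0.15")
  v <- volume
  for (it in seq_len(n_iterations)) {
    upd <- array(0, dim(v))
    for (ax in 1:3) {
      dplus <- shift_axis(v, ax, -1L) - v      # forward difference
      g <- 1 / (1 + (dplus / kappa)^2)
      flux <- g * dplus                        # flux across i+1/2
      # zero-flux boundary: the last face has no forward neighbor, so its
      # flux is zeroed; the wrap in shift_axis then injects exactly 0 at the
      # first face, making the scheme conservative.
      flux <- zero_last_slice(flux, ax)
      upd <- upd + flux - shift_axis(flux, ax, 1L)
    }
    v <- v + dt * upd
  }
  v
}

# circular shift replaced by edge replication handled via zeroed fluxes
shift_axis <- function(x, ax, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  n <- d[ax]
  idx[[ax]] <- ((seq_len(n) - 1 - by) %% n) + 1
  do.call(`[`, c(list(x), idx))
}

zero_last_slice <- function(x, ax) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- d[ax]
  eval_call <- as.call(c(list(as.name("[<-"), x), idx, list(0)))
  eval(eval_call)
}
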