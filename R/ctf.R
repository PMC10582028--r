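#' Contrast transfer function parameters
#'
#' @param voltage_kv acceleration voltage in kV.
#' @param cs_mm spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in `[0, 1]`.
#' @param defocus_um defocus in micrometer, positive = underfocus.  Negative
#'   acquisition-style values (as defocus is often logged at the scope) are
#'   accepted and normalized to the positive-underfocus convention with a
#'   message.
#' @param pixel_size pixel size in Angstrom.
#' @param phase_shift additional phase shift in radians (phase plate), default 0.
#' @return list of class `ctf_params`.
#' @export
ctf_params <- function(voltage_kv = 300, cs_mm = 2.7,
                       amplitude_contrast = 0.07, defocus_um = 3,
                       pixel_size = 1, phase_shift = 0) {
  stopifnot(voltage_kv > 0, pixel_size > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  if (any(defocus_um < 0)) {
    message("negative defocus interpreted as underfocus (sign normalized)")
    defocus_um <- abs(defocus_um)
  }
  structure(list(voltage_kv = voltage_kv, cs_mm = cs_mm,
                 amplitude_contrast = amplitude_contrast,
                 defocus_um = defocus_um, pixel_size = pixel_size,
                 phase_shift = phase_shift),
            class = "ctf_params")
}

# Relativistic electron wavelength in Angstrom.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF at given spatial frequencies
#'
#' Returns `-sqrt(1 - A^2) * sin(chi) - A * cos(chi)` with the standard
#' aberration phase
#' `chi = pi * lambda * f^2 * dz - pi/2 * Cs * lambda^3 * f^4 + phase_shift`,
#' where positive defocus `dz` means underfocus.
#'
#' @param params a [ctf_params()] object.
#' @param freq spatial frequency in 1/Angstrom (vector or array, >= 0).
#' @param defocus_um optional defocus override (micrometer).
#' @return contrast factor, same shape as `freq`, bounded in `[-1, 1]`.
#' @export
ctf_value <- function(params, freq, defocus_um = params$defocus_um) {
  lambda <- electron_wavelength(params$voltage_kv)
  dz <- defocus_um * 1e4       # um -> A
  cs <- params$cs_mm * 1e7     # mm -> A
  chi <- pi * lambda * freq^2 * dz - pi / 2 * cs * lambda^3 * freq^4 +
    params$phase_shift
  a <- params$amplitude_contrast
  -sqrt(1 - a^2) * sin(chi) - a * cos(chi)
}

# First zero of the CTF in 1/A (smallest f > 0 with ctf_value = 0).
ctf_first_zero <- function(params, defocus_um = params$defocus_um) {
  f <- seq(1e-4, 1 / (2 * params$pixel_size), length.out = 4096)
  v <- ctf_value(params, f, defocus_um)
  s <- which(diff(sign(v)) != 0)
  if (!length(s)) return(Inf)
  i <- s[1]
  stats::uniroot(function(x) ctf_value(params, x, defocus_um),
                 c(f[i], f[i + 1]), tol = 1e-10)$root
}

# 2D frequency-magnitude grid (1/A) for an image, unshifted layout.
freq_grid_2d <- function(nx, ny, pixel_size) {
  fx <- fft_freq(nx) / pixel_size
  fy <- fft_freq(ny) / pixel_size
  sqrt(outer(fx^2, fy^2, `+`))
}

#' Phase-flip CTF correction of a 2D image
#'
#' Inverts the sign of Fourier components whose CTF sign differs from the
#' low-frequency (first-band) sign, unifying the contrast polarity across
#' the whole spectrum while leaving data below the first zero untouched.
#' The amplitude spectrum is unchanged, so total spectral power is
#' conserved exactly.  Note that the corrected image keeps the first-band
#' contrast polarity (density-negative in the underfocus convention);
#' multiply by -1 if density-positive contrast is wanted downstream.
#' In strip mode (for tilted images) the defocus varies
#' perpendicular to the tilt axis (y): strips of `strip_width` pixels with
#' 50% overlap are corrected at their local defocus
#' `defocus + handedness * offset_x * pixel_size * tan(tilt)` and blended
#' with cosine weights.
#'
#' @param image 2D numeric matrix.
#' @param params a [ctf_params()] object.
#' @param tilt_deg optional tilt angle (degrees); enables strip mode.
#' @param strip_width strip width in pixels for tilted correction.
#' @param handedness defocus handedness, `+1` or `-1`.
#' @return corrected image, same dimensions.
#' @export
phase_flip <- function(image, params, tilt_deg = NULL, strip_width = 256,
                       handedness = 1) {
  stopifnot(is.matrix(image))
  if (is.null(tilt_deg) || abs(tilt_deg) < 1e-9)
    return(phase_flip_const(image, params, params$defocus_um))
  nx <- nrow(image)
  cx <- nx %/% 2
  step <- max(1L, strip_width %/% 2L)
  starts <- unique(c(seq(1L, max(1L, nx - strip_width + 1L), by = step),
                     max(1L, nx - strip_width + 1L)))
  out <- matrix(0, nx, ncol(image))
  wsum <- matrix(0, nx, ncol(image))
  for (s in starts) {
    e <- min(nx, s + strip_width - 1L)
    mid <- (s + e) / 2 - 1  # 0-based strip center
    dz <- params$defocus_um +
      handedness * (mid - cx) * params$pixel_size * tan(tilt_deg * pi / 180) * 1e-4
    strip <- phase_flip_const(image[s:e, , drop = FALSE], params, dz)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq(s, e) - s + 0.5) / (e - s + 1))
    out[s:e, ] <- out[s:e, ] + strip * w
    wsum[s:e, ] <- wsum[s:e, ] + w
  }
  out / pmax(wsum, 1e-12)
}

phase_flip_const <- function(image, params, defocus_um) {
  fg <- freq_grid_2d(nrow(image), ncol(image), params$pixel_size)
  ctf <- ctf_value(params, fg, defocus_um)
  # flip relative to the first band: components whose CTF sign differs from
  # the low-frequency sign are inverted, so an image whose first zero lies
  # beyond Nyquist passes through untouched
  dc_sign <- sign(ctf_value(params, 0, defocus_um))
  if (dc_sign == 0) dc_sign <- -1
  flip <- ifelse(sign(ctf) == dc_sign | ctf == 0, 1, -1)
  Re(stats::fft(stats::fft(image) * flip, inverse = TRUE)) / length(image)
}

#' Per-particle defocus from particle height
#'
#' A particle sitting `z_offset` voxels above the tomogram center has its
#' own defocus `global + handedness * z_offset * pixel_size * 1e-4` (in
#' micrometer).  The handedness sign is dataset-dependent and therefore an
#' explicit parameter, never guessed.
#'
#' @param global_defocus_um tilt-level defocus, micrometer.
#' @param z_offset particle height relative to the tomogram center, voxels.
#' @param pixel_size Angstrom per voxel.
#' @param handedness `+1` or `-1`.
#' @return particle defocus in micrometer.
#' @examples
#' particle_defocus(3.0, 250, 2.0, +1) # 3.05
#' @export
particle_defocus <- function(global_defocus_um, z_offset, pixel_size,
                             handedness = 1) {
  stopifnot(handedness %in% c(-1, 1))
  global_defocus_um + handedness * z_offset * pixel_size * 1e-4
}

#' Grid-search defocus estimation from an image power spectrum
#'
#' Radially averages the image power spectrum, removes the smooth background
#' by a low-order polynomial fit to the log-spectrum and correlates the
#' residual with the model `CTF^2` over a defocus grid.  The returned fit
#' profile (experimental vs model) supports visual inspection; a fit score
#' below `reject_score` flags the estimate as unreliable (flat or
#' CTF-free spectra).
#'
#' @param image 2D numeric matrix.
#' @param params [ctf_params()] without a trusted defocus.
#' @param search_min,search_max,step defocus search grid in micrometer.
#' @param freq_range fraction band of Nyquist used for fitting.
#' @param reject_score minimum correlation for a reliable fit.
#' @return list with `defocus_um`, `score`, `reliable`, `profile`
#'   (data.frame: freq, power, model).
#' @export
estimate_defocus <- function(image, params, search_min = 1, search_max = 6,
                             step = 0.05, freq_range = c(0.08, 0.9),
                             reject_score = 0.3) {
  stopifnot(search_min > 0, search_max > search_min, step > 0)
  ps <- Mod(stats::fft(image))^2
  fg <- freq_grid_2d(nrow(image), ncol(image), params$pixel_size)
  nyq <- 1 / (2 * params$pixel_size)
  nbin <- 256L
  bin <- pmin(nbin, 1L + floor(fg / nyq * nbin))
  sel <- fg <= nyq & fg > 0
  rad <- tapply(ps[sel], bin[sel], mean)
  freq <- (as.integer(names(rad)) - 0.5) / nbin * nyq
  if (stats::sd(rad) == 0 || !all(is.finite(log(rad))))
    stop("estimation error: flat image spectrum")
  keep <- freq >= freq_range[1] * nyq & freq <= freq_range[2] * nyq
  lp <- log(rad[keep]); fq <- freq[keep]
  bg <- stats::fitted(stats::lm(lp ~ poly(fq, 4)))
  resid <- lp - bg
  grid <- seq(search_min, search_max, by = step)
  scores <- vapply(grid, function(dz) {
    model <- ctf_value(params, fq, dz)^2
    if (stats::sd(model) == 0 || stats::sd(resid) == 0) return(0)
    stats::cor(resid, model)
  }, numeric(1))
  best <- which.max(scores)
  model <- ctf_value(params, fq, grid[best])^2
  list(defocus_um = grid[best], score = scores[best],
       reliable = scores[best] >= reject_score,
       profile = data.frame(freq = fq, power = as.numeric(resid),
                            model = as.numeric(model - mean(model))))
}

#' Read or write a per-tilt defocus list
#'
#' Two-column plain text: tilt index (1-based) and defocus in micrometer.
#'
#' @param defocus_um numeric vector of per-tilt defoci.
#' @param path file path.
#' @export
write_defocus <- function(defocus_um, path) {
  writeLines(sprintf("%d %.6g", seq_along(defocus_um), defocus_um), path)
  invisible(path)
}

#' @rdname write_defocus
#' @export
read_defocus <- function(path) {
  m <- do.call(rbind, lapply(strsplit(trimws(readLines(path)),
                                      "[[:space:]]+"), as.numeric))
  m[order(m[, 1]), 2]
}
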