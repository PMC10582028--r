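#' Prepare a template (and mask) for matching
#'
#' Fourier-resamples a reference density to the tomogram voxel size,
#' low-pass filters it to a conservative resolution with a soft cosine edge,
#' and normalizes it to zero mean / unit variance inside a soft spherical
#' mask.  The output box is rounded to an even FFT-friendly size.
#'
#' @param volume cubic reference density.
#' @param source_voxel_size,target_voxel_size Angstrom per voxel (> 0).
#' @param lowpass low-pass resolution in Angstrom (`Inf` = none); must be
#'   coarser than twice the target voxel size (Nyquist).
#' @param mask_radius,mask_edge spherical mask geometry in voxels of the
#'   output box (defaults: `box/2 - 2` and 3).
#' @return list with `template`, `mask`, `voxel_size`, `box`.
#' @export
prepare_template <- function(volume, source_voxel_size, target_voxel_size,
                             lowpass = Inf, mask_radius = NULL,
                             mask_edge = 3) {
  stopifnot(source_voxel_size > 0, target_voxel_size > 0)
  if (is.finite(lowpass) && lowpass < 2 * target_voxel_size)
    stop("lowpass (", lowpass, " A) is beyond the Nyquist of the target ",
         "voxel size (", 2 * target_voxel_size, " A)")
  d <- vol_dims(volume)
  if (length(unique(d)) != 1L) stop("template must be cubic")
  b0 <- d[1]
  b1 <- round(b0 * source_voxel_size / target_voxel_size)
  b1 <- max(8L, if (b1 %% 2 == 1L) b1 + 1L else as.integer(b1))
  if (!is_smooth_size(b1)) b1 <- good_fft_size(b1)
  vol <- if (b1 == b0) volume else fourier_resample(volume, b1)
  vx <- source_voxel_size * b0 / b1
  if (is.finite(lowpass)) {
    r <- radius_grid(rep(b1, 3))                  # Fourier voxel radius
    cutoff <- b1 * vx / lowpass                   # shells
    filt <- soft_edge(r, cutoff, 2)
    vol <- Re(stats::fft(stats::fft(vol) * filt, inverse = TRUE)) / length(vol)
  }
  mask <- spherical_mask(b1, mask_radius %||% (b1 / 2 - 2), mask_edge)
  nm <- sum(mask)
  mu <- sum(mask * vol) / nm
  s <- sqrt(sum(mask * (vol - mu)^2) / nm)
  if (s == 0) stop("template has zero variance inside the mask")
  list(template = (vol - mu) / s, mask = mask, voxel_size = vx, box = b1)
}

# Fourier crop or pad a cubic volume to a new box size.
fourier_resample <- function(volume, new_box) {
  d <- vol_dims(volume)
  sp <- stats::fft(volume)
  b0 <- d[1]; b1 <- as.integer(new_box)
  keep <- min(b0, b1)
  idx0 <- c(1:(keep - keep %/% 2), (b0 - keep %/% 2 + 1):b0)
  idx1 <- c(1:(keep - keep %/% 2), (b1 - keep %/% 2 + 1):b1)
  out <- array(0 + 0i, rep(b1, 3))
  out[idx1, idx1, idx1] <- sp[idx0, idx0, idx0]
  Re(stats::fft(out, inverse = TRUE)) / prod(d)
}

#' Missing-wedge-aware template matching
#'
#' Exhaustive local-normalized cross-correlation of a template against a
#' tomogram over an orientation grid.  For each orientation the template is
#' rotated, filtered with the tomogram-frame wedge mask in Fourier space
#' (so the reference suffers the same missing wedge as the data) and
#' correlated by FFT with fast local normalization under the spherical
#' mask.  Large volumes are processed in chunks with an overlap of one
#' template box and seam-free stitching; chunk borders use periodic
#' continuation of the tomogram, so chunked and unchunked results agree
#' everywhere.
#'
#' @param tomogram a `tomogram` (see [wbp_reconstruct()]) or a 3D array.
#' @param template,mask normalized template and soft mask from
#'   [prepare_template()].
#' @param grid an [generate_grid()] orientation grid.
#' @param wedge tilt angles (degrees) defining the missing wedge, or a
#'   precomputed box-sized Fourier mask, or `NULL` to disable.
#' @param chunk chunk side in voxels (scalar or length 3; `NULL` = whole
#'   volume in one chunk).  Must be at least the template box.
#' @param eps_rel relative variance floor of the local normalization.
#' @return list of class `match_result`: `cc_map`, `orient_map` (1-based
#'   grid row index per voxel), `grid`, `chunk`.
#' @export
match_template <- function(tomogram, template, mask, grid, wedge = NULL,
                           chunk = NULL, eps_rel = 1e-6) {
  vol <- if (inherits(tomogram, "tomogram")) tomogram$volume else tomogram
  d <- vol_dims(vol)
  b <- vol_dims(template)[1]
  if (!is.null(chunk) && any(chunk < b))
    stop("chunk (", paste(chunk, collapse = "x"),
         ") smaller than the template box (", b, ")")
  wmask <- NULL
  if (!is.null(wedge)) {
    wmask <- if (is.array(wedge)) wedge else wedge_mask(wedge, rep(b, 3))
    stopifnot(all(dim(wmask) == b))
  } else {
    wmask <- array(1, rep(b, 3))
  }
  rots <- grid_matrices(grid)
  use_wedge <- !is.null(wedge)

  run_chunk <- function(cvol) {
    cpp_match_chunk(as.numeric(cvol), vol_dims(cvol), as.numeric(template),
                    as.numeric(mask), b, rots, as.numeric(wmask),
                    use_wedge, eps_rel)
  }

  if (is.null(chunk) || all(d <= rep_len(chunk, 3))) {
    dd <- d
    padded <- !all(vapply(d, is_smooth_size, logical(1)))
    if (padded) {
      dd <- vapply(d, good_fft_size, integer(1))
      big <- array(mean(vol), dd)
      big[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
      res <- run_chunk(big)
      cc <- res$cc[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
      ori <- res$ori[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
    } else {
      res <- run_chunk(vol)
      cc <- res$cc; ori <- res$ori
    }
    return(structure(list(cc_map = cc, orient_map = ori, grid = grid,
                          chunk = NULL), class = "match_result"))
  }

  chunk <- rep_len(as.integer(chunk), 3L)
  chunk <- pmin(chunk, vapply(d, good_fft_size, integer(1)))
  chunk <- vapply(chunk, good_fft_size, integer(1))
  # an axis fully covered by the chunk is processed whole (no halo), so its
  # circular topology matches the unchunked computation exactly
  whole <- chunk >= d
  chunk[whole] <- d[whole]
  halo <- ifelse(whole, 0L, b %/% 2)
  stride <- ifelse(whole, d, chunk - b)  # overlap = template box
  if (any(stride <= 0)) stop("chunk must exceed the template box by the stride")
  cc <- array(0, d); ori <- array(1L, d)
  starts <- lapply(1:3, function(i) {
    if (whole[i]) 0L else seq(0L, d[i] - 1L, by = stride[i])
  })
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    s <- c(sx, sy, sz)
    ix <- ((sx - halo[1]) + seq_len(chunk[1]) - 1L) %% d[1] + 1L
    iy <- ((sy - halo[2]) + seq_len(chunk[2]) - 1L) %% d[2] + 1L
    iz <- ((sz - halo[3]) + seq_len(chunk[3]) - 1L) %% d[3] + 1L
    res <- run_chunk(vol[ix, iy, iz])
    # interior of the chunk: voxels with full template support
    vx <- seq_len(min(stride[1], d[1] - sx)) + halo[1]
    vy <- seq_len(min(stride[2], d[2] - sy)) + halo[2]
    vz <- seq_len(min(stride[3], d[3] - sz)) + halo[3]
    gx <- sx + seq_along(vx); gy <- sy + seq_along(vy); gz <- sz + seq_along(vz)
    cc[gx, gy, gz] <- res$cc[vx, vy, vz]
    ori[gx, gy, gz] <- res$ori[vx, vy, vz]
  }
  structure(list(cc_map = cc, orient_map = ori, grid = grid, chunk = chunk),
            class = "match_result")
}

#' Remove large connected islands from a cross-correlation map
#'
#' Membranes, grid edges and reconstruction artifacts produce extended
#' high-CC regions.  Connected components of suprathreshold CC (threshold:
#' mean + 2 sd) larger than `island_max_size` voxels are zeroed, with an
#' optional dilation margin; point-like peaks are preserved.
#'
#' @param cc_map 3D array.
#' @param island_max_size maximum allowed component size in voxels
#'   (`Inf` = identity).
#' @param dilation margin in voxels around removed components.
#' @return cleaned cc_map.
#' @export
postprocess_cc <- function(cc_map, island_max_size, dilation = 0) {
  if (!is.finite(island_max_size)) return(cc_map)
  thr <- mean(cc_map) + 2 * stats::sd(cc_map)
  lab <- cpp_label(cc_map > thr, vol_dims(cc_map))
  if (max(lab) == 0L) return(cc_map)
  sizes <- tabulate(lab)
  big <- which(sizes > island_max_size)
  if (!length(big)) return(cc_map)
  kill <- array(lab %in% big, dim(lab))
  if (dilation > 0) for (i in seq_len(ceiling(dilation))) kill <- dilate6(kill)
  cc_map[kill] <- 0
  cc_map
}

dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) {
    out <- out | shift_axis(mask, ax, 1L) | shift_axis(mask, ax, -1L)
  }
  out
}

#' Extract particle peaks from a match result
#'
#' Greedy descending-CC selection with non-maximum suppression: map
#' statistics (mean, sd) are computed once, then peaks are taken from the
#' top down, each suppressing a sphere of `exclusion_radius`, until the CC
#' falls below `mean + threshold_sigma * sd` or `max_particles` is reached.
#' Equal CC values are resolved toward the lowest linear voxel index.
#'
#' @param match_result a [match_template()] result.
#' @param threshold_sigma stop threshold in map standard deviations (or
#'   `NULL` if only the cap is used).
#' @param max_particles particle cap (or `NULL`).
#' @param exclusion_radius suppression radius in voxels.
#' @param tomogram_id id written into the table rows.
#' @param valid_mask optional logical array restricting both the map
#'   statistics and the candidate voxels.
#' @return a `particle_table` (positions 0-based) sorted by descending CC.
#' @export
extract_peaks <- function(match_result, threshold_sigma = NULL,
                          max_particles = NULL, exclusion_radius,
                          tomogram_id = 1L, valid_mask = NULL) {
  if (is.null(threshold_sigma) && is.null(max_particles))
    stop("at least one of threshold_sigma / max_particles must be set")
  cc <- match_result$cc_map
  d <- vol_dims(cc)
  vals <- if (is.null(valid_mask)) cc else cc[valid_mask]
  mu <- mean(vals); sdev <- stats::sd(vals)
  thr <- if (is.null(threshold_sigma)) -Inf else mu + threshold_sigma * sdev
  cap <- max_particles %||% Inf
  work <- cc
  if (!is.null(valid_mask)) work[!valid_mask] <- -Inf
  rows <- list()
  r2 <- exclusion_radius^2
  while (length(rows) < cap) {
    i <- which.max(work)          # ties -> lowest linear index
    v <- work[i]
    if (!is.finite(v) || v < thr) break
    pos <- arrayInd(i, d) - 1L
    ori <- match_result$grid[match_result$orient_map[i], ]
    rows[[length(rows) + 1L]] <-
      data.frame(tag = length(rows) + 1L, cc = v,
                 x = pos[1], y = pos[2], z = pos[3], dx = 0, dy = 0, dz = 0,
                 tdrot = ori$tdrot, tilt = ori$tilt, narot = ori$narot,
                 class_id = 0L, tomogram_id = as.integer(tomogram_id),
                 half_set = 0L)
    # suppress a sphere around the peak
    xr <- clamp_range(pos[1], exclusion_radius, d[1])
    yr <- clamp_range(pos[2], exclusion_radius, d[2])
    zr <- clamp_range(pos[3], exclusion_radius, d[3])
    sub <- expand.grid(x = xr, y = yr, z = zr)
    inside <- (sub$x - pos[1])^2 + (sub$y - pos[2])^2 + (sub$z - pos[3])^2 <= r2
    work[cbind(sub$x, sub$y, sub$z)[inside, , drop = FALSE] + 1L] <- -Inf
  }
  out <- if (length(rows)) do.call(rbind, rows) else particle_table(0L)
  class(out) <- c("particle_table", "data.frame")
  out
}

clamp_range <- function(center, radius, n) {
  max(0L, floor(center - radius)):min(n - 1L, ceiling(center + radius))
}
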