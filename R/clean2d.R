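#' Erase gold beads from a micrograph
#'
#' Fiducial gold beads produce extreme round densities that trigger false
#' template-matching peaks.  Given bead positions (or auto-detected ones via
#' a matched disc filter), each bead disc plus a 2-pixel margin is replaced
#' by the local background mean plus noise matched to the local variance.
#'
#' @param image 2D matrix.
#' @param bead_diameter_px bead diameter in pixels (> 2).
#' @param positions optional n x 2 matrix of 0-based bead centers; when
#'   missing, beads are auto-detected as matched-filter peaks exceeding
#'   `detect_sigma` standard deviations (either polarity).
#' @param detect_sigma matched-filter detection threshold.
#' @param seed RNG seed for the fill-in noise.
#' @return list with `image` (cleaned) and `positions` (used bead centers).
#' @export
erase_gold <- function(image, bead_diameter_px, positions = NULL,
                       detect_sigma = 7, seed = 1) {
  stopifnot(is.matrix(image), bead_diameter_px > 2)
  r <- bead_diameter_px / 2
  if (is.null(positions)) {
    cc <- disc_match_map(image, r)
    positions <- local_peaks_2d(abs(cc), mean(abs(cc)) + detect_sigma * stats::sd(abs(cc)),
                                min_dist = bead_diameter_px)
  }
  if (is.null(positions) || nrow(positions) == 0L)
    return(list(image = image, positions = matrix(0, 0, 2)))
  set.seed(seed)
  out <- image
  d <- dim(image)
  rr <- r + 2  # margin
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    xr <- clamp_range(p[1], rr + 2 * r + 2, d[1])
    yr <- clamp_range(p[2], rr + 2 * r + 2, d[2])
    g <- expand.grid(x = xr, y = yr)
    dist <- sqrt((g$x - p[1])^2 + (g$y - p[2])^2)
    inside <- dist <= rr
    ring <- dist > rr & dist <= rr + 2 * r
    idx_in <- cbind(g$x, g$y)[inside, , drop = FALSE] + 1L
    idx_ring <- cbind(g$x, g$y)[ring, , drop = FALSE] + 1L
    bg <- out[idx_ring]
    out[idx_in] <- mean(bg) + stats::rnorm(nrow(idx_in), 0, stats::sd(bg))
  }
  list(image = out, positions = positions)
}

# Normalized correlation of the image with a soft disc of radius r.
disc_match_map <- function(image, r) {
  d <- dim(image)
  rr <- ceiling(r) + 1L
  ax <- -rr:rr
  disc <- soft_edge(sqrt(outer(ax^2, ax^2, `+`)), r - 0.5, 1)
  disc <- disc - mean(disc)
  disc <- disc / sqrt(sum(disc^2))
  ker <- matrix(0, d[1], d[2])
  ker[((ax + d[1]) %% d[1]) + 1L, ((ax + d[2]) %% d[2]) + 1L] <- disc
  img <- image - mean(image)
  img <- img / stats::sd(img)
  Re(stats::fft(Conj(stats::fft(ker)) * stats::fft(img), inverse = TRUE)) /
    length(img)
}

# Greedy peak picking on a 2D map (0-based coordinates).
local_peaks_2d <- function(map, threshold, min_dist, max_peaks = 200L) {
  d <- dim(map)
  work <- map
  out <- matrix(0, 0, 2)
  while (nrow(out) < max_peaks) {
    i <- which.max(work)
    if (work[i] < threshold) break
    p <- arrayInd(i, d) - 1L
    out <- rbind(out, p)
    xr <- clamp_range(p[1], min_dist, d[1])
    yr <- clamp_range(p[2], min_dist, d[2])
    g <- expand.grid(x = xr, y = yr)
    sel <- (g$x - p[1])^2 + (g$y - p[2])^2 <= min_dist^2
    work[cbind(g$x, g$y)[sel, , drop = FALSE] + 1L] <- -Inf
  }
  out
}

#' Erase a grid edge from a micrograph
#'
#' The largest connected low-intensity region that touches the image border
#' (a grid bar or hole edge) is replaced by background mean plus matched
#' noise.  Interior dark contamination is deliberately left untouched.
#'
#' @param image 2D matrix (positive-mean convention).
#' @param intensity_drop_threshold region counts as "low" below
#'   `threshold * mean(image)`.
#' @param min_fraction minimum region size as a fraction of the image.
#' @param seed RNG seed for the fill-in noise.
#' @return list with `image` and logical `mask` of replaced pixels.
#' @export
erase_grid_edge <- function(image, intensity_drop_threshold = 0.5,
                            min_fraction = 0.02, seed = 1) {
  stopifnot(is.matrix(image))
  d <- dim(image)
  low <- image < intensity_drop_threshold * mean(image)
  lab <- cpp_label(low, as.integer(d))
  mask <- matrix(FALSE, d[1], d[2])
  if (max(lab) > 0L) {
    border_labels <- setdiff(unique(c(lab[1, ], lab[d[1], ],
                                      lab[, 1], lab[, d[2]])), 0L)
    if (length(border_labels)) {
      sizes <- tabulate(lab)
      cand <- border_labels[which.max(sizes[border_labels])]
      if (sizes[cand] >= min_fraction * length(image))
        mask <- array(lab == cand, d)
    }
  }
  if (!any(mask)) return(list(image = image, mask = mask))
  set.seed(seed)
  bg <- image[!mask]
  out <- image
  out[mask] <- mean(bg) + stats::rnorm(sum(mask), 0, stats::sd(bg))
  list(image = out, mask = mask)
}

#' Cosine-taper the edges of an image or volume toward its mean
#'
#' @param data 2D or 3D numeric array.
#' @param width_px taper band width in pixels (< half the smallest
#'   dimension); 0 returns the input.
#' @return tapered array; the interior (outside the band) is bit-identical.
#' @export
taper_edges <- function(data, width_px) {
  if (width_px == 0) return(data)
  d <- dim(data)
  stopifnot(width_px < min(d) / 2)
  mu <- mean(data)
  w <- lapply(d, function(n) {
    i <- seq_len(n) - 1
    dist <- pmin(i, n - 1 - i)
    # 0 at the corner faces, 1 inside the band
    ifelse(dist >= width_px, 1, 0.5 - 0.5 * cos(pi * dist / width_px))
  })
  wt <- if (length(d) == 2L) outer(w[[1]], w[[2]], pmin)
        else outer(outer(w[[1]], w[[2]], pmin), w[[3]], pmin)
  out <- data
  band <- wt < 1           # keep the interior bit-identical
  out[band] <- (data[band] - mu) * wt[band] + mu
  out
}
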