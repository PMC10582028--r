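# Internal numeric helpers shared across modules.

# Signed Fourier index frequencies in cycles/box (DC first, unshifted).
fft_index <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n)
}

# Frequencies in cycles per voxel, unshifted layout.
fft_freq <- function(n) fft_index(n) / n

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n %/% 2 + 1L):n, 1L:(n %/% 2)))
  do.call(`[`, c(list(x), idx))
}

ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    h <- n - n %/% 2
    c((h + 1L):n, 1L:h)
  })
  do.call(`[`, c(list(x), idx))
}

# Is n a product of primes <= 13 (limit of the compiled FFT engine)?
is_smooth_size <- function(n) {
  for (p in c(2L, 3L, 5L, 7L, 11L, 13L)) while (n %% p == 0L) n <- n %/% p
  n == 1L
}

# Smallest even 13-smooth integer >= n.
good_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  if (n %% 2L == 1L) n <- n + 1L
  while (!is_smooth_size(n)) n <- n + 2L
  n
}

# Radial distance (in Fourier voxels) from DC, unshifted layout.
radius_grid <- function(dims, relative = FALSE) {
  kx <- if (relative) fft_freq(dims[1]) else fft_index(dims[1])
  ky <- if (relative) fft_freq(dims[2]) else fft_index(dims[2])
  kz <- if (relative) fft_freq(dims[3]) else fft_index(dims[3])
  r2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  sqrt(r2)
}

# Raised-cosine step: 1 for d <= r0, 0 for d >= r0 + width, cosine in between.
soft_edge <- function(d, r0, width) {
  if (width <= 0) return(as.numeric(d <= r0))
  w <- 0.5 * (1 + cos(pi * (d - r0) / width))
  w[d <= r0] <- 1
  w[d >= r0 + width] <- 0
  w
}

# Soft spherical mask centered at floor(dim/2), radius r, cosine edge.
spherical_mask <- function(box, radius = box / 2 - 2, edge = 3) {
  ax <- seq_len(box) - 1 - box %/% 2
  d <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  array(soft_edge(d, radius - edge, edge), dim = c(box, box, box))
}

as_volume <- function(x) {
  if (is.null(dim(x))) stop("expected an array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

vol_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("expected a 3D array")
  as.integer(d)
}

# Pearson correlation of two arrays, NA-safe guard for zero variance.
vol_cor <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
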