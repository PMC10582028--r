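#' Extract subtomogram particles
#'
#' Crops cubic boxes from a tomogram (crop mode) or reconstructs each
#' particle directly from the tilt series (direct mode, see
#' [reconstruct_particle()]).  With `recenter = TRUE` accumulated sub-voxel
#' shifts are folded into the integer positions (`new = old + round(shift)`,
#' residual kept), as done at every extraction step of an iterative
#' alignment.  Orientation randomization replaces the Euler triplets with
#' uniform rotations — used to break the missing-wedge alignment bias after
#' a restricted-range angular search.
#'
#' @param source a `tomogram`, a plain 3D array, or a `tilt_series` (direct
#'   mode; requires `thickness`).
#' @param table a `particle_table` (positions 0-based, in source voxels).
#' @param box cube side, voxels (even).
#' @param recenter fold sub-voxel shifts into positions first.
#' @param randomize_orientations replace orientations with uniform rotations.
#' @param thickness tomogram thickness for direct mode.
#' @param ctf,handedness CTF handling for direct mode.
#' @param wedge tilt-angle list used to attach a per-particle wedge.
#' @param seed RNG seed (orientation randomization).
#' @return list of class `particle_stack`: `boxes` (list of arrays),
#'   `table` (updated), `wedge` (tilt angles), `box`.
#' @export
extract_particles <- function(source, table, box, recenter = TRUE,
                              randomize_orientations = FALSE,
                              thickness = NULL, ctf = NULL, handedness = 1,
                              wedge = NULL, seed = 1) {
  if (nrow(table) == 0L) stop("empty particle table")
  stopifnot(box %% 2 == 0)
  tbl <- as_particle_table(table)
  if (recenter) {
    for (ax in c("x", "y", "z")) {
      sh <- tbl[[paste0("d", ax)]]
      tbl[[ax]] <- tbl[[ax]] + round(sh)
      tbl[[paste0("d", ax)]] <- sh - round(sh)
    }
  }
  if (randomize_orientations) {
    set.seed(seed)
    eul <- do.call(rbind, lapply(random_rotations(nrow(tbl)), matrix_to_euler))
    tbl$tdrot <- eul[, 1]; tbl$tilt <- eul[, 2]; tbl$narot <- eul[, 3]
  }
  direct <- inherits(source, "tilt_series")
  vol <- if (inherits(source, "tomogram")) source$volume
         else if (!direct) source else NULL
  b2 <- box %/% 2
  boxes <- list(); keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    p <- round(c(tbl$x[i], tbl$y[i], tbl$z[i]))
    if (direct) {
      sub <- reconstruct_particle(source, p, box,
                                  thickness %||% stop("direct mode needs thickness"),
                                  ctf = ctf, handedness = handedness)
      if (is.null(sub)) next  # reason already messaged
    } else {
      d <- vol_dims(vol)
      lo <- p - b2; hi <- p + b2 - 1L
      if (any(lo < 0) || any(hi >= d)) {
        message("particle ", tbl$tag[i], " skipped: box out of bounds")
        next
      }
      sub <- vol[lo[1]:hi[1] + 1L, lo[2]:hi[2] + 1L, lo[3]:hi[3] + 1L]
    }
    keep[i] <- TRUE
    boxes[[length(boxes) + 1L]] <- sub
  }
  tbl <- tbl[keep, ]
  row.names(tbl) <- NULL
  structure(list(boxes = boxes, table = tbl, wedge = wedge, box = box),
            class = "particle_stack")
}

#' Build a noise-trap reference
#'
#' Pure Gaussian noise shaped like the template: low-pass filtered at the
#' same cutoff, zero mean and matched standard deviation inside the mask.
#' Used as decoy classes in multi-reference alignment so false-positive
#' picks converge into it instead of contaminating the structural class.
#'
#' @param template reference volume defining box and amplitude.
#' @param mask soft alignment mask.
#' @param lowpass_frac low-pass cutoff as a fraction of Nyquist (matches the
#'   template preparation low-pass).
#' @param seed RNG seed.
#' @return noise volume, same box as the template.
#' @export
make_noise_trap <- function(template, mask, lowpass_frac = 0.3, seed = 1) {
  d <- vol_dims(template)
  set.seed(seed)
  noise <- array(stats::rnorm(prod(d)), d)
  r <- radius_grid(d, relative = TRUE)      # cycles/voxel, nyquist 0.5
  filt <- soft_edge(r, lowpass_frac * 0.5, 0.05)
  noise <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / prod(d)
  nm <- sum(mask)
  mu <- sum(mask * noise) / nm
  s <- sqrt(sum(mask * (noise - mu)^2) / nm)
  tmu <- sum(mask * template) / nm
  ts <- sqrt(sum(mask * (template - tmu)^2) / nm)
  (noise - mu) / s * ts
}

#' Constrained alignment of one particle against a reference
#'
#' For every candidate orientation of a local grid (composed onto the
#' particle's current orientation) the reference is rotated, filtered with
#' the particle's missing wedge, masked, and correlated with the particle
#' over translations by FFT.  The best orientation, the sub-voxel shift
#' (parabolic interpolation of the correlation peak, clamped to
#' `shift_limit`) and the correlation value are returned.
#'
#' @param particle cubic array.
#' @param reference cubic array, same box.
#' @param mask soft alignment mask.
#' @param local_grid an [generate_grid()] around identity; composed onto
#'   `current` per candidate.
#' @param current current orientation triplet of the particle.
#' @param wedge tilt angles defining the particle's wedge (or `NULL`).
#' @param shift_limit maximum shift in voxels (<= box/4).
#' @return list with `euler`, `shift`, `cc`.
#' @export
align_particle <- function(particle, reference, mask, local_grid,
                           current = c(0, 0, 0), wedge = NULL,
                           shift_limit = 4) {
  d <- vol_dims(particle)
  b <- d[1]
  stopifnot(shift_limit <= b / 4)
  if (sum(mask) == 0) stop("empty alignment mask")
  wmask <- if (is.null(wedge)) array(1, d) else wedge_mask(wedge, d)
  Rcur <- euler_to_matrix(current)
  rots <- vapply(seq_len(nrow(local_grid)), function(i) {
    Rcur %*% euler_to_matrix(as.numeric(local_grid[i, c("tdrot", "tilt", "narot")]))
  }, numeric(9))
  res <- cpp_align(as.numeric(particle), as.numeric(mask), b,
                   as.numeric(reference), rots, as.numeric(wmask),
                   !is.null(wedge), as.integer(floor(shift_limit)))
  R <- matrix(rots[, res$ori], 3, 3)
  sub <- shift_refine(res$window, floor(shift_limit))
  list(euler = matrix_to_euler(R),
       shift = pmax(-shift_limit, pmin(shift_limit, sub$shift)),
       cc = res$cc)
}

# Parabolic sub-voxel refinement of the correlation window around zero.
shift_refine <- function(sub, limit) {
  win <- -limit:limit
  i <- which.max(sub)
  p <- arrayInd(i, dim(sub))
  shift <- win[c(p[1], p[2], p[3])]
  shift <- vapply(1:3, function(ax) {
    lo <- p; lo[ax] <- p[ax] - 1
    hi <- p; hi[ax] <- p[ax] + 1
    if (lo[ax] < 1 || hi[ax] > dim(sub)[ax]) return(shift[ax])
    y0 <- sub[matrix(lo, 1)]; y1 <- sub[matrix(p, 1)]; y2 <- sub[matrix(hi, 1)]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
    shift[ax] + max(-0.5, min(0.5, off))
  }, numeric(1))
  list(cc = sub[i], shift = pmax(-limit, pmin(limit, shift)))
}

#' Multi-reference alignment and classification with noise traps
#'
#' Each iteration aligns every particle against every reference, assigns it
#' to the best-correlating class, and recomputes the non-noise class
#' averages by wedge-compensated averaging.  Noise-trap references are kept
#' fixed (default) so they act as stable sinks for false positives.  An
#' emptying class keeps its previous reference with a warning.
#'
#' @param stack a `particle_stack`.
#' @param references list of reference volumes.
#' @param is_noise_trap logical vector parallel to `references`.
#' @param mask soft alignment mask.
#' @param n_iterations iterations (>= 1).
#' @param local_grid orientation grid for the constrained search.
#' @param shift_limit translation limit, voxels.
#' @param regenerate_traps regenerate trap noise each iteration.
#' @param ref_lowpass_frac low-pass cutoff (fraction of Nyquist) applied to
#'   recomputed class averages between iterations; limiting references to
#'   the alignment resolution is the standard guard against noise
#'   overfitting (a class average that kept its members' noise would
#'   attract those members back by self-correlation).
#' @return list with `assignments` (final class per particle), `table`
#'   (refined), `references` (final class averages), `report`
#'   (per-iteration class counts), `cc` (final per-particle cc).
#' @export
classify_mra <- function(stack, references, is_noise_trap, mask,
                         n_iterations = 3, local_grid = NULL,
                         shift_limit = 4, regenerate_traps = FALSE,
                         ref_lowpass_frac = 0.3) {
  stopifnot(n_iterations >= 1,
            length(references) == length(is_noise_trap),
            any(!is_noise_trap))
  n <- length(stack$boxes)
  tbl <- stack$table
  local_grid <- local_grid %||% generate_grid(15, 45, 15, 45, "C1")
  refs <- references
  assign_vec <- rep(1L, n)
  ccs <- numeric(n)
  report <- data.frame()
  for (it in seq_len(n_iterations)) {
    new_euler <- matrix(0, n, 3)
    new_shift <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      best <- list(cc = -Inf, class = 1L)
      cur <- as.numeric(tbl[i, c("tdrot", "tilt", "narot")])
      for (k in seq_along(refs)) {
        al <- align_particle(stack$boxes[[i]], refs[[k]], mask, local_grid,
                             current = cur, wedge = stack$wedge,
                             shift_limit = shift_limit)
        if (al$cc > best$cc) best <- list(cc = al$cc, class = k, al = al)
      }
      assign_vec[i] <- best$class
      ccs[i] <- best$cc
      new_euler[i, ] <- best$al$euler
      new_shift[i, ] <- best$al$shift
    }
    tbl$tdrot <- new_euler[, 1]; tbl$tilt <- new_euler[, 2]
    tbl$narot <- new_euler[, 3]
    tbl$dx <- new_shift[, 1]; tbl$dy <- new_shift[, 2]
    tbl$dz <- new_shift[, 3]
    tbl$class_id <- assign_vec
    tbl$cc <- ccs
    counts <- tabulate(assign_vec, length(refs))
    report <- rbind(report, data.frame(iteration = it,
                                       t(stats::setNames(counts,
                                         paste0("class", seq_along(refs))))))
    for (k in seq_along(refs)) {
      if (is_noise_trap[k]) {
        if (regenerate_traps)
          refs[[k]] <- make_noise_trap(refs[[which(!is_noise_trap)[1]]], mask,
                                       seed = it * 100 + k)
        next
      }
      members <- which(assign_vec == k)
      if (!length(members)) {
        warning("class ", k, " emptied at iteration ", it,
                "; keeping previous reference")
        next
      }
      sub <- stack
      sub$boxes <- stack$boxes[members]
      sub$table <- tbl[members, ]
      avg <- average_particles(sub, sub$table)
      refs[[k]] <- lowpass_volume(avg, ref_lowpass_frac)
    }
  }
  list(assignments = assign_vec, table = tbl, references = refs,
       report = report, cc = ccs)
}

#' Wedge-compensated averaging of aligned particles
#'
#' Rotates every particle (and its wedge mask) back to the reference frame
#' and averages in Fourier space as
#' `sum_i F(aligned_i) / max(sum_i wedge_i, eps)`, with the denominator
#' floored at 1% of its maximum to prevent missing-wedge noise
#' amplification.  Optional symmetrization is applied last.
#'
#' @param stack a `particle_stack`.
#' @param table pose table (defaults to `stack$table`).
#' @param symmetry optional group label.
#' @return average volume.
#' @export
average_particles <- function(stack, table = stack$table, symmetry = NULL) {
  n <- length(stack$boxes)
  if (n == 0L) stop("zero particles")
  d <- vol_dims(stack$boxes[[1]])
  num <- array(0 + 0i, d)
  den <- array(0, d)
  wmask <- if (is.null(stack$wedge)) array(1, d)
           else wedge_mask(stack$wedge, d)
  wcent <- fftshift3(wmask)   # wedge as a DC-centered volume for rotation
  for (i in seq_len(n)) {
    R <- euler_to_matrix(as.numeric(table[i, c("tdrot", "tilt", "narot")]))
    sh <- c(table$dx[i], table$dy[i], table$dz[i])
    # particle = shift_sh(rotate_R(ref)); invert both: sample at
    # R (v - c) + c + sh, i.e. rotate by R^T with pre-rotation shift -R^T sh
    aligned <- cpp_rotate3(as.numeric(stack$boxes[[i]]), d, t(R),
                           -as.numeric(t(R) %*% sh))
    num <- num + stats::fft(array(aligned, d))
    wrot <- cpp_rotate3(as.numeric(wcent), d, t(R), c(0, 0, 0))
    den <- den + ifftshift3(array(wrot, d))
  }
  den <- pmax(den, 0.01 * max(den))
  avg <- Re(stats::fft(num / den, inverse = TRUE)) / prod(d)
  if (!is.null(symmetry)) avg <- symmetrize(avg, symmetry)
  avg
}

#' Split a particle table into half-sets
#'
#' @param table a `particle_table`.
#' @param mode `"even-odd"` (by row parity, the default) or `"random"`.
#' @param seed RNG seed for the random mode.
#' @return list of two `particle_table`s (`half_set` written as 1/2);
#'   disjoint, exhaustive, sizes differing by at most 1.
#' @export
split_half_sets <- function(table, mode = c("even-odd", "random"), seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 particles to split")
  sel <- switch(mode,
    "even-odd" = seq_len(n) %% 2L == 1L,
    "random" = { set.seed(seed); sample(rep(c(TRUE, FALSE), length.out = n)) })
  a <- table[sel, ]; b <- table[!sel, ]
  a$half_set <- 1L; b$half_set <- 2L
  row.names(a) <- NULL; row.names(b) <- NULL
  class(a) <- class(b) <- c("particle_table", "data.frame")
  list(a, b)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell (1 Fourier voxel wide) normalized cross-correlation of the
#' Fourier coefficients; optionally under a soft real-space mask.
#'
#' @param volume_a,volume_b cubic volumes of identical dimension.
#' @param mask optional soft mask applied to both.
#' @return data.frame of class `fsc_curve`: `shell`, `freq` (1/A given the
#'   `voxel_size` attribute set by the caller via [resolution_at()]),
#'   `fsc`, `n_voxels`.
#' @export
compute_fsc <- function(volume_a, volume_b, mask = NULL) {
  da <- vol_dims(volume_a)
  if (!all(da == vol_dims(volume_b))) stop("box mismatch")
  if (!is.null(mask)) {
    volume_a <- volume_a * mask
    volume_b <- volume_b * mask
  }
  fa <- stats::fft(volume_a)
  fb <- stats::fft(volume_b)
  shell <- round(radius_grid(da))
  nmax <- min(da) %/% 2
  sel <- shell <= nmax
  num <- Re(tapply(Re(fa[sel] * Conj(fb[sel])), shell[sel], sum))
  pa <- tapply(Mod(fa[sel])^2, shell[sel], sum)
  pb <- tapply(Mod(fb[sel])^2, shell[sel], sum)
  nvox <- tapply(rep(1, sum(sel)), shell[sel], sum)
  fsc <- num / sqrt(pmax(pa * pb, 1e-300))
  out <- data.frame(shell = as.integer(names(nvox)), fsc = as.numeric(fsc),
                    n_voxels = as.integer(nvox))
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Finds the first crossing of the FSC below the threshold (linear
#' interpolation between shells) and converts it to Angstrom as
#' `N * voxel / shell`.  If the curve never crosses, the Nyquist bound is
#' returned flagged `crossed = FALSE`.
#'
#' @param fsc an `fsc_curve` from [compute_fsc()].
#' @param box box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param threshold FSC threshold (default 0.143).
#' @return list with `resolution_A`, `crossed`, `shell`.
#' @export
resolution_at <- function(fsc, box, voxel_size, threshold = 0.143) {
  s <- fsc$shell; v <- fsc$fsc
  keep <- s > 0
  s <- s[keep]; v <- v[keep]
  below <- which(v < threshold)
  if (!length(below))
    return(list(resolution_A = 2 * voxel_size, crossed = FALSE,
                shell = max(s)))
  i <- below[1]
  if (i == 1L) {
    sc <- s[1]
  } else {
    # linear interpolation between the last shell above and first below
    f <- (v[i - 1] - threshold) / (v[i - 1] - v[i])
    sc <- s[i - 1] + f * (s[i] - s[i - 1])
  }
  list(resolution_A = box * voxel_size / sc, crossed = TRUE, shell = sc)
}

#' Write an FSC curve as two-column text plus a JSON summary
#'
#' @param fsc an `fsc_curve`.
#' @param box,voxel_size geometry for the frequency axis.
#' @param path output path (text); summary goes to `<path>.json`.
#' @export
write_fsc <- function(fsc, box, voxel_size, path) {
  freq <- fsc$shell / (box * voxel_size)
  writeLines(sprintf("%.8g %.8g", freq, fsc$fsc), path)
  res <- resolution_at(fsc, box, voxel_size)
  jsonlite::write_json(list(resolution_A = res$resolution_A,
                            crossed = res$crossed, threshold = 0.143),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Soft low-pass at a fraction of Nyquist (cosine edge).
lowpass_volume <- function(volume, frac) {
  if (frac >= 1) return(volume)
  d <- vol_dims(volume)
  r <- radius_grid(d, relative = TRUE)
  filt <- soft_edge(r, frac * 0.5, 0.05)
  Re(stats::fft(stats::fft(volume) * filt, inverse = TRUE)) / prod(d)
}
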