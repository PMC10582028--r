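#' Rotations, Euler conventions and orientation grids
#'
#' Orientations follow the ZXZ active convention used by Dynamo-style
#' particle tables: `tdrot` rotates about the z axis, `tilt` about the new
#' x axis, `narot` about the resulting z axis, all in degrees.  The
#' corresponding operator is `Rz(tdrot) %*% Rx(tilt) %*% Rz(narot)` and acts
#' on column vectors (active rotation of the template into the particle).
#'
#' @param euler numeric triplet `c(tdrot, tilt, narot)` in degrees.
#' @return `euler_to_matrix` returns a 3x3 rotation matrix;
#'   `matrix_to_euler` returns a named numeric triplet with
#'   `tdrot, narot` in `[0, 360)` and `tilt` in `[0, 180]`.
#' @examples
#' R <- euler_to_matrix(c(30, 40, 50))
#' matrix_to_euler(R)
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(length(euler) == 3L, all(is.finite(euler)))
  rot_z(euler[1]) %*% rot_x(euler[2]) %*% rot_z(euler[3])
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @param R a 3x3 proper rotation matrix (determinant +1).
#' @rdname euler_to_matrix
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (abs(det(R) - 1) > 1e-6)
    stop("not a proper rotation (determinant ", format(det(R)), ")")
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    # gimbal degeneracy: only tdrot + sign(ct) * narot is defined
    tdrot <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (ct < 0) tdrot <- -tdrot
    narot <- 0
  } else {
    tdrot <- atan2(R[1, 3], -R[2, 3]) * 180 / pi
    narot <- atan2(R[3, 1], R[3, 2]) * 180 / pi
  }
  c(tdrot = tdrot %% 360, tilt = tilt, narot = narot %% 360)
}

# Geodesic distance between two rotations, degrees in [0, 180].
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Point-symmetry groups
#'
#' Builds the explicit rotation-operator set for a symmetry group label.
#' Supported: cyclic groups `C1, C2, ...` (n-fold about z) and the
#' octahedral group `O` (24 operators, generated by closure).
#'
#' @param label group label, e.g. `"C4"` or `"O"`.
#' @return list with `label`, `order` and `ops` (list of 3x3 matrices,
#'   identity first).
#' @export
symmetry_group <- function(label) {
  label <- toupper(label)
  if (grepl("^C[0-9]+$", label)) {
    n <- as.integer(sub("^C", "", label))
    if (n < 1) stop("invalid cyclic order in ", label)
    ops <- lapply(seq_len(n) - 1L, function(k) rot_z(360 * k / n))
  } else if (label == "O") {
    ops <- group_closure(list(rot_z(90), rot_x(90)))
    if (length(ops) != 24L) stop("octahedral closure failed") # nocov
  } else {
    stop("unsupported symmetry group '", label,
         "'; supported: C1, C2, ... and O")
  }
  list(label = label, order = length(ops), ops = ops)
}

group_closure <- function(generators, max_order = 100L) {
  ops <- list(diag(3))
  repeat {
    new_ops <- list()
    for (g in generators) for (o in ops) {
      cand <- g %*% o
      known <- any(vapply(c(ops, new_ops),
                          function(x) rotation_distance(x, cand) < 1e-6,
                          logical(1)))
      if (!known) new_ops[[length(new_ops) + 1L]] <- cand
    }
    if (length(new_ops) == 0L) break
    ops <- c(ops, new_ops)
    if (length(ops) > max_order) stop("group closure exceeded ", max_order)
  }
  ops
}

#' Orientation grid for exhaustive angular search
#'
#' Samples template orientations as a cone search (axis directions on a
#' spherical cap) combined with an in-plane rotation sweep, then removes
#' orientations equivalent under the template point symmetry.  Cone axes are
#' placed on a deterministic equal-area spiral so grids are reproducible
#' without a seed.  `cone_range` is the full opening angle of the search
#' cone (`360` means the full sphere); the cap half-angle is
#' `cone_range / 2`.
#'
#' @param cone_sampling,inplane_sampling angular step, degrees (> 0).
#' @param cone_range,inplane_range search extent, degrees in `(0, 360]`;
#'   `cone_range = 0` disables the axis search.
#' @param symmetry group label (see [symmetry_group()]); for cyclic groups
#'   the in-plane range collapses to `360 / n`.
#' @return data.frame of class `orientation_grid` with columns
#'   `tdrot, tilt, narot` (identity first) and the parameters as attributes.
#' @examples
#' nrow(generate_grid(15, 0, 15, 360, "C1")) # 24
#' nrow(generate_grid(15, 0, 15, 360, "C4")) # 6
#' @export
generate_grid <- function(cone_sampling, cone_range,
                          inplane_sampling, inplane_range,
                          symmetry = "C1") {
  stopifnot(cone_sampling > 0, inplane_sampling > 0,
            cone_range >= 0, cone_range <= 360,
            inplane_range > 0, inplane_range <= 360)
  if (cone_range > 0 && cone_sampling > cone_range) {
    warning("cone sampling exceeds cone range; axis search disabled")
    cone_range <- 0
  }
  if (inplane_sampling > inplane_range) {
    warning("in-plane sampling exceeds range; single in-plane angle")
  }
  grp <- symmetry_group(symmetry)
  cyclic_n <- if (grepl("^C[0-9]+$", grp$label))
    as.integer(sub("^C", "", grp$label)) else 1L

  # axis directions (tdrot = azimuth, tilt = polar) on an equal-area spiral
  if (cone_range <= 0) {
    axes <- data.frame(tdrot = 0, tilt = 0)
  } else {
    half <- min(cone_range, 360) / 2 * pi / 180
    s <- cone_sampling * pi / 180
    area <- 2 * pi * (1 - cos(half))
    n_ax <- max(1L, ceiling(1.2 * area / s^2))
    if (n_ax == 1L) {
      axes <- data.frame(tdrot = 0, tilt = 0)
    } else {
      i <- seq_len(n_ax)
      z <- 1 - (1 - cos(half)) * (i - 1) / (n_ax - 1)
      theta <- acos(pmin(1, pmax(-1, z))) * 180 / pi
      golden <- 180 * (3 - sqrt(5))
      phi <- ((i - 1) * golden) %% 360
      phi[1] <- 0
      axes <- data.frame(tdrot = phi, tilt = theta)
    }
  }

  # in-plane sweep, centered on zero; cyclic symmetry collapses the range
  ir <- min(inplane_range, 360 / cyclic_n)
  if (inplane_sampling > ir) {
    psi <- 0
  } else {
    # symmetric sweep that always contains the identity in-plane angle
    pos <- seq(0, ir / 2 + 1e-9, by = inplane_sampling)
    psi <- sort(unique(c(-pos, pos)))
    if (length(psi) > 1L &&
        isTRUE(all.equal((max(psi) - min(psi)) %% 360, ir %% 360)) &&
        isTRUE(all.equal(ir %% (360 / cyclic_n), 0)))
      psi <- psi[-length(psi)] # endpoints equivalent under the symmetry
  }

  grid <- expand.grid(narot = psi, idx = seq_len(nrow(axes)))
  out <- data.frame(tdrot = axes$tdrot[grid$idx] %% 360,
                    tilt = axes$tilt[grid$idx],
                    narot = grid$narot %% 360)
  # put the identity orientation first
  id_row <- which(out$tilt < 1e-9 & (out$tdrot + out$narot) %% 360 < 1e-9)
  if (length(id_row) >= 1L)
    out <- rbind(out[id_row[1], ], out[-id_row[1], ])
  row.names(out) <- NULL

  # generic symmetry reduction for non-cyclic groups
  if (!grepl("^C[0-9]+$", grp$label)) {
    tol <- 0.5 * min(cone_sampling, inplane_sampling)
    out <- reduce_by_symmetry(out, grp, tol)
  }
  attr(out, "cone_sampling") <- cone_sampling
  attr(out, "cone_range") <- cone_range
  attr(out, "inplane_sampling") <- inplane_sampling
  attr(out, "inplane_range") <- inplane_range
  attr(out, "symmetry") <- grp$label
  class(out) <- c("orientation_grid", "data.frame")
  out
}

reduce_by_symmetry <- function(grid, grp, tol_deg) {
  mats <- lapply(seq_len(nrow(grid)),
                 function(i) euler_to_matrix(as.numeric(grid[i, 1:3])))
  keep <- logical(nrow(grid))
  kept <- list()
  for (i in seq_along(mats)) {
    dup <- FALSE
    for (k in kept) {
      for (s in grp$ops) {
        if (rotation_distance(mats[[i]] %*% s, k) < tol_deg) { dup <- TRUE; break }
      }
      if (dup) break
    }
    if (!dup) {
      keep[i] <- TRUE
      kept[[length(kept) + 1L]] <- mats[[i]]
    }
  }
  out <- grid[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

grid_matrices <- function(grid) {
  vapply(seq_len(nrow(grid)),
         function(i) euler_to_matrix(as.numeric(grid[i, c("tdrot", "tilt", "narot")])),
         numeric(9))
}

#' Fourier-space missing-wedge mask
#'
#' Marks the Fourier voxels of a box that are sampled by a single-axis tilt
#' series (tilt axis = y).  Each tilt angle contributes a central section of
#' one Fourier-voxel thickness; the union over the tilt list is the sampled
#' region, optionally smoothed by a cosine ramp.  The mask is returned in
#' unshifted layout (DC at the first element) and is Hermitian-symmetric.
#'
#' @param tilt_angles tilt angles in degrees, within (-90, 90).
#' @param box_shape integer length-3 box dimensions.
#' @param soft_edge_width cosine ramp width in Fourier voxels (0 = binary).
#' @return numeric array in `[0, 1]` of dimension `box_shape`.
#' @export
wedge_mask <- function(tilt_angles, box_shape, soft_edge_width = 0) {
  if (length(tilt_angles) == 0L) stop("empty tilt list")
  stopifnot(all(tilt_angles > -90 & tilt_angles < 90))
  box_shape <- as.integer(box_shape)
  kx <- fft_index(box_shape[1])
  kz <- fft_index(box_shape[3])
  # distance of (kx, kz) to the nearest central section; ky is free.
  # Nyquist bins alias +n/2 and -n/2, so the distance is taken as the
  # minimum over both sign interpretations, keeping the sampled mask
  # exactly Hermitian.
  kxa <- ifelse(abs(kx) == box_shape[1] / 2, -kx, kx)
  kza <- ifelse(abs(kz) == box_shape[3] / 2, -kz, kz)
  dmin <- matrix(Inf, length(kx), length(kz))
  for (th in tilt_angles * pi / 180) {
    # section plane normal in the xz Fourier plane: (-sin, cos)
    s <- -sin(th); cth <- cos(th)
    dmin <- pmin(dmin,
                 abs(outer(kx * s, kz * cth, `+`)),
                 abs(outer(kxa * s, kz * cth, `+`)),
                 abs(outer(kx * s, kza * cth, `+`)),
                 abs(outer(kxa * s, kza * cth, `+`)))
  }
  m2d <- soft_edge(dmin, 0.5, soft_edge_width)
  aperm(array(rep(m2d, box_shape[2]),
              dim = c(box_shape[1], box_shape[3], box_shape[2])),
        c(1, 3, 2))
}

#' Symmetrize a volume
#'
#' Replaces a cubic volume by the mean over its orbit under a point-symmetry
#' group (trilinear interpolation per rotated copy).
#'
#' @param volume cubic 3D array.
#' @param symmetry group label (see [symmetry_group()]).
#' @return symmetrized array of the same dimension.
#' @export
symmetrize <- function(volume, symmetry) {
  d <- vol_dims(volume)
  if (length(unique(d)) != 1L) stop("symmetrize expects a cubic volume")
  grp <- symmetry_group(symmetry)
  if (grp$order == 1L) return(volume)
  acc <- array(0, d)
  for (s in grp$ops)
    acc <- acc + cpp_rotate3(as.numeric(volume), d, s, c(0, 0, 0))
  acc / grp$order
}

# Uniform random rotation matrices (Haar measure) via quaternions.
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) quat_to_matrix(q[i, ]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
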