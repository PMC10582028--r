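#' Export particles and tomogram metadata as a STAR file
#'
#' Writes three blocks: `data_tomograms` (name, dimensions, pixel size),
#' `data_tilts` (per-tilt angle and pre-exposure, i.e. the accumulated dose
#' before each image in acquisition order — this carries uneven schemes such
#' as a high-dose zero-tilt image) and `data_particles` (coordinates and
#' Euler angles).  Angles are mapped from the internal ZXZ triplet to the
#' ZYZ `rot/tilt/psi` convention through the rotation matrix, so the
#' identity orientation exports as all-zero angles.
#'
#' @param records a `particle_table` (positions 0-based; written 1-based? no:
#'   coordinates are written as the internal 0-based voxel positions plus
#'   sub-voxel shifts, in voxels of the source tomogram).
#' @param tomogram_descriptions data.frame with columns
#'   `tomogram_id, name, nx, ny, nz, pixel_size`.
#' @param dose_table data.frame with columns
#'   `tomogram_id, tilt_angle, acquisition_order, dose`; pre-exposure is
#'   computed as the cumulative dose before each image in acquisition order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_star <- function(records, tomogram_descriptions, dose_table, path) {
  records <- as_particle_table(records)
  td <- tomogram_descriptions
  need <- c("tomogram_id", "name", "nx", "ny", "nz", "pixel_size")
  if (!all(need %in% names(td)))
    stop("tomogram_descriptions needs columns: ", paste(need, collapse = ", "))
  missing_ids <- setdiff(unique(records$tomogram_id), td$tomogram_id)
  if (length(missing_ids))
    stop("no tomogram description for tomogram_id ",
         paste(missing_ids, collapse = ", "))

  con <- textConnection("starout", "w", local = TRUE)
  w <- function(...) writeLines(paste0(...), con)

  w("data_tomograms"); w(""); w("loop_")
  w("_rlnTomoName #1"); w("_rlnTomoSizeX #2"); w("_rlnTomoSizeY #3")
  w("_rlnTomoSizeZ #4"); w("_rlnTomoTiltSeriesPixelSize #5")
  for (i in seq_len(nrow(td)))
    w(sprintf("%s %d %d %d %.6g", td$name[i], td$nx[i], td$ny[i], td$nz[i],
              td$pixel_size[i]))
  w("")

  w("data_tilts"); w(""); w("loop_")
  w("_rlnTomoName #1"); w("_rlnTomoNominalStageTiltAngle #2")
  w("_rlnMicrographPreExposure #3")
  for (tid in unique(dose_table$tomogram_id)) {
    dt <- dose_table[dose_table$tomogram_id == tid, ]
    dt <- dt[order(dt$tilt_angle), ]  # rows in stack (tilt) order
    nm <- td$name[match(tid, td$tomogram_id)]
    ord <- order(dt$acquisition_order)
    # pre-exposure: cumulative dose before each image, in acquisition order
    pre_tilt <- numeric(nrow(dt))
    pre_tilt[ord] <- cumsum(c(0, dt$dose[ord]))[seq_len(nrow(dt))]
    for (i in seq_len(nrow(dt)))
      w(sprintf("%s %.4f %.6g", nm, dt$tilt_angle[i], pre_tilt[i]))
  }
  w("")

  w("data_particles"); w(""); w("loop_")
  w("_rlnTomoName #1"); w("_rlnCoordinateX #2"); w("_rlnCoordinateY #3")
  w("_rlnCoordinateZ #4"); w("_rlnAngleRot #5"); w("_rlnAngleTilt #6")
  w("_rlnAnglePsi #7"); w("_rlnClassNumber #8")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    zyz <- zxz_to_zyz(c(r$tdrot, r$tilt, r$narot))
    nm <- td$name[match(r$tomogram_id, td$tomogram_id)]
    w(sprintf("%s %.6g %.6g %.6g %.6g %.6g %.6g %d",
              nm, r$x + r$dx, r$y + r$dy, r$z + r$dz,
              zyz[1], zyz[2], zyz[3], r$class_id))
  }
  close(con)
  writeLines(starout, path)
  invisible(path)
}

# ZXZ (tdrot, tilt, narot) -> ZYZ (rot, tilt, psi), via the matrix so the
# gimbal-degenerate identity maps to (0, 0, 0).
zxz_to_zyz <- function(euler) {
  R <- euler_to_matrix(euler)
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    rot <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (ct < 0) rot <- -rot
    return(c(rot = rot, tilt = tilt, psi = 0))
  }
  # R = Rz(rot) Ry(tilt) Rz(psi)
  rot <- atan2(R[2, 3], R[1, 3]) * 180 / pi
  psi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  c(rot = rot, tilt = tilt, psi = psi)
}

#' Read particle coordinates back from an exported STAR file
#'
#' Companion to [export_star()] for round-trip checks: parses the
#' `data_particles` block and returns a data.frame of coordinates, angles
#' and tomogram names.
#'
#' @param path STAR file written by [export_star()].
#' @export
read_star_particles <- function(path) {
  lines <- readLines(path)
  i <- which(lines == "data_particles")
  if (!length(i)) stop("no data_particles block in ", path)
  j <- i + 1L
  while (j <= length(lines) && lines[j] != "loop_") j <- j + 1L
  cols <- character()
  j <- j + 1L
  while (j <= length(lines) && startsWith(lines[j], "_")) {
    cols <- c(cols, sub("^_(\\S+).*$", "\\1", lines[j]))
    j <- j + 1L
  }
  rows <- list()
  while (j <= length(lines) && nzchar(trimws(lines[j]))) {
    rows[[length(rows) + 1L]] <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
    j <- j + 1L
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  for (cc in setdiff(cols, "rlnTomoName"))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}
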