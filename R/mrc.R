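#' Read and write MRC2014 volumes and stacks
#'
#' Minimal self-contained MRC2014 implementation.  Volumes are stored with
#' the x axis fastest (`nx, ny, nz`); the writer always emits mode 2
#' (32-bit float) with the `MAP ` magic and little-endian machine stamp.
#' The reader accepts modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16).
#'
#' @param path file path.
#' @param volume 2D or 3D numeric array of finite values.
#' @param voxel_size voxel size in Angstrom (scalar or length 3).
#' @param origin origin offset in Angstrom (length 3).
#' @return `read_mrc` returns a list with `data` (array) and `header`
#'   (list: `shape`, `voxel_size`, `mode`, `origin`); `write_mrc` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' write_mrc(array(0, c(16, 16, 16)), f, voxel_size = 1.378)
#' read_mrc(f)$header$voxel_size
#' @export
write_mrc <- function(volume, path, voxel_size = 1, origin = c(0, 0, 0)) {
  volume <- as_volume(volume)
  if (!all(is.finite(volume)))
    stop("refusing to write non-finite voxel values")
  d <- dim(volume)
  voxel_size <- rep_len(voxel_size, 3L)
  stopifnot(all(voxel_size > 0))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * voxel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(volume), max(volume), mean(volume)))
  wi(c(1L, 0L))              # ispg, nsymbt
  writeBin(raw(100L), con)   # extra
  wf(origin)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(volume)))
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(volume), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 1024) stop("MRC format error: file shorter than the 1024-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (any(d <= 0) || any(d > 1e5))
    stop("MRC format error: invalid dimensions field (nx,ny,nz = ",
         paste(d, collapse = ","), ")")
  ri(3L)            # nxstart
  m <- ri(3L)       # mx my mz
  cella <- rf(3L)
  rf(3L)            # cellb
  ri(3L)            # axis order
  rf(3L); ri(2L)    # dmin/dmax/dmean, ispg/nsymbt
  readBin(con, "raw", n = 100L)
  origin <- rf(3L)
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (!identical(magic, "MAP "))
    warning("missing 'MAP ' magic; attempting to read anyway")
  seek(con, 1024L)
  n <- prod(d)
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(mode)]
  if (is.na(bytes))
    stop("MRC format error: unsupported mode field (", mode, ")")
  if (sz < 1024 + n * bytes)
    stop("MRC format error: data section truncated (expected ",
         n * bytes, " bytes after header)")
  data <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    `1` = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = FALSE, endian = "little")))
  dim(data) <- d
  vx <- ifelse(m > 0, cella / m, 1)
  if (any(vx <= 0)) vx <- rep(1, 3)
  list(data = data,
       header = list(shape = d, voxel_size = vx[1], voxel_size_xyz = vx,
                     mode = mode, origin = origin))
}
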