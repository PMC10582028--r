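#' Particle tables
#'
#' Plain-text, whitespace-separated particle tables in a Dynamo-style
#' dialect with 14 fixed columns, one row per particle:
#' `tag cc x y z dx dy dz tdrot tilt narot class_id tomogram_id half_set`.
#' On disk, `x y z` are 1-based voxel indices (the table-dialect
#' convention); in memory every position is 0-based — the conversion
#' happens only here, at the I/O boundary.  Extra trailing columns are
#' ignored with a warning; a row with fewer columns is a parse error that
#' names the line.
#'
#' @param n number of empty records.
#' @return a `data.frame` of class `particle_table`.
#' @export
particle_table <- function(n = 0L) {
  df <- data.frame(tag = integer(n), cc = numeric(n),
                   x = numeric(n), y = numeric(n), z = numeric(n),
                   dx = numeric(n), dy = numeric(n), dz = numeric(n),
                   tdrot = numeric(n), tilt = numeric(n), narot = numeric(n),
                   class_id = integer(n), tomogram_id = integer(n),
                   half_set = integer(n))
  class(df) <- c("particle_table", "data.frame")
  df
}

table_columns <- function() names(particle_table(0L))

as_particle_table <- function(df) {
  miss <- setdiff(table_columns(), names(df))
  if (length(miss)) stop("missing particle-table columns: ",
                         paste(miss, collapse = ", "))
  df <- df[table_columns()]
  class(df) <- c("particle_table", "data.frame")
  df
}

validate_particle_table <- function(tbl) {
  num <- as.matrix(tbl)
  if (!all(is.finite(num))) stop("non-finite values in particle table")
  if (anyDuplicated(tbl$tag)) stop("duplicate particle tags")
  invisible(tbl)
}

#' @param records a `particle_table` (positions 0-based, see Details).
#' @param path file path (conventionally `.tbl`).
#' @rdname particle_table
#' @export
write_table <- function(records, path) {
  records <- as_particle_table(records)
  validate_particle_table(records)
  m <- as.matrix(records)
  m[, c("x", "y", "z")] <- m[, c("x", "y", "z")] + 1  # to 1-based dialect
  lines <- apply(m, 1L, function(r) paste(sprintf("%.8g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname particle_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ncols <- length(table_columns())
  rows <- vector("list", length(lines))
  warned <- FALSE
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) < ncols)
      stop("parse error in ", path, " line ", i, ": expected at least ",
           ncols, " columns, found ", length(f))
    if (length(f) > ncols && !warned) {
      warning("ignoring ", length(f) - ncols, " extra trailing column(s) in ",
              path)
      warned <- TRUE
    }
    v <- suppressWarnings(as.numeric(f[seq_len(ncols)]))
    if (anyNA(v))
      stop("parse error in ", path, " line ", i, ": non-numeric field")
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) return(particle_table(0L))
  df <- as.data.frame(m)
  names(df) <- table_columns()
  df$x <- df$x - 1; df$y <- df$y - 1; df$z <- df$z - 1  # to 0-based internal
  for (cc in c("tag", "class_id", "tomogram_id", "half_set"))
    df[[cc]] <- as.integer(round(df[[cc]]))
  class(df) <- c("particle_table", "data.frame")
  df
}
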