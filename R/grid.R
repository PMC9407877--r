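# Grid plumbing shared by all modules: grid specification, raster matrices,
# neighbourhood shifts, smoothed Gaussian random fields, plain-text raster I/O.
# Rasters are base R numeric/integer matrices in row-major display order
# (row 1 = top of the map); georeferencing is carried by the GridSpec only
# and areas always come from cell_size, never from a projection.

#' Grid specification
#'
#' Defines the raster geometry every layer of a run shares: number of rows
#' and columns, square cell size in metres, and the nodata sentinel used
#' when rasters are written to disk.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0). Default 250 m.
#' @param nodata Sentinel written for missing cells in ASCII grids.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 250, nodata = -9999) {
  if (!is.numeric(n_rows) || n_rows < 1 || !is.numeric(n_cols) || n_cols < 1)
    stop_invalid("n_rows and n_cols must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop_invalid("cell_size must be > 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), nodata = nodata),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.0f m resolution (%.1f ha/cell)\n",
              x$n_rows, x$n_cols, x$cell_size, cell_area_ha(x)))
  invisible(x)
}

#' Cell area in hectares
#' @param spec A `grid_spec`.
#' @return Scalar area of one cell in ha.
#' @export
cell_area_ha <- function(spec) spec$cell_size^2 / 1e4

n_cells <- function(spec) spec$n_rows * spec$n_cols

# ---- error helpers -----------------------------------------------------

stop_with <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eslines_error")))
}
stop_invalid <- function(msg) stop_with(msg, "eslines_invalid_parameter")

# ---- deterministic RNG scope -------------------------------------------

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are pure functions of (args, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# ---- neighbourhood shifts ----------------------------------------------

# Shift a matrix by (dr, dc), padding with `fill`. shift_mat(m, 1, 0) moves
# content down: result[r, c] == m[r - 1, c].
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

offsets4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
offsets8 <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                  dc = c(0, 0, -1, 1, -1, 1, -1, 1))

# ---- smoothed Gaussian random field ------------------------------------

# Unit-variance spatially autocorrelated field: white noise blurred with
# three passes of a box filter of half-width `range_cells` (approximates a
# Gaussian kernel), rescaled to sd 1. The grid mean is NOT removed: smooth
# fields have few effective degrees of freedom, so their spatial mean
# fluctuates realization to realization — this is what gives yearly
# regional anomalies around a configured climate path. Consumes the active
# RNG stream.
gaussian_field <- function(n_rows, n_cols, range_cells = 5) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  w <- max(1L, as.integer(round(range_cells)))
  for (i in 1:3) z <- box_blur(z, w)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}

# Separable box blur with reflecting edges via padded cumulative sums.
box_blur <- function(m, w) {
  m <- t(apply(m, 1, running_mean, w = w))
  m <- apply(m, 2, running_mean, w = w)
  m
}

running_mean <- function(x, w) {
  n <- length(x)
  if (n == 1L) return(x)
  wn <- min(w, n)
  xp <- c(rev(x[seq_len(wn)]), x, rev(x[seq.int(n - wn + 1L, n)]))
  cs <- c(0, cumsum(xp))
  idx <- seq_len(n) + wn            # centre positions within xp
  (cs[idx + wn + 1L] - cs[idx - wn]) / (2L * wn + 1L)
}

# ---- plain-text raster I/O (ESRI ASCII grid) ---------------------------

#' Write a raster matrix as an ESRI ASCII grid
#'
#' Single-band plain-text raster format (`.asc`): a six-line header followed
#' by rows of whitespace-separated values, row 1 at the top.
#'
#' @param m Numeric matrix.
#' @param spec A `grid_spec` (dimensions must match `m`).
#' @param path Output file path.
#' @param xll,yll Lower-left corner coordinates (metres).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, spec, path, xll = 0, yll = 0) {
  stopifnot(nrow(m) == spec$n_rows, ncol(m) == spec$n_cols)
  v <- m
  v[is.na(v)] <- spec$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.6f", xll),
    sprintf("yllcorner %.6f", yll),
    sprintf("cellsize %.6f", spec$cell_size),
    sprintf("NODATA_value %s", format(spec$nodata))
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_ascii_grid()] or any conforming
#'   tool.
#' @return A list with `values` (matrix, `NA` where nodata) and `spec`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m,
       spec = grid_spec(nr, nc, cell_size = vals[["cellsize"]],
                        nodata = nodata))
}

# clamp utility used across modules
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
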