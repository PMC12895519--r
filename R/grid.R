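#' Rectilinear finite-volume grids
#'
#' The continuum solvers discretise the channel window on a tensor-product
#' grid that is fine near the interface (where attractant gradients and
#' bacterial accumulation live) and geometrically stretched toward the far
#' boundaries.  Faces are the primary objects; cell centres sit midway
#' between faces.
#'
#' @name fv_grid
NULL

# One stretched axis: uniform spacing h_fine on [fine_lo, fine_hi],
# geometric stretching (factor `ratio`, capped at h_max) out to the ends,
# with the outermost segment rescaled so faces land exactly on from/to.
stretched_axis <- function(from, to, fine_lo, fine_hi,
                           h_fine, h_max, ratio = 1.15) {
  stopifnot(from < to, fine_lo < fine_hi, h_fine > 0, h_max >= h_fine,
            ratio > 1)
  fine_lo <- max(fine_lo, from)
  fine_hi <- min(fine_hi, to)
  n_fine <- max(1L, ceiling((fine_hi - fine_lo) / h_fine))
  faces <- seq(fine_lo, fine_hi, length.out = n_fine + 1L)

  stretch <- function(gap) {
    if (gap <= 1e-9) return(numeric(0))
    h <- h_fine
    steps <- numeric(0)
    while (sum(steps) < gap) {
      h <- min(h * ratio, h_max)
      steps <- c(steps, h)
    }
    steps * (gap / sum(steps))  # land exactly on the boundary
  }
  left <- stretch(fine_lo - from)
  right <- stretch(to - fine_hi)
  faces <- c(fine_lo - rev(cumsum(left)), faces, fine_hi + cumsum(right))
  faces[1] <- from
  faces[length(faces)] <- to
  faces
}

#' Build the default solver grid for a channel window
#'
#' @param geom A [channel_geometry()].
#' @param h_fine_x,h_fine_y Fine spacing (um) in the refined region around
#'   the interface segment.
#' @param h_max_x,h_max_y Cap on the stretched spacing (um).
#' @param fine_margin_x Streamwise half-extent of the refined region
#'   beyond the interface segment (um).
#' @param fine_extent_y Transverse extent of the refined region from the
#'   interface wall (um).
#' @param ratio Geometric stretching factor.
#' @return An `fv_grid`: face coordinates `xf`, `yf`, centres `xc`, `yc`,
#'   spacings `dx`, `dy` and counts `nx`, `ny`.
#' @export
make_grid <- function(geom,
                      h_fine_x = 10, h_max_x = 150, fine_margin_x = 300,
                      h_fine_y = 2.5, h_max_y = 150, fine_extent_y = 250,
                      ratio = 1.15) {
  x0 <- geom$interface_start_x
  x1 <- x0 + geom$interface_width
  xf <- stretched_axis(geom$x_min, geom$x_max,
                       x0 - fine_margin_x, x1 + fine_margin_x,
                       h_fine_x, h_max_x, ratio)
  yf <- stretched_axis(0, geom$domain_width_y, 0, fine_extent_y,
                       h_fine_y, h_max_y, ratio)
  structure(list(
    xf = xf, yf = yf,
    xc = (xf[-1] + xf[-length(xf)]) / 2,
    yc = (yf[-1] + yf[-length(yf)]) / 2,
    dx = diff(xf), dy = diff(yf),
    nx = length(xf) - 1L, ny = length(yf) - 1L
  ), class = "fv_grid")
}

#' @export
print.fv_grid <- function(x, ...) {
  cat(sprintf(
    "<fv_grid> %d x %d cells; x in [%.0f, %.0f] (h %.2g-%.3g um), y in [%.0f, %.0f] (h %.2g-%.3g um)\n",
    x$nx, x$ny, min(x$xf), max(x$xf), min(x$dx), max(x$dx),
    min(x$yf), max(x$yf), min(x$dy), max(x$dy)))
  invisible(x)
}

#' Gridded scalar field
#'
#' Container for a concentration or density defined at cell centres of an
#' [make_grid()] grid: `values` is an `nx` x `ny` matrix (x indexes rows).
#'
#' @param grid An `fv_grid`.
#' @param values `nx` x `ny` numeric matrix.
#' @param units Character unit tag (informational).
#' @param time Optional time stamp (s) for transient snapshots.
#' @return A `scalar_field2d` object.
#' @export
scalar_field2d <- function(grid, values, units = "mol/m^3", time = NA_real_) {
  stopifnot(inherits(grid, "fv_grid"),
            is.matrix(values),
            nrow(values) == grid$nx, ncol(values) == grid$ny,
            all(is.finite(values)))
  structure(list(grid = grid, values = values, units = units, time = time),
            class = "scalar_field2d")
}

#' @export
print.scalar_field2d <- function(x, ...) {
  cat(sprintf("<scalar_field2d> %d x %d cells, range [%.4g, %.4g] %s\n",
              x$grid$nx, x$grid$ny, min(x$values), max(x$values), x$units))
  invisible(x)
}

#' Bilinear interpolation of a field at arbitrary points
#'
#' Cell-centre values are interpolated bilinearly; points outside the
#' centre lattice are clamped to the nearest centre (constant
#' extrapolation), which is the behaviour agents need right against a
#' wall.
#'
#' @param field A `scalar_field2d`.
#' @param x,y Point coordinates (um), equal length.
#' @return Interpolated values.
#' @export
field_interp <- function(field, x, y) {
  g <- field$grid
  xi <- clamp(x, g$xc[1], g$xc[g$nx])
  yi <- clamp(y, g$yc[1], g$yc[g$ny])
  i <- findInterval(xi, g$xc, rightmost.closed = TRUE)
  i <- clamp_int(i, 1L, g$nx - 1L)
  j <- findInterval(yi, g$yc, rightmost.closed = TRUE)
  j <- clamp_int(j, 1L, g$ny - 1L)
  tx <- (xi - g$xc[i]) / (g$xc[i + 1L] - g$xc[i])
  ty <- (yi - g$yc[j]) / (g$yc[j + 1L] - g$yc[j])
  v <- field$values
  (1 - tx) * (1 - ty) * v[cbind(i, j)] +
    tx * (1 - ty) * v[cbind(i + 1L, j)] +
    (1 - tx) * ty * v[cbind(i, j + 1L)] +
    tx * ty * v[cbind(i + 1L, j + 1L)]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp_int <- function(x, lo, hi) pmin.int(pmax.int(x, lo), hi)

#' Export / import a field as delimited text
#'
#' Long-format `(x_um, y_um, value)` tables, one row per cell centre.
#'
#' @param field A `scalar_field2d`.
#' @param path File path.
#' @return `write_field` returns `path` invisibly; `read_field_table`
#'   returns a data frame.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  df <- data.frame(x_um = rep(g$xc, times = g$ny),
                   y_um = rep(g$yc, each = g$nx),
                   value = as.vector(field$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
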