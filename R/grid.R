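#' Regular 2-D calculation grid
#'
#' Defines the beam's-eye-view grid on which fluence and planar dose are
#' rasterized.  Coordinates are in millimetres at the isocenter plane;
#' `x` is the leaf-travel (crossplane) axis and `y` the leaf-pair axis.
#' `origin_mm` is the centre of the first grid voxel.
#'
#' @param origin_mm numeric length-2, centre of voxel (1,1) in mm `(x, y)`.
#' @param spacing_mm voxel pitch in mm (isotropic, > 0).
#' @param nx,ny number of voxels along x and y (each >= 2).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(-127.5, -127.5), 1, 256, 256)
#' range(grid_axes(g)$x)
#' @export
grid_spec <- function(origin_mm = c(-127.5, -127.5), spacing_mm = 1,
                      nx = 256, ny = 256) {
  stopifnot(length(origin_mm) == 2, is.finite(origin_mm),
            is.numeric(spacing_mm), length(spacing_mm) == 1, spacing_mm > 0,
            nx >= 2, ny >= 2)
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' Grid axis coordinates
#'
#' @param grid a [grid_spec()].
#' @return list with numeric vectors `x` (length `nx`) and `y` (length `ny`).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$origin_mm[1] + (seq_len(grid$nx) - 1) * grid$spacing_mm,
       y = grid$origin_mm[2] + (seq_len(grid$ny) - 1) * grid$spacing_mm)
}

#' Construct a scalar field on a grid
#'
#' A `dose_map` holds a nonnegative scalar field (fluence or dose, the
#' semantics are carried by the caller) as an `nx x ny` matrix with
#' `values[i, j]` the sample at `(x_i, y_j)`.
#'
#' @param grid a [grid_spec()].
#' @param values `nx x ny` numeric matrix, finite and >= 0.
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$nx, ncol(values) == grid$ny)
  if (!all(is.finite(values)) || any(values < -1e-12))
    stop("dose_map values must be finite and nonnegative")
  structure(list(grid = grid, values = values), class = "dose_map")
}

#' @export
print.grid_spec <- function(x, ...) {
  ax <- grid_axes(x)
  cat(sprintf("<grid_spec> %d x %d @ %.3g mm, x [%g, %g] mm, y [%g, %g] mm\n",
              x$nx, x$ny, x$spacing_mm, min(ax$x), max(ax$x),
              min(ax$y), max(ax$y)))
  invisible(x)
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d @ %.3g mm, range [%.4g, %.4g]\n",
              x$grid$nx, x$grid$ny, x$grid$spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Bilinear interpolation of a dose map at arbitrary points
#'
#' Points outside the grid are clamped to the nearest edge value, which is
#' adequate here because maps of interest decay to leaf transmission well
#' inside the grid boundary.
#'
#' @param map a [dose_map()].
#' @param x_mm,y_mm numeric vectors of equal length (or recyclable).
#' @return numeric vector of interpolated values.
#' @export
interp_map <- function(map, x_mm, y_mm) {
  stopifnot(inherits(map, "dose_map"))
  g <- map$grid
  fx <- pmin(pmax((x_mm - g$origin_mm[1]) / g$spacing_mm, 0), g$nx - 1)
  fy <- pmin(pmax((y_mm - g$origin_mm[2]) / g$spacing_mm, 0), g$ny - 1)
  i0 <- pmin(floor(fx), g$nx - 2); j0 <- pmin(floor(fy), g$ny - 2)
  tx <- fx - i0; ty <- fy - j0
  v <- map$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0 + 1, j0) +
    (1 - tx) * ty * idx(i0, j0 + 1) + tx * ty * idx(i0 + 1, j0 + 1)
}

#' Write / read a dose map as a delimited table
#'
#' The header line carries the grid geometry so that a map round-trips
#' exactly; the body is a plain matrix of values.
#'
#' @param map a [dose_map()].
#' @param path file path.
#' @return `write_dose_map` returns `path` invisibly; `read_dose_map`
#'   returns a [dose_map()].
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  g <- map$grid
  hdr <- sprintf("# grid origin_mm=%.9g,%.9g spacing_mm=%.9g nx=%d ny=%d",
                 g$origin_mm[1], g$origin_mm[2], g$spacing_mm, g$nx, g$ny)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "origin_mm=([-0-9.eE+]+),([-0-9.eE+]+) spacing_mm=([-0-9.eE+]+) nx=([0-9]+) ny=([0-9]+)",
    hdr))[[1]]
  if (length(m) != 6) stop("not a dose map file: ", path)
  g <- grid_spec(as.numeric(m[2:3]), as.numeric(m[4]),
                 as.integer(m[5]), as.integer(m[6]))
  vals <- as.matrix(utils::read.table(path, skip = 1, sep = ","))
  dimnames(vals) <- NULL
  dose_map(g, vals)
}
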