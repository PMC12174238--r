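#' Axis-aligned voxel grid geometry
#'
#' A `voxel_grid` describes the geometry of a 3-D image: the number of voxels
#' per axis, the voxel spacing in millimetres, and the world position (mm) of
#' the *centre* of voxel `(1,1,1)`. Grids are axis-aligned; oblique
#' orientations are not supported.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing_mm Positive numeric vector of length 3, voxel edge lengths
#'   in mm.
#' @param origin_mm Numeric vector of length 3, world coordinate (mm) of the
#'   centre of the first voxel. Default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(128, 128, 64), spacing_mm = c(4.42, 4.42, 2.50))
#' voxel_volume_mL(g)
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 integers, each >= 1", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers", call. = FALSE)
  structure(
    list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]
  ))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @return `voxel_volume_mL()`: the volume of one voxel in millilitres.
#' @export
voxel_volume_mL <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing_mm) / 1000
}

#' @rdname voxel_grid
#' @return `grid_n_voxels()`: total number of voxels.
#' @export
grid_n_voxels <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$shape)
}

#' @method all.equal voxel_grid
#' @export
all.equal.voxel_grid <- function(target, current, tolerance = 1e-8, ...) {
  if (!inherits(current, "voxel_grid")) return("not a voxel_grid")
  ok <- identical(target$shape, current$shape) &&
    isTRUE(all.equal(target$spacing_mm, current$spacing_mm, tolerance = tolerance)) &&
    isTRUE(all.equal(target$origin_mm, current$origin_mm, tolerance = tolerance))
  if (ok) TRUE else "voxel grids differ"
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

# World coordinates (mm) of voxel centres along one axis.
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

#' Construct a grid covering a world-space box
#'
#' Builds an axis-aligned `voxel_grid` with the requested spacing whose voxel
#' extent (outer faces) covers `[lower_mm, upper_mm]`.
#'
#' @param lower_mm,upper_mm Numeric length-3 world corners (mm).
#' @param spacing_mm Numeric length-3 voxel spacing (mm).
#' @return A `voxel_grid`.
#' @export
grid_covering <- function(lower_mm, upper_mm, spacing_mm) {
  stopifnot(length(lower_mm) == 3, length(upper_mm) == 3, all(upper_mm > lower_mm))
  shape <- pmax(1L, as.integer(ceiling((upper_mm - lower_mm) / spacing_mm)))
  centre <- (lower_mm + upper_mm) / 2
  origin <- centre - (shape - 1) * spacing_mm / 2
  voxel_grid(shape, spacing_mm, origin)
}

#' Scalar field on a voxel grid
#'
#' A `scalar_volume` couples a 3-D array of non-negative values with its
#' `voxel_grid` geometry and a physical quantity tag: raw `counts`, activity
#' in GBq (`activity_GBq`), or absorbed dose in Gy (`dose_Gy`).
#'
#' @param values Numeric 3-D array (or vector reshaped to `grid$shape`),
#'   finite and non-negative.
#' @param grid A [voxel_grid()].
#' @param quantity One of `"counts"`, `"activity_GBq"`, `"dose_Gy"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid,
                          quantity = c("counts", "activity_GBq", "dose_Gy")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(values) != grid_n_voxels(grid))
    stop("`values` length does not match the grid shape", call. = FALSE)
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (any(values < 0))
    stop(sprintf("negative values are invalid for quantity '%s'", quantity),
         call. = FALSE)
  structure(list(values = values, grid = grid, quantity = quantity),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume: %s> total %.6g, range [%.4g, %.4g]\n",
              x$quantity, sum(x$values), min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' @rdname scalar_volume
#' @param volume A `scalar_volume`.
#' @return `volume_total()`: the sum of all voxel values.
#' @export
volume_total <- function(volume) {
  stopifnot(inherits(volume, "scalar_volume"))
  sum(volume$values)
}

#' Convert a scalar volume to a tibble of voxel records
#'
#' One row per voxel with array indices, world coordinates (mm) of the voxel
#' centre, and the value. Mainly useful for plotting slices with ggplot2.
#'
#' @param x A [scalar_volume()].
#' @param ... Unused.
#' @return A tibble with columns `i, j, k, x_mm, y_mm, z_mm, value`.
#' @method as_tibble scalar_volume
#' @export
as_tibble.scalar_volume <- function(x, ...) {
  g <- x$grid
  idx <- arrayInd(seq_along(x$values), g$shape)
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x_mm = g$origin_mm[1] + (idx[, 1] - 1) * g$spacing_mm[1],
    y_mm = g$origin_mm[2] + (idx[, 2] - 1) * g$spacing_mm[2],
    z_mm = g$origin_mm[3] + (idx[, 3] - 1) * g$spacing_mm[3],
    value = as.vector(x$values)
  )
}
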