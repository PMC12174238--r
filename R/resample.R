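#' Resample a scalar volume onto another grid under a rigid transform
#'
#' Applies a rigid registration transform (source world -> target world) and
#' resamples onto `target_grid` by tri-linear interpolation at the transformed
#' voxel centres. Positions outside the source field of view sample as zero
#' signal (air background), not missing.
#'
#' Two modes are provided:
#' \describe{
#'   \item{`interpolate`}{plain tri-linear sampling; appropriate for dose
#'     maps, which are intensive quantities.}
#'   \item{`conserve_total`}{tri-linear sampling followed by a global rescale
#'     so the output total equals the input total. Required for counts and
#'     activity (extensive quantities, e.g. GBq, must not be created or lost
#'     by regridding) and forbidden for dose.}
#' }
#'
#' @param volume A [scalar_volume()].
#' @param target_grid A [voxel_grid()] to resample onto.
#' @param transform A [rigid_transform()] mapping source world coordinates to
#'   target world coordinates. Default: identity.
#' @param mode `"interpolate"` or `"conserve_total"`.
#' @return A [scalar_volume()] on `target_grid` with the same quantity.
#' @examples
#' g <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
#' v <- scalar_volume(rep(5, 512), g, "counts")
#' out <- resample(v, g)            # identity: returns the input values
#' all.equal(out$values, v$values)
#' @export
resample <- function(volume, target_grid,
                     transform = rigid_transform(),
                     mode = c("interpolate", "conserve_total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "scalar_volume"), inherits(target_grid, "voxel_grid"))
  total_in <- sum(volume$values)
  if (mode == "conserve_total") {
    if (volume$quantity == "dose_Gy")
      stop("non-conserved quantity: dose must not be resampled with conserve_total",
           call. = FALSE)
    if (total_in <= 0)
      stop("empty source: cannot conserve a zero total", call. = FALSE)
  }
  # Identity transform onto the same grid is exact by construction.
  if (is_identity_transform(transform) && same_grid(volume$grid, target_grid))
    return(scalar_volume(volume$values, target_grid, volume$quantity))

  vals <- trilinear_sample(volume$values, volume$grid, target_grid,
                           invert_transform(transform))
  if (mode == "conserve_total") {
    total_out <- sum(vals)
    if (total_out <= 0)
      stop("empty source: the source signal fell entirely outside the target field",
           call. = FALSE)
    vals <- vals * (total_in / total_out)
  }
  scalar_volume(vals, target_grid, volume$quantity)
}

# Continuous (0-based) source array indices of the target voxel centres.
source_index_coords <- function(src_grid, target_grid, inv_transform) {
  sh <- target_grid$shape
  xs <- axis_coords(target_grid, 1)
  ys <- axis_coords(target_grid, 2)
  zs <- axis_coords(target_grid, 3)
  pts <- cbind(
    rep(xs, times = sh[2] * sh[3]),
    rep(rep(ys, each = sh[1]), times = sh[3]),
    rep(zs, each = sh[1] * sh[2])
  )
  pts <- apply_transform(inv_transform, pts)
  sweep(sweep(pts, 2, src_grid$origin_mm, "-"), 2, src_grid$spacing_mm, "/")
}

# Vectorized tri-linear interpolation; out-of-field corners contribute zero.
trilinear_sample <- function(src_values, src_grid, target_grid, inv_transform) {
  cidx <- source_index_coords(src_grid, target_grid, inv_transform)
  n <- src_grid$shape
  i0 <- floor(cidx)
  fr <- cidx - i0
  out <- numeric(nrow(cidx))
  str1 <- n[1]; str2 <- n[1] * n[2]
  for (corner in 0:7) {
    di <- corner %% 2L
    dj <- (corner %/% 2L) %% 2L
    dk <- corner %/% 4L
    ci <- i0[, 1] + di; cj <- i0[, 2] + dj; ck <- i0[, 3] + dk
    ok <- ci >= 0 & ci < n[1] & cj >= 0 & cj < n[2] & ck >= 0 & ck < n[3]
    if (!any(ok)) next
    w <- (if (di == 1L) fr[, 1] else 1 - fr[, 1]) *
         (if (dj == 1L) fr[, 2] else 1 - fr[, 2]) *
         (if (dk == 1L) fr[, 3] else 1 - fr[, 3])
    lin <- ci[ok] + cj[ok] * str1 + ck[ok] * str2 + 1
    out[ok] <- out[ok] + w[ok] * src_values[lin]
  }
  out
}

# Nearest-neighbour mask resampling (masks are categorical; interpolation
# would create fractional membership).
resample_mask <- function(mask, src_grid, target_grid,
                          transform = rigid_transform()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  if (is_identity_transform(transform) && same_grid(src_grid, target_grid))
    return(array(as.logical(mask), dim = target_grid$shape))
  cidx <- source_index_coords(src_grid, target_grid, invert_transform(transform))
  n <- src_grid$shape
  idx <- round(cidx)
  ok <- idx[, 1] >= 0 & idx[, 1] < n[1] &
        idx[, 2] >= 0 & idx[, 2] < n[2] &
        idx[, 3] >= 0 & idx[, 3] < n[3]
  out <- logical(nrow(idx))
  lin <- idx[ok, 1] + idx[ok, 2] * n[1] + idx[ok, 3] * n[1] * n[2] + 1
  out[ok] <- as.logical(mask)[lin]
  array(out, dim = target_grid$shape)
}
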