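#' Read and write scalar volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with an axis-aligned sform affine: the 3x3
#' part must be diagonal with positive entries (spacing), and the
#' translation column is the world position of the centre of the first
#' voxel. Oblique or sheared affines are rejected with an explicit error —
#' this package does not reorient images.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param quantity Quantity tag for the volume being read.
#' @return `read_volume()`: a [scalar_volume()].
#' @export
read_volume <- function(path, quantity = c("counts", "activity_GBq", "dose_Gy")) {
  quantity <- match.arg(quantity)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  grid <- grid_from_affine(aff, dim(img))
  vals <- as.array(img)
  if (any(vals < 0))
    stop(sprintf("negative voxel values are invalid for quantity '%s'", quantity),
         call. = FALSE)
  scalar_volume(vals, grid, quantity)
}

#' @rdname read_volume
#' @param volume A [scalar_volume()] (for `write_volume`).
#' @return `write_volume()`: the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  write_nifti_array(volume$values, volume$grid, path)
  invisible(path)
}

write_nifti_array <- function(arr, grid, path, datatype = "double") {
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing_mm
  aff[1:3, 4] <- grid$origin_mm
  img <- RNifti::asNifti(arr, pixdim = grid$spacing_mm, datatype = datatype)
  # sform only: RNifti re-derives pixdim from a qform assignment, which
  # destroys the spacing on write
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

grid_from_affine <- function(aff, shape) {
  rot <- aff[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  scale <- pmax(abs(diag(rot)), .Machine$double.eps)
  if (max(abs(offdiag)) > 1e-6 * max(scale))
    stop("oblique or sheared affine: only axis-aligned volumes are supported",
         call. = FALSE)
  if (any(diag(rot) <= 0))
    stop("affine with non-positive diagonal: flip the volume to a positive-diagonal orientation first",
         call. = FALSE)
  voxel_grid(shape, diag(rot), aff[1:3, 4])
}

#' Read and write compartment sets
#'
#' A compartment set is stored as one integer-labelled NIfTI volume plus a
#' JSON sidecar (`<stem>.labels.json`) mapping each role to its label.
#' Because roles overlap (e.g. `perfused_tumor` is inside both `perfused`
#' and `tumor`), each role is written as its own bit in a label bitmask.
#'
#' @param comp A [compartment_set()].
#' @param path Path to the `.nii`/`.nii.gz` label volume; the sidecar is
#'   written next to it.
#' @return `write_compartments()`: `path`, invisibly.
#' @export
write_compartments <- function(comp, path) {
  stopifnot(inherits(comp, "compartment_set"))
  roles <- names(comp$masks)
  lab <- array(0, dim = comp$grid$shape)
  for (i in seq_along(roles))
    lab <- lab + comp$masks[[roles[i]]] * 2^(i - 1)
  write_nifti_array(lab, comp$grid, path)
  sidecar <- sidecar_path(path)
  jsonlite::write_json(as.list(setNames(2^(seq_along(roles) - 1), roles)),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_compartments
#' @return `read_compartments()`: a [compartment_set()].
#' @export
read_compartments <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_affine(RNifti::xform(img), dim(img))
  labels <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  lab <- as.array(img)
  masks <- lapply(labels, function(bit) {
    array(bitwAnd(as.integer(round(lab)), as.integer(bit)) > 0,
          dim = grid$shape)
  })
  compartment_set(masks, grid)
}

sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, ".labels.json")
}
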