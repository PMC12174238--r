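#' Named compartment masks on a shared grid
#'
#' A `compartment_set` holds the binary segmentation masks used throughout
#' the dosimetry workflow, all on one [voxel_grid()]. Recognised roles are
#' `whole_liver`, `tumor`, `normal_liver`, `perfused`, `perfused_tumor`,
#' `perfused_normal` and `lungs`. Set identities are enforced when the roles
#' involved are present: `tumor` is a subset of `whole_liver`,
#' `normal_liver = whole_liver \ tumor`,
#' `perfused_tumor = perfused & tumor`, and
#' `perfused_normal = perfused & normal_liver`.
#'
#' @param masks Named list of logical arrays (or 0/1 arrays) with grid shape.
#' @param grid The shared [voxel_grid()].
#' @param check Validate the set identities (default `TRUE`).
#' @return An object of class `compartment_set`.
#' @export
compartment_set <- function(masks, grid, check = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks))
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all masks must be named by role", call. = FALSE)
  unknown <- setdiff(names(masks), COMPARTMENT_ROLES)
  if (length(unknown))
    stop("unrecognized roles: ", paste(unknown, collapse = ", "),
         "; recognized roles are: ", paste(COMPARTMENT_ROLES, collapse = ", "),
         call. = FALSE)
  masks <- lapply(masks, function(m) {
    if (length(m) != grid_n_voxels(grid))
      stop("mask does not match the grid shape", call. = FALSE)
    array(as.logical(m), dim = grid$shape)
  })
  x <- structure(list(masks = masks, grid = grid), class = "compartment_set")
  if (check) validate_compartments(x)
  x
}

COMPARTMENT_ROLES <- c("whole_liver", "tumor", "normal_liver", "perfused",
                       "perfused_tumor", "perfused_normal", "lungs")

validate_compartments <- function(comp) {
  m <- comp$masks
  has <- function(...) all(c(...) %in% names(m))
  if (has("tumor", "whole_liver") && any(m$tumor & !m$whole_liver))
    stop("set identity violated: tumor must be a subset of whole_liver",
         call. = FALSE)
  if (has("normal_liver", "whole_liver", "tumor") &&
      !identical(m$normal_liver, m$whole_liver & !m$tumor))
    stop("set identity violated: normal_liver must equal whole_liver \\ tumor",
         call. = FALSE)
  if (has("perfused_tumor", "perfused", "tumor") &&
      !identical(m$perfused_tumor, m$perfused & m$tumor))
    stop("set identity violated: perfused_tumor must equal perfused & tumor",
         call. = FALSE)
  if (has("perfused_normal", "perfused", "normal_liver") &&
      !identical(m$perfused_normal, m$perfused & m$normal_liver))
    stop("set identity violated: perfused_normal must equal perfused & normal_liver",
         call. = FALSE)
  invisible(comp)
}

get_mask <- function(comp, role, require_nonempty = TRUE) {
  stopifnot(inherits(comp, "compartment_set"))
  if (!role %in% names(comp$masks))
    stop(sprintf("unknown role '%s'; available roles: %s", role,
                 paste(names(comp$masks), collapse = ", ")), call. = FALSE)
  m <- comp$masks[[role]]
  if (require_nonempty && !any(m))
    stop(sprintf("compartment '%s' is empty", role), call. = FALSE)
  m
}

#' @export
print.compartment_set <- function(x, ...) {
  cat("<compartment_set>\n")
  print(x$grid)
  for (r in names(x$masks))
    cat(sprintf("  %-16s %8d voxels  %9.1f mL\n", r, sum(x$masks[[r]]),
                sum(x$masks[[r]]) * voxel_volume_mL(x$grid)))
  invisible(x)
}

#' Compartment volume in millilitres
#'
#' Voxel count of the role's mask times the voxel volume.
#'
#' @param comp A [compartment_set()].
#' @param role A role label present in `comp`.
#' @return Volume in mL.
#' @examples
#' g <- voxel_grid(c(10, 10, 10), c(1, 1, 1))
#' cs <- compartment_set(list(whole_liver = array(TRUE, c(10, 10, 10))), g)
#' compartment_volume_mL(cs, "whole_liver")  # 1.0 mL
#' @export
compartment_volume_mL <- function(comp, role) {
  m <- get_mask(comp, role, require_nonempty = FALSE)
  sum(m) * voxel_volume_mL(comp$grid)
}

#' Summarise compartment volumes as a tibble
#'
#' @param x A [compartment_set()].
#' @param ... Unused.
#' @return A tibble with columns `role`, `n_voxels`, `volume_mL`.
#' @method tidy compartment_set
#' @export
tidy.compartment_set <- function(x, ...) {
  tibble::tibble(
    role = names(x$masks),
    n_voxels = unname(vapply(x$masks, sum, integer(1))),
    volume_mL = unname(vapply(names(x$masks),
                              function(r) compartment_volume_mL(x, r),
                              numeric(1)))
  )
}

#' Resample a compartment set onto another grid
#'
#' Nearest-neighbour resampling of every mask under a rigid transform.
#' Derived roles are recomputed from the resampled primary masks where
#' possible so the set identities hold exactly on the new grid.
#'
#' @param comp A [compartment_set()].
#' @param target_grid Target [voxel_grid()].
#' @param transform A [rigid_transform()] (source world -> target world).
#' @return A [compartment_set()] on `target_grid`.
#' @export
resample_compartments <- function(comp, target_grid,
                                  transform = rigid_transform()) {
  stopifnot(inherits(comp, "compartment_set"))
  m <- lapply(comp$masks, resample_mask, src_grid = comp$grid,
              target_grid = target_grid, transform = transform)
  # re-derive dependent roles so identities survive nearest-neighbour rounding
  if (all(c("whole_liver", "tumor") %in% names(m)))
    m$tumor <- m$tumor & m$whole_liver
  if (all(c("whole_liver", "tumor", "normal_liver") %in% names(m)))
    m$normal_liver <- m$whole_liver & !m$tumor
  if (all(c("perfused", "tumor", "perfused_tumor") %in% names(m)))
    m$perfused_tumor <- m$perfused & m$tumor
  if (all(c("perfused", "normal_liver", "perfused_normal") %in% names(m)))
    m$perfused_normal <- m$perfused & m$normal_liver
  compartment_set(m, target_grid)
}
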