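#' Rigid (rotation + translation) world-space transform
#'
#' Represents the manual rigid registration that maps source world coordinates
#' (mm) to target world coordinates: `x' = R x + t`. The rotation must be a
#' proper orthogonal 3x3 matrix (orthonormal, determinant +1).
#'
#' @param rotation 3x3 proper orthogonal matrix. Default: identity.
#' @param translation_mm Numeric length-3 translation in mm. Default zero.
#' @return An object of class `rigid_transform`.
#' @seealso [rigid_transform_euler()] for the Euler-angle constructor used by
#'   run configurations.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation_mm <- as.numeric(translation_mm)
  stopifnot(length(translation_mm) == 3, all(is.finite(rotation)),
            all(is.finite(translation_mm)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthogonal (R'R != I within 1e-9)", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (det = +1 within 1e-9)", call. = FALSE)
  structure(list(rotation = rotation, translation_mm = translation_mm),
            class = "rigid_transform")
}

#' Rigid transform from Euler angles
#'
#' Angles are in degrees, applied in ZYX order (intrinsic yaw-pitch-roll):
#' `R = Rz(az) %*% Ry(ay) %*% Rx(ax)`. This is the convention used for
#' transform parameters in run configurations.
#'
#' @param angles_deg Numeric length-3: rotations about the x, y and z axes in
#'   degrees, composed as ZYX.
#' @param translation_mm Numeric length-3 translation in mm.
#' @return A [rigid_transform()].
#' @export
rigid_transform_euler <- function(angles_deg = c(0, 0, 0),
                                  translation_mm = c(0, 0, 0)) {
  a <- as.numeric(angles_deg) * pi / 180
  stopifnot(length(a) == 3, all(is.finite(a)))
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rigid_transform(rz %*% ry %*% rx, translation_mm)
}

#' @rdname rigid_transform
#' @param transform A `rigid_transform`.
#' @return `invert_transform()`: the inverse transform.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation_mm))
}

#' @rdname rigid_transform
#' @param points_mm An n x 3 matrix of world points (mm).
#' @return `apply_transform()`: the transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points_mm) {
  stopifnot(inherits(transform, "rigid_transform"))
  points_mm <- matrix(points_mm, ncol = 3)
  sweep(points_mm %*% t(transform$rotation), 2, transform$translation_mm, "+")
}

is_identity_transform <- function(transform, tol = 1e-12) {
  max(abs(transform$rotation - diag(3))) <= tol &&
    max(abs(transform$translation_mm)) <= tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", format(x$translation_mm), "\n")
  invisible(x)
}
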