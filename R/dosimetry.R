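#' Patient-relative activity calibration
#'
#' Converts a count volume to an activity volume by the patient-relative
#' method: voxel counts are scaled so that the total inside the field-of-view
#' mask equals the net administered activity (administered minus the residual
#' measured in vial and catheter). Voxels outside the field of view are set
#' to zero.
#'
#' @param counts A [scalar_volume()] of quantity `"counts"`.
#' @param net_activity_GBq Net administered activity in GBq (> 0).
#' @param fov_mask Logical array on the same grid marking the region whose
#'   counts represent the administered activity. Default: the whole volume.
#' @return A [scalar_volume()] of quantity `"activity_GBq"` whose total is
#'   exactly `net_activity_GBq`.
#' @examples
#' g <- voxel_grid(c(2, 1, 1), c(10, 10, 10))
#' cts <- scalar_volume(c(1, 3), g, "counts")
#' act <- calibrate_activity(cts, net_activity_GBq = 1)
#' as.vector(act$values)  # 0.25 0.75
#' @export
calibrate_activity <- function(counts, net_activity_GBq, fov_mask = NULL) {
  stopifnot(inherits(counts, "scalar_volume"), counts$quantity == "counts")
  if (!is.finite(net_activity_GBq) || net_activity_GBq <= 0)
    stop("`net_activity_GBq` must be a positive number", call. = FALSE)
  if (is.null(fov_mask)) fov_mask <- array(TRUE, dim = counts$grid$shape)
  fov_mask <- array(as.logical(fov_mask), dim = counts$grid$shape)
  total <- sum(counts$values[fov_mask])
  if (total <= 0)
    stop("cannot calibrate empty field", call. = FALSE)
  act <- counts$values * (net_activity_GBq / total)
  act[!fov_mask] <- 0
  scalar_volume(act, counts$grid, "activity_GBq")
}

#' Local deposition method dose map
#'
#' Converts a voxel activity map (GBq) to an absorbed dose map (Gy) assuming
#' each voxel's activity deposits its complete decay energy locally:
#' \deqn{D [\mathrm{Gy}] = 49.67\,[\mathrm{J/GBq}] \times A [\mathrm{GBq}] / m [\mathrm{kg}]}
#' with the voxel mass \eqn{m = \rho \times V_{voxel}}. 49.67 J/GBq is the
#' energy released per GBq of Y-90 integrated over complete decay; half-life
#' and spectrum are therefore not needed.
#'
#' @param activity A [scalar_volume()] of quantity `"activity_GBq"`.
#' @param density_g_per_mL Tissue density in g/mL (> 0). Default 1.03
#'   (soft tissue / liver).
#' @return A [scalar_volume()] of quantity `"dose_Gy"`.
#' @export
ldm_dose <- function(activity, density_g_per_mL = 1.03) {
  stopifnot(inherits(activity, "scalar_volume"),
            activity$quantity == "activity_GBq")
  if (!is.finite(density_g_per_mL) || density_g_per_mL <= 0)
    stop("`density_g_per_mL` must be positive", call. = FALSE)
  v_mL <- voxel_volume_mL(activity$grid)
  if (v_mL <= 0) stop("non-positive voxel volume", call. = FALSE)
  mass_kg <- density_g_per_mL * v_mL / 1000
  scalar_volume(Y90_J_PER_GBQ * activity$values / mass_kg,
                activity$grid, "dose_Gy")
}

#' Mean absorbed dose in a compartment
#'
#' Arithmetic mean of the voxel doses inside the role's mask. With equal
#' voxel masses the arithmetic mean equals the mass-weighted mean.
#'
#' @param dose A [scalar_volume()] of quantity `"dose_Gy"`.
#' @param comp A [compartment_set()] on the same grid.
#' @param role Role label.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, comp, role) {
  stopifnot(inherits(dose, "scalar_volume"), dose$quantity == "dose_Gy")
  check_same_grid(dose, comp)
  mean(dose$values[get_mask(comp, role)])
}

#' Tumour-to-normal dose ratio
#'
#' Mean tumour dose divided by the mean dose in perfused normal tissue. The
#' numerator defaults to the treated (`perfused_tumor`) compartment; pass
#' `tumor_role = "tumor"` to use the whole tumour instead.
#'
#' @inheritParams mean_dose
#' @param tumor_role Numerator role, `"perfused_tumor"` (default) or
#'   `"tumor"`.
#' @param normal_role Denominator role, default `"perfused_normal"`.
#' @return The T/N ratio (dimensionless).
#' @export
tn_ratio <- function(dose, comp, tumor_role = "perfused_tumor",
                     normal_role = "perfused_normal") {
  num <- mean_dose(dose, comp, tumor_role)
  den <- mean_dose(dose, comp, normal_role)
  if (den <= 0) stop("undefined T/N: perfused-normal mean dose is zero",
                     call. = FALSE)
  num / den
}

#' Cumulative dose-volume histogram
#'
#' The exact empirical survival function of the voxel doses in a compartment:
#' for each dose level `d` on a uniform grid from 0 to the maximum voxel
#' dose, the percentage of the compartment volume receiving at least `d`.
#' By construction the curve starts at 100% and is non-increasing.
#'
#' @inheritParams mean_dose
#' @param n_bins Number of dose levels on the uniform grid (>= 2). Default
#'   1000 (export resolution; D-metrics never use the binned curve, see
#'   [d_metric()]).
#' @return A tibble with columns `dose_Gy` and `volume_pct`.
#' @export
dvh <- function(dose, comp, role, n_bins = 1000) {
  stopifnot(inherits(dose, "scalar_volume"), dose$quantity == "dose_Gy")
  check_same_grid(dose, comp)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  d <- sort(dose$values[get_mask(comp, role)])
  n <- length(d)
  levels <- seq(0, max(d), length.out = n_bins)
  # voxels >= t  =  n - #{voxels < t}; exact under ties
  at_least <- n - findInterval(levels, d, left.open = TRUE)
  tibble::tibble(dose_Gy = levels, volume_pct = 100 * at_least / n)
}

#' D and V metrics from exact order statistics
#'
#' `d_metric()` returns \eqn{D_x}: with the voxel doses sorted in descending
#' order \eqn{d_{(1)} \ge \dots \ge d_{(n)}},
#' \eqn{D_x = d_{(\lceil x n / 100 \rceil)}} — the largest dose such that at
#' least x% of the compartment receives at least that dose (so D100 is the
#' minimum voxel dose). No interpolation between voxels is applied.
#' `v_metric()` returns \eqn{V_d}: the percentage of the compartment volume
#' receiving at least `dose_Gy_threshold`.
#'
#' @inheritParams mean_dose
#' @param x Percentage in (0, 100]; may be a vector.
#' @return `d_metric()`: dose(s) in Gy, named `D<x>`.
#' @examples
#' g <- voxel_grid(c(10, 1, 1), c(1, 1, 1))
#' d <- scalar_volume(seq(10, 100, by = 10), g, "dose_Gy")
#' cs <- compartment_set(list(tumor = array(TRUE, c(10, 1, 1)),
#'                            whole_liver = array(TRUE, c(10, 1, 1))), g)
#' d_metric(d, cs, "tumor", c(10, 50, 90))  # 100 60 20
#' @export
d_metric <- function(dose, comp, role, x) {
  stopifnot(inherits(dose, "scalar_volume"), dose$quantity == "dose_Gy")
  check_same_grid(dose, comp)
  if (any(x <= 0 | x > 100)) stop("`x` must be in (0, 100]", call. = FALSE)
  d <- sort(dose$values[get_mask(comp, role)], decreasing = TRUE)
  n <- length(d)
  out <- d[pmin(n, ceiling(x * n / 100))]
  names(out) <- paste0("D", format(x, trim = TRUE))
  out
}

#' @rdname d_metric
#' @param dose_Gy_threshold Dose threshold(s) in Gy (>= 0).
#' @return `v_metric()`: percentage(s) of volume, named `V<threshold>`.
#' @export
v_metric <- function(dose, comp, role, dose_Gy_threshold) {
  stopifnot(inherits(dose, "scalar_volume"), dose$quantity == "dose_Gy")
  check_same_grid(dose, comp)
  if (any(dose_Gy_threshold < 0)) stop("thresholds must be >= 0", call. = FALSE)
  d <- dose$values[get_mask(comp, role)]
  out <- vapply(dose_Gy_threshold, function(t) 100 * mean(d >= t), numeric(1))
  names(out) <- paste0("V", format(dose_Gy_threshold, trim = TRUE))
  out
}

#' Lung shunt fraction from planar scintigraphy
#'
#' The geometric-mean method: for each organ ROI the geometric mean of the
#' anterior and posterior total counts is taken,
#' \eqn{GM = \sqrt{C_{ant} \times C_{post}}}, and the lung shunt fraction is
#' \eqn{LSF = GM_{lung} / (GM_{lung} + GM_{liver})}.
#'
#' @param anterior,posterior Numeric 2-D count matrices (same dimensions).
#' @param lung_roi,liver_roi Logical matrices marking the organ ROIs.
#' @return An object of class `lung_shunt_result` with fields `lsf`,
#'   `gm_lung` and `gm_liver`.
#' @examples
#' a <- matrix(c(100, 900), 2, 1)  # lung pixel, liver pixel
#' lsf <- lung_shunt_fraction(a, a, lung_roi = matrix(c(TRUE, FALSE), 2, 1),
#'                            liver_roi = matrix(c(FALSE, TRUE), 2, 1))
#' lsf$lsf  # 0.1
#' @export
lung_shunt_fraction <- function(anterior, posterior, lung_roi, liver_roi) {
  stopifnot(is.matrix(anterior), is.matrix(posterior),
            all(dim(anterior) == dim(posterior)))
  lung_roi <- matrix(as.logical(lung_roi), nrow(anterior), ncol(anterior))
  liver_roi <- matrix(as.logical(liver_roi), nrow(anterior), ncol(anterior))
  # sums coerced to double: integer count images overflow the product
  ant_liver <- sum(as.numeric(anterior[liver_roi]))
  post_liver <- sum(as.numeric(posterior[liver_roi]))
  if (ant_liver <= 0 || post_liver <= 0)
    stop("liver ROI counts must be positive on both views", call. = FALSE)
  gm_lung <- sqrt(sum(as.numeric(anterior[lung_roi])) *
                    sum(as.numeric(posterior[lung_roi])))
  gm_liver <- sqrt(ant_liver * post_liver)
  structure(list(lsf = gm_lung / (gm_lung + gm_liver),
                 gm_lung = gm_lung, gm_liver = gm_liver),
            class = "lung_shunt_result")
}

#' @export
print.lung_shunt_result <- function(x, ...) {
  cat(sprintf("<lung_shunt_result> LSF = %.4f (GM lung %.4g, GM liver %.4g)\n",
              x$lsf, x$gm_lung, x$gm_liver))
  invisible(x)
}

#' Mean lung dose from the shunted activity
#'
#' Single-compartment local-deposition dose to the lungs: the shunted
#' fraction of the net administered activity deposits its complete decay
#' energy in the lung mass,
#' \eqn{D_{lung} = 49.67 \times A_{net} \times LSF / m_{lung}}.
#'
#' @param net_activity_GBq Net administered activity (GBq).
#' @param lsf Lung shunt fraction in [0, 1].
#' @param lung_mass_kg Lung mass in kg (> 0). Default 1.0.
#' @return Mean lung dose in Gy.
#' @export
lung_dose <- function(net_activity_GBq, lsf, lung_mass_kg = 1.0) {
  stopifnot(is.finite(net_activity_GBq), net_activity_GBq >= 0,
            is.finite(lsf), lsf >= 0, lsf <= 1)
  if (!is.finite(lung_mass_kg) || lung_mass_kg <= 0)
    stop("`lung_mass_kg` must be positive", call. = FALSE)
  Y90_J_PER_GBQ * net_activity_GBq * lsf / lung_mass_kg
}

check_same_grid <- function(dose, comp) {
  if (!same_grid(dose$grid, comp$grid))
    stop("dose map and compartments are on different grids; resample first",
         call. = FALSE)
  invisible(TRUE)
}

#' Per-compartment dose report
#'
#' Computes, for each requested role, the volume, mean dose, D-metrics and
#' (optionally) V-metrics plus the cumulative DVH, together with the T/N
#' ratio. This is the per-modality summary used for the pre/post agreement
#' comparison.
#'
#' @inheritParams mean_dose
#' @param roles Roles to report. Default: every non-empty role except lungs.
#' @param d_percents D-metric percentages. Default `c(10, 50, 90)`.
#' @param v_thresholds_Gy Optional V-metric dose thresholds (Gy).
#' @param n_bins DVH export resolution (see [dvh()]).
#' @param modality Free-text label (e.g. `"spect"`, `"pet"`).
#' @param tn_tumor_role Numerator role for the T/N ratio (see [tn_ratio()]).
#' @return An object of class `dose_report`; see [tidy.dose_report()].
#' @export
dose_report <- function(dose, comp, roles = NULL, d_percents = c(10, 50, 90),
                        v_thresholds_Gy = NULL, n_bins = 1000,
                        modality = "unspecified",
                        tn_tumor_role = "perfused_tumor") {
  stopifnot(inherits(dose, "scalar_volume"), dose$quantity == "dose_Gy")
  check_same_grid(dose, comp)
  if (is.null(roles)) {
    roles <- setdiff(names(comp$masks), "lungs")
    roles <- roles[vapply(roles, function(r) any(comp$masks[[r]]), logical(1))]
  }
  rows <- purrr::map(roles, function(r) {
    dm <- d_metric(dose, comp, r, d_percents)
    row <- tibble::tibble(
      modality = modality, role = r,
      volume_mL = compartment_volume_mL(comp, r),
      mean_dose_Gy = mean_dose(dose, comp, r)
    )
    row[names(dm)] <- as.list(unname(dm))
    if (!is.null(v_thresholds_Gy)) {
      vm <- v_metric(dose, comp, r, v_thresholds_Gy)
      row[names(vm)] <- as.list(unname(vm))
    }
    row
  })
  metrics <- dplyr::bind_rows(rows)
  dvhs <- purrr::map(roles, function(r)
    dplyr::mutate(dvh(dose, comp, r, n_bins), role = r, modality = modality,
                  .before = 1))
  tn <- tryCatch(tn_ratio(dose, comp, tumor_role = tn_tumor_role),
                 error = function(e) NA_real_)
  structure(list(metrics = metrics, dvh = dplyr::bind_rows(dvhs),
                 tn_ratio = tn, modality = modality),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report: %s> T/N = %s\n", x$modality,
              ifelse(is.na(x$tn_ratio), "NA", sprintf("%.3f", x$tn_ratio))))
  print(x$metrics)
  invisible(x)
}

#' Tidy a dose report
#'
#' @param x A [dose_report()].
#' @param ... Unused.
#' @return `tidy()`: the per-role metrics tibble. `glance()`: a one-row
#'   tibble with the modality, T/N ratio and number of roles.
#' @method tidy dose_report
#' @export
tidy.dose_report <- function(x, ...) x$metrics

#' @rdname tidy.dose_report
#' @method glance dose_report
#' @export
glance.dose_report <- function(x, ...) {
  tibble::tibble(modality = x$modality, tn_ratio = x$tn_ratio,
                 n_roles = nrow(x$metrics))
}
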