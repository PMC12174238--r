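#' Treatment-planning constraints for glass and resin microspheres
#'
#' Encodes the multicompartment planning targets and limits: for glass
#' microspheres a minimum tumour dose of 250 Gy (HCC) or 200 Gy
#' (metastasis) with the whole-liver normal-tissue dose limited to a
#' configurable ceiling in the 50-90 Gy window (default 90 Gy); for resin
#' microspheres a minimum tumour dose of 100 Gy with the perfused
#' normal-tissue dose limited to 40 Gy. Lungs are limited to 30 Gy per
#' treatment and 50 Gy cumulatively.
#'
#' @param device `"glass"` or `"resin"`.
#' @param disease `"HCC"` or `"metastasis"` (selects the glass tumour
#'   target; resin uses 100 Gy for both).
#' @param tumor_target_Gy Override the tumour dose target (Gy).
#' @param normal_limit_Gy Override the normal-tissue limit (Gy). For glass
#'   the value must lie in the 50-90 Gy window.
#' @param lung_limit_Gy Per-treatment lung limit (Gy). Default 30.
#' @param lung_cumulative_limit_Gy Cumulative lung limit (Gy). Default 50.
#' @param prior_lung_dose_Gy Lung dose already received (Gy, >= 0).
#' @return An object of class `plan_constraints`. The constrained normal
#'   role is part of the object: `normal_liver` (whole-liver normal tissue)
#'   for glass, `perfused_normal` for resin.
#' @export
plan_constraints <- function(device = c("glass", "resin"),
                             disease = c("metastasis", "HCC"),
                             tumor_target_Gy = NULL,
                             normal_limit_Gy = NULL,
                             lung_limit_Gy = 30,
                             lung_cumulative_limit_Gy = 50,
                             prior_lung_dose_Gy = 0) {
  device <- match.arg(device)
  disease <- match.arg(disease)
  if (is.null(tumor_target_Gy))
    tumor_target_Gy <- if (device == "glass") {
      if (disease == "HCC") 250 else 200
    } else 100
  if (is.null(normal_limit_Gy))
    normal_limit_Gy <- if (device == "glass") 90 else 40
  if (device == "glass" && (normal_limit_Gy < 50 || normal_limit_Gy > 90))
    stop("glass whole-liver normal limit must lie in the 50-90 Gy window",
         call. = FALSE)
  stopifnot(tumor_target_Gy > 0, normal_limit_Gy > 0, lung_limit_Gy > 0,
            lung_cumulative_limit_Gy > 0, prior_lung_dose_Gy >= 0)
  structure(list(
    device = device, disease = disease,
    tumor_target_Gy = tumor_target_Gy,
    normal_limit_Gy = normal_limit_Gy,
    normal_role = if (device == "glass") "normal_liver" else "perfused_normal",
    lung_limit_Gy = lung_limit_Gy,
    lung_cumulative_limit_Gy = lung_cumulative_limit_Gy,
    prior_lung_dose_Gy = prior_lung_dose_Gy
  ), class = "plan_constraints")
}

#' Predicted dose per unit administered activity
#'
#' Calibrates the predictive (pre-treatment) count volume to 1 GBq, runs the
#' local-deposition dose conversion, and returns the mean dose per role in
#' Gy per GBq. Because the calibration is patient-relative these scale
#' factors are invariant to any global rescaling of the counts.
#'
#' @param predictive_counts A [scalar_volume()] of quantity `"counts"`.
#' @param comp A [compartment_set()] on the same grid.
#' @param density_g_per_mL Tissue density (g/mL). Default 1.03.
#' @param roles Roles to evaluate. Default: all non-empty, lungs excluded.
#' @param fov_mask Optional field-of-view mask for the calibration.
#' @return Named numeric vector, Gy per GBq by role.
#' @export
dose_per_GBq <- function(predictive_counts, comp, density_g_per_mL = 1.03,
                         roles = NULL, fov_mask = NULL) {
  act <- calibrate_activity(predictive_counts, 1, fov_mask)
  dose <- ldm_dose(act, density_g_per_mL)
  if (is.null(roles)) {
    roles <- setdiff(names(comp$masks), "lungs")
    roles <- roles[vapply(roles, function(r) any(comp$masks[[r]]), logical(1))]
  }
  vapply(roles, function(r) mean_dose(dose, comp, r), numeric(1))
}

#' Prescribe the administered activity under multicompartment constraints
#'
#' Finds the administered activity that reaches the tumour dose target if
#' possible while respecting the normal-tissue and lung limits. All
#' predicted doses are linear in the administered activity, so the
#' prescription reduces to
#' `prescribed = min(target / s_tumor, normal_limit / s_normal, A_lung)`
#' where `A_lung` is the activity at which the lung dose reaches its
#' headroom `min(lung_limit, lung_cumulative_limit - prior_lung_dose)`.
#' When the target is unreachable within the limits the plan prescribes the
#' limiting activity and flags `tumor_target_met = FALSE` (the target is
#' pursued "if possible", not at the expense of the limits). A shunt of
#' zero removes the lung bound; exhausted cumulative lung headroom makes
#' the plan infeasible.
#'
#' @param s Named numeric vector of predicted mean doses in Gy per GBq (from
#'   [dose_per_GBq()]); must contain `tumor_role` and the constrained normal
#'   role of `constraints`.
#' @param constraints A [plan_constraints()].
#' @param lsf Lung shunt fraction in [0, 1). Default 0.
#' @param lung_mass_kg Lung mass (kg). Default 1.0.
#' @param tumor_role Role used for the tumour target. Default
#'   `"perfused_tumor"`; falls back to `"tumor"` if absent from `s`.
#' @return An object of class `plan_result`; see [tidy.plan_result()].
#' @export
prescribe <- function(s, constraints, lsf = 0, lung_mass_kg = 1.0,
                      tumor_role = "perfused_tumor") {
  stopifnot(inherits(constraints, "plan_constraints"),
            is.numeric(s), !is.null(names(s)),
            lsf >= 0, lsf < 1, lung_mass_kg > 0)
  if (!tumor_role %in% names(s) && tumor_role == "perfused_tumor" &&
      "tumor" %in% names(s))
    tumor_role <- "tumor"
  normal_role <- constraints$normal_role
  for (r in c(tumor_role, normal_role))
    if (!r %in% names(s))
      stop(sprintf("`s` is missing role '%s'", r), call. = FALSE)
  if (s[[tumor_role]] <= 0 || s[[normal_role]] <= 0)
    stop("dose-per-GBq scale factors must be positive for the tumor and the constrained normal role",
         call. = FALSE)

  lung_headroom <- min(constraints$lung_limit_Gy,
                       constraints$lung_cumulative_limit_Gy -
                         constraints$prior_lung_dose_Gy)
  if (lung_headroom <= 0) {
    return(structure(list(
      prescribed_GBq = 0, predicted_doses_Gy = 0 * s,
      binding_constraint = "lung", tumor_target_met = FALSE,
      lung_dose_Gy = 0, feasible = FALSE,
      reason = "cumulative lung limit exhausted",
      constraints = constraints, lsf = lsf, lung_mass_kg = lung_mass_kg,
      tumor_role = tumor_role, warnings = character()
    ), class = "plan_result"))
  }

  a_target <- constraints$tumor_target_Gy / s[[tumor_role]]
  a_normal <- constraints$normal_limit_Gy / s[[normal_role]]
  lung_slope <- Y90_J_PER_GBQ * lsf / lung_mass_kg  # Gy per GBq to the lungs
  a_lung <- if (lung_slope > 0) lung_headroom / lung_slope else Inf
  a_limit <- min(a_normal, a_lung)
  prescribed <- min(a_target, a_limit)

  # fixed tie-break priority: tumor_target, normal_tissue, lung
  tol <- 1e-12
  binding <- if (prescribed >= a_target - tol) "tumor_target"
  else if (prescribed >= a_normal - tol) "normal_tissue"
  else "lung"

  warnings <- character()
  predicted <- s * prescribed
  if (constraints$device == "glass" && predicted[[normal_role]] > 50)
    warnings <- c(warnings, sprintf(
      "predicted whole-liver normal dose %.1f Gy exceeds 50 Gy (within the 50-90 Gy window)",
      predicted[[normal_role]]))

  structure(list(
    prescribed_GBq = unname(prescribed),
    predicted_doses_Gy = predicted,
    binding_constraint = binding,
    tumor_target_met = prescribed >= a_target - 1e-12,
    lung_dose_Gy = unname(lung_slope * prescribed),
    feasible = prescribed > 0,
    reason = NULL,
    constraints = constraints, lsf = lsf, lung_mass_kg = lung_mass_kg,
    tumor_role = tumor_role, warnings = warnings
  ), class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<plan_result> INFEASIBLE: %s\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "<plan_result> %s/%s: prescribe %.3f GBq (binding: %s; tumor target %s)\n",
    x$constraints$device, x$constraints$disease, x$prescribed_GBq,
    x$binding_constraint, ifelse(x$tumor_target_met, "met", "NOT met")))
  cat(sprintf("  lung dose %.2f Gy (LSF %.3f)\n", x$lung_dose_Gy, x$lsf))
  for (r in names(x$predicted_doses_Gy))
    cat(sprintf("  %-16s %8.1f Gy\n", r, x$predicted_doses_Gy[[r]]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy a plan result
#'
#' @param x A [prescribe()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per role with the predicted dose at the
#'   prescribed activity. `glance()`: a one-row plan summary.
#' @method tidy plan_result
#' @export
tidy.plan_result <- function(x, ...) {
  tibble::tibble(role = names(x$predicted_doses_Gy),
                 predicted_dose_Gy = unname(x$predicted_doses_Gy),
                 prescribed_GBq = x$prescribed_GBq)
}

#' @rdname tidy.plan_result
#' @method glance plan_result
#' @export
glance.plan_result <- function(x, ...) {
  tibble::tibble(
    device = x$constraints$device, disease = x$constraints$disease,
    prescribed_GBq = x$prescribed_GBq,
    binding_constraint = x$binding_constraint,
    tumor_target_met = x$tumor_target_met,
    lung_dose_Gy = x$lung_dose_Gy, feasible = x$feasible
  )
}
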