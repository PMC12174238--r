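# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a digital liver phantom
#'
#' Describes an ellipsoidal liver with one or more spherical tumours, a
#' perfused (treated) sub-volume split off by a sagittal plane, a true
#' tumour-to-normal activity concentration ratio, a known lung shunt
#' fraction, and the net administered activity. Defaults reproduce the
#' typical anatomy and activities of a unilobar Y-90 treatment: a ~1700 mL
#' liver, a ~113 mL tumour, a perfused fraction of 0.62 (right lobe), and a
#' net activity of 2.35 GBq of glass microspheres.
#'
#' @param liver_semiaxes_mm Ellipsoid semi-axes (mm).
#' @param tumor_centers_mm Matrix (or length-3 vector) of tumour centres (mm),
#'   one row per tumour, in the liver-centred frame.
#' @param tumor_radii_mm Tumour radii (mm), one per centre.
#' @param true_TN True tumour:normal activity concentration ratio (>= 0).
#' @param perfused_fraction Fraction of the liver that is perfused, in
#'   (0, 1]; the split is a sagittal plane.
#' @param net_activity_GBq Net administered activity (GBq, > 0).
#' @param lung_shunt_true True lung shunt fraction in [0, 1).
#' @param device `"glass"` or `"resin"`.
#' @param spacing_mm Truth-grid voxel spacing (mm). Default 2.5 mm isotropic.
#' @param heterogeneity_sdlog Standard deviation (log scale) of optional
#'   log-normal voxel-wise activity multipliers with unit mean; 0 (default)
#'   gives piecewise-uniform activity.
#' @param seed Integer seed controlling the heterogeneity draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(liver_semiaxes_mm = c(105, 70, 55),
                         tumor_centers_mm = c(55, 10, 10),
                         tumor_radii_mm = 30,
                         true_TN = 2.32,
                         perfused_fraction = 0.62,
                         net_activity_GBq = 2.35,
                         lung_shunt_true = 0.05,
                         device = c("glass", "resin"),
                         spacing_mm = c(2.5, 2.5, 2.5),
                         heterogeneity_sdlog = 0,
                         seed = 1L) {
  device <- match.arg(device)
  centers <- matrix(as.numeric(tumor_centers_mm), ncol = 3, byrow = FALSE)
  if (is.vector(tumor_centers_mm) && length(tumor_centers_mm) == 3)
    centers <- matrix(as.numeric(tumor_centers_mm), 1, 3)
  radii <- as.numeric(tumor_radii_mm)
  stopifnot(length(liver_semiaxes_mm) == 3, all(liver_semiaxes_mm > 0),
            nrow(centers) == length(radii), all(radii > 0),
            is.finite(true_TN), true_TN >= 0,
            perfused_fraction > 0, perfused_fraction <= 1,
            net_activity_GBq > 0,
            lung_shunt_true >= 0, lung_shunt_true < 1,
            heterogeneity_sdlog >= 0)
  # conservative containment check: tumour sphere must fit inside the ellipsoid
  semi <- as.numeric(liver_semiaxes_mm)
  for (i in seq_len(nrow(centers))) {
    shrunk <- pmax(semi - radii[i], 1e-9)
    if (sum((centers[i, ] / shrunk)^2) > 1)
      stop("tumor ", i, " is outside the liver ellipsoid", call. = FALSE)
  }
  structure(list(
    liver_semiaxes_mm = semi, tumor_centers_mm = centers,
    tumor_radii_mm = radii, true_TN = true_TN,
    perfused_fraction = perfused_fraction,
    net_activity_GBq = net_activity_GBq,
    lung_shunt_true = lung_shunt_true, device = device,
    spacing_mm = as.numeric(spacing_mm),
    heterogeneity_sdlog = heterogeneity_sdlog, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Build a phantom with known ground truth
#'
#' Voxelizes the [phantom_spec()] onto its truth grid: compartment masks
#' (whole liver, tumour, normal liver, perfused and its intersections, and a
#' lung slab superior to the liver), plus a noise-free activity map that is
#' uniform within perfused normal tissue and uniform within perfused tumour
#' with concentration ratio `true_TN`, zero outside the perfused region. The
#' activity total equals `net_activity_GBq * (1 - lung_shunt_true)` (the
#' hepatic fraction; the shunted fraction lives in the lungs and appears only
#' in planar simulations). Ground-truth dosimetry metrics are computed on the
#' noise-free map and stored for parameter-recovery testing.
#'
#' @param spec A [phantom_spec()].
#' @param density_g_per_mL Tissue density used for the truth dose map.
#' @return An object of class `phantom_truth` with elements `spec`,
#'   `activity` (a [scalar_volume()]), `compartments` (a
#'   [compartment_set()]), and `truth` (list: `metrics` tibble, `tn_ratio`,
#'   `lsf`, `liver_activity_GBq`).
#' @export
make_phantom <- function(spec, density_g_per_mL = 1.03) {
  stopifnot(inherits(spec, "phantom_spec"))
  semi <- spec$liver_semiaxes_mm
  margin <- 8
  lung_gap <- 12; lung_height <- 60
  lower <- c(-semi[1] - margin, -semi[2] - margin, -semi[3] - margin)
  upper <- c(semi[1] + margin, semi[2] + margin,
             semi[3] + lung_gap + lung_height + margin)
  grid <- grid_covering(lower, upper, spec$spacing_mm)

  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  sh <- grid$shape
  X <- array(rep(xs, times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(ys, each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(zs, each = sh[1] * sh[2]), dim = sh)

  liver <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  tumor <- array(FALSE, sh)
  for (i in seq_along(spec$tumor_radii_mm)) {
    ctr <- spec$tumor_centers_mm[i, ]
    tumor <- tumor | ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
                        spec$tumor_radii_mm[i]^2)
  }
  if (any(tumor & !liver))
    stop("tumor outside the liver after voxelization", call. = FALSE)

  # sagittal split: the perfused lobe is the high-x side of the liver
  if (spec$perfused_fraction >= 1) {
    perfused <- liver
  } else {
    xl <- X[liver]
    thr <- stats::quantile(xl, 1 - spec$perfused_fraction, type = 1,
                           names = FALSE)
    perfused <- liver & (X >= thr)
  }
  if (!any(perfused)) stop("perfused region is empty", call. = FALSE)

  lungs <- (Z >= semi[3] + lung_gap) &
    (Z < semi[3] + lung_gap + lung_height) &
    ((X / (0.85 * semi[1]))^2 + (Y / (0.9 * semi[2]))^2 <= 1)

  comp <- compartment_set(list(
    whole_liver = liver, tumor = tumor, normal_liver = liver & !tumor,
    perfused = perfused, perfused_tumor = perfused & tumor,
    perfused_normal = perfused & liver & !tumor, lungs = lungs
  ), grid)
  if (!any(comp$masks$perfused_tumor))
    stop("no tumor lies inside the perfused region", call. = FALSE)
  if (!any(comp$masks$perfused_normal))
    stop("no normal tissue lies inside the perfused region", call. = FALSE)

  liver_activity <- spec$net_activity_GBq * (1 - spec$lung_shunt_true)
  n_pt <- sum(comp$masks$perfused_tumor)
  n_pn <- sum(comp$masks$perfused_normal)
  a_pn <- liver_activity / (n_pn + spec$true_TN * n_pt)
  act <- array(0, sh)
  act[comp$masks$perfused_normal] <- a_pn
  act[comp$masks$perfused_tumor] <- spec$true_TN * a_pn
  if (spec$heterogeneity_sdlog > 0) {
    mult <- with_seed(spec$seed, {
      s <- spec$heterogeneity_sdlog
      stats::rlnorm(sum(perfused), meanlog = -s^2 / 2, sdlog = s)
    })
    act[perfused] <- act[perfused] * mult
    act <- act * (liver_activity / sum(act))  # keep the total invariant exact
  }
  activity <- scalar_volume(act, grid, "activity_GBq")

  truth_dose <- ldm_dose(activity, density_g_per_mL)
  report <- dose_report(truth_dose, comp, modality = "truth")
  structure(list(
    spec = spec, activity = activity, compartments = comp,
    truth = list(metrics = report$metrics, dvh = report$dvh,
                 tn_ratio = report$tn_ratio, lsf = spec$lung_shunt_true,
                 liver_activity_GBq = liver_activity,
                 density_g_per_mL = density_g_per_mL)
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> device %s, net %.3g GBq, true T/N %.3g, LSF %.3g\n",
    x$spec$device, x$spec$net_activity_GBq, x$spec$true_TN, x$truth$lsf))
  print(x$compartments)
  invisible(x)
}

# Gaussian blur with a per-axis column-normalized discrete kernel: every
# source voxel redistributes exactly its own content, so the array total is
# conserved even at the field edges.
gaussian_blur_conserve <- function(values, spacing_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sigma <- sigma_mm / spacing_mm[axis]
    if (sigma < 1e-6) next
    n <- dim(values)[axis]
    r <- min(n - 1L, max(1L, as.integer(ceiling(4 * sigma))))
    offs <- -r:r
    k <- dnorm(offs, sd = sigma)
    M <- matrix(0, n, n)
    for (o in seq_along(offs)) {
      i <- seq_len(n) + offs[o]
      ok <- i >= 1 & i <= n
      M[cbind(i[ok], seq_len(n)[ok])] <- k[o]
    }
    M <- sweep(M, 2, colSums(M), "/")
    values <- apply_along_axis(values, axis, M)
  }
  values
}

# Multiply a matrix M (n_axis x n_axis) along one axis of a 3-D array.
apply_along_axis <- function(arr, axis, M) {
  d <- dim(arr)
  if (axis == 1) {
    array(M %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  } else if (axis == 2) {
    p <- aperm(arr, c(2, 1, 3))
    p <- array(M %*% matrix(p, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    aperm(p, c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    p <- array(M %*% matrix(p, d[3], d[1] * d[2]), dim = c(d[3], d[1], d[2]))
    aperm(p, c(2, 3, 1))
  }
}

#' Simulate a tomographic acquisition of a phantom
#'
#' Emulates SPECT- or PET-like imaging of the phantom's hepatic activity:
#' the truth activity is resampled (count-conserving) onto the scanner grid,
#' convolved with an isotropic Gaussian point-spread function (kernel
#' renormalized at the edges so the total is conserved), scaled to expected
#' counts, and optionally Poisson-sampled.
#'
#' @param truth A [make_phantom()] result.
#' @param grid Scanner [voxel_grid()]; see [spect_grid()] / [pet_grid()].
#' @param psf_fwhm_mm Isotropic PSF full width at half maximum (mm, >= 0).
#' @param noise `"none"` or `"poisson"`.
#' @param counts_per_GBq Expected counts per GBq of activity (> 0).
#' @param seed Integer seed for the Poisson draw (required for
#'   reproducibility when `noise = "poisson"`).
#' @return A [scalar_volume()] of quantity `"counts"` on `grid`.
#' @export
simulate_modality <- function(truth, grid, psf_fwhm_mm,
                              noise = c("none", "poisson"),
                              counts_per_GBq = 1e6, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "phantom_truth"), inherits(grid, "voxel_grid"))
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be >= 0", call. = FALSE)
  if (!is.finite(counts_per_GBq) || counts_per_GBq <= 0)
    stop("`counts_per_GBq` must be positive", call. = FALSE)
  act <- resample(truth$activity, grid, mode = "conserve_total")
  vals <- gaussian_blur_conserve(act$values, grid$spacing_mm, psf_fwhm_mm)
  expected <- counts_per_GBq * vals
  if (noise == "poisson")
    expected <- with_seed(seed, array(rpois(length(expected), expected),
                                      dim = dim(expected)))
  scalar_volume(expected, grid, "counts")
}

#' Scanner grids with the standard voxel sizes
#'
#' Convenience constructors for the acquisition grids used by the
#' simulators: SPECT-like 4.42 x 4.42 x 2.50 mm voxels, PET-like
#' 2.34 x 2.34 x 2.78 mm voxels, covering the phantom's field of view.
#'
#' @param truth A [make_phantom()] result (defines the field of view).
#' @return A [voxel_grid()].
#' @export
spect_grid <- function(truth) scanner_grid(truth, c(4.42, 4.42, 2.50))

#' @rdname spect_grid
#' @export
pet_grid <- function(truth) scanner_grid(truth, c(2.34, 2.34, 2.78))

scanner_grid <- function(truth, spacing_mm) {
  g <- truth$activity$grid
  lower <- g$origin_mm - g$spacing_mm
  upper <- g$origin_mm + (g$shape - 1) * g$spacing_mm + g$spacing_mm
  grid_covering(lower, upper, spacing_mm)
}

#' Default modality simulators
#'
#' `simulate_spect()` and `simulate_pet()` call [simulate_modality()] with
#' the standard grids and the package's default system resolutions:
#' 12 mm FWHM for the SPECT-like path and 5 mm FWHM for the PET-like path
#' (the PET post-reconstruction filter width).
#'
#' @inheritParams simulate_modality
#' @export
simulate_spect <- function(truth, psf_fwhm_mm = 12, noise = "poisson",
                           counts_per_GBq = 1e6, seed = NULL) {
  simulate_modality(truth, spect_grid(truth), psf_fwhm_mm, noise,
                    counts_per_GBq, seed)
}

#' @rdname simulate_spect
#' @export
simulate_pet <- function(truth, psf_fwhm_mm = 5, noise = "poisson",
                         counts_per_GBq = 1e6, seed = NULL) {
  simulate_modality(truth, pet_grid(truth), psf_fwhm_mm, noise,
                    counts_per_GBq, seed)
}

#' Simulate anterior/posterior planar scintigraphy
#'
#' Builds the total-body activity (hepatic activity plus the shunted
#' fraction `lung_shunt_true * net_activity_GBq` spread uniformly over the
#' lung slab), projects it along the anterior-posterior axis, and rebins the
#' projection onto the planar pixel grid with exact area-weighted
#' redistribution (every source pixel's counts land in the target pixels it
#' overlaps, in proportion to the overlap — no counts are created or lost).
#' Each view is optionally Poisson-sampled independently. Without
#' attenuation the posterior projection equals the anterior one; the
#' posterior view is stored in the same pixel frame, so one set of ROIs
#' applies to both views and the geometric mean of the two views reduces
#' exactly to the single-view estimate. ROI masks are the organ-mask
#' projections mapped through the same rebinning, so they cover each organ's
#' counts entirely.
#'
#' @param truth A [make_phantom()] result.
#' @param pixel_mm Planar pixel size (mm), length 2 (x, z).
#' @param noise `"none"` or `"poisson"`.
#' @param counts_per_GBq Expected counts per GBq per view (> 0).
#' @param seed Integer seed for the Poisson draws.
#' @return An object of class `planar_study`: list with `anterior`,
#'   `posterior` (count matrices), `lung_roi`, `liver_roi` (logical
#'   matrices) and `pixel_mm`.
#' @export
simulate_planar <- function(truth, pixel_mm = c(2.4, 2.4),
                            noise = c("none", "poisson"),
                            counts_per_GBq = 1e6, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "phantom_truth"), length(pixel_mm) == 2,
            all(pixel_mm > 0))
  if (!is.finite(counts_per_GBq) || counts_per_GBq <= 0)
    stop("`counts_per_GBq` must be positive", call. = FALSE)
  g <- truth$activity$grid
  body <- truth$activity$values
  lungs <- truth$compartments$masks$lungs
  shunted <- truth$spec$net_activity_GBq * truth$spec$lung_shunt_true
  if (shunted > 0) {
    if (!any(lungs)) stop("lung compartment is empty", call. = FALSE)
    body[lungs] <- body[lungs] + shunted / sum(lungs)
  }

  # project along the anterior-posterior (y) axis on the native grid, then
  # rebin in-plane: separable, exactly mass-conserving
  proj <- apply(body, c(1, 3), sum)
  wx <- rebin_matrix(g, 1, pixel_mm[1])
  wz <- rebin_matrix(g, 3, pixel_mm[2])
  expected <- counts_per_GBq * (wx %*% proj %*% t(wz))

  proj_roi <- function(mask) {
    m2 <- apply(mask, c(1, 3), any)
    (wx %*% (m2 * 1) %*% t(wz)) > 1e-12
  }
  lung_roi <- proj_roi(lungs)
  liver_roi <- proj_roi(truth$compartments$masks$whole_liver)

  views <- if (noise == "poisson") {
    with_seed(seed, list(
      anterior = matrix(rpois(length(expected), expected), nrow(expected)),
      posterior = matrix(rpois(length(expected), expected), nrow(expected))
    ))
  } else list(anterior = expected, posterior = expected)

  structure(c(views, list(lung_roi = lung_roi, liver_roi = liver_roi,
                          pixel_mm = pixel_mm)),
            class = "planar_study")
}

# 1-D area-weighted rebinning matrix from a grid axis onto pixels of width
# `pixel_mm` covering the same extent; columns sum to 1 exactly, so every
# source voxel's content is fully redistributed.
rebin_matrix <- function(grid, axis, pixel_mm) {
  n_src <- grid$shape[axis]
  sp <- grid$spacing_mm[axis]
  lo <- grid$origin_mm[axis] - sp / 2
  src_edges <- lo + (0:n_src) * sp
  n_tgt <- max(1L, as.integer(ceiling(n_src * sp / pixel_mm)))
  tgt_edges <- lo + (0:n_tgt) * pixel_mm
  W <- matrix(0, n_tgt, n_src)
  for (j in seq_len(n_src)) {
    a <- src_edges[j]; b <- src_edges[j + 1]
    overlap <- pmax(0, pmin(b, tgt_edges[-1]) - pmax(a, tgt_edges[-(n_tgt + 1)]))
    W[, j] <- overlap / (b - a)
  }
  W
}

#' @export
print.planar_study <- function(x, ...) {
  cat(sprintf("<planar_study> %d x %d pixels, total counts ant %.4g / post %.4g\n",
              nrow(x$anterior), ncol(x$anterior),
              sum(x$anterior), sum(x$posterior)))
  invisible(x)
}
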