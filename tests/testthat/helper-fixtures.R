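# Shared fixtures: small phantoms and volumes built in code at test time.

# A compact phantom: ~4 cm liver with one 1 cm perfused tumour, coarse grid.
small_spec <- function(...) {
  args <- modifyList(list(
    liver_semiaxes_mm = c(40, 30, 25),
    tumor_centers_mm = c(18, 0, 0),
    tumor_radii_mm = 10,
    true_TN = 3,
    perfused_fraction = 0.6,
    net_activity_GBq = 2.0,
    lung_shunt_true = 0.10,
    spacing_mm = c(4, 4, 4),
    seed = 7L
  ), list(...))
  do.call(phantom_spec, args)
}

# A uniform single-compartment volume with exact total mass `mass_kg`:
# n voxels of 1 mL each at density 1 g/mL.
uniform_compartment <- function(n = 1000L, value = 1) {
  g <- voxel_grid(c(n, 1L, 1L), c(10, 10, 10))  # 1 mL voxels
  list(
    grid = g,
    counts = scalar_volume(rep(value, n), g, "counts"),
    comp = compartment_set(list(whole_liver = array(TRUE, c(n, 1, 1))), g)
  )
}

# Random dose map + full-mask compartments on a small grid.
random_dose_map <- function(shape = c(17, 13, 11), seed = 1) {
  set.seed(seed)
  g <- voxel_grid(shape, c(2, 2, 2))
  dose <- scalar_volume(rexp(prod(shape), rate = 1 / 50), g, "dose_Gy")
  comp <- compartment_set(list(whole_liver = array(TRUE, shape)), g)
  list(dose = dose, comp = comp)
}

# Independent D_x oracle: largest dose d with at least x% of voxels >= d,
# found by scanning the observed dose values directly.
d_metric_oracle <- function(doses, x) {
  n <- length(doses)
  cand <- sort(unique(doses))
  frac <- vapply(cand, function(t) sum(doses >= t) / n, numeric(1))
  vapply(x, function(p) max(cand[frac >= p / 100]), numeric(1))
}

# Independent DVH oracle: direct threshold counting.
dvh_oracle <- function(doses, levels) {
  n <- length(doses)
  vapply(levels, function(t) 100 * sum(doses >= t) / n, numeric(1))
}
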