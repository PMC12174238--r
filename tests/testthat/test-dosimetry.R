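test_that("patient-relative calibration allocates counts proportionally", {
  g <- voxel_grid(c(2, 1, 1), c(10, 10, 10))
  cts <- scalar_volume(c(1, 3), g, "counts")
  act <- calibrate_activity(cts, 1.0)
  expect_equal(as.vector(act$values), c(0.25, 0.75))

  u <- uniform_compartment(n = 250L, value = 4)
  act_u <- calibrate_activity(u$counts, 2.0)
  expect_equal(unique(as.vector(act_u$values)), 2.0 / 250)
  expect_equal(volume_total(act_u), 2.0, tolerance = 1e-9)

  set.seed(2)
  cts2 <- scalar_volume(runif(250), u$grid, "counts")
  expect_equal(volume_total(calibrate_activity(cts2, 2.0)), 2.0,
               tolerance = 1e-9)
})

test_that("calibration respects the field-of-view mask and rejects empty fields", {
  g <- voxel_grid(c(4, 1, 1), c(10, 10, 10))
  cts <- scalar_volume(c(1, 1, 1, 1), g, "counts")
  fov <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  act <- calibrate_activity(cts, 1.0, fov)
  expect_equal(as.vector(act$values), c(0.5, 0.5, 0, 0))
  zero <- scalar_volume(rep(0, 4), g, "counts")
  expect_error(calibrate_activity(zero, 1.0), "cannot calibrate empty field")
})

test_that("local deposition dose follows the 49.67 J/GBq conversion", {
  # 1 voxel of 1000 mL at 1 g/mL = 1 kg holding 1 GBq -> 49.67 Gy
  g <- voxel_grid(c(1, 1, 1), c(100, 100, 100))
  act <- scalar_volume(1.0, g, "activity_GBq")
  expect_equal(as.vector(ldm_dose(act, 1.0)$values), 49.67, tolerance = 1e-12)
  # 0.001 GBq in a 0.001 kg voxel -> also 49.67 Gy
  g2 <- voxel_grid(c(1, 1, 1), c(10, 10, 10))
  act2 <- scalar_volume(0.001, g2, "activity_GBq")
  expect_equal(as.vector(ldm_dose(act2, 1.0)$values), 49.67, tolerance = 1e-12)
  # zero activity maps to zero dose
  g3 <- voxel_grid(c(3, 3, 3), c(2, 2, 2))
  act3 <- scalar_volume(rep(0, 27), g3, "activity_GBq")
  expect_true(all(ldm_dose(act3)$values == 0))
})

test_that("mean dose matches a brute-force accumulation oracle", {
  rd <- random_dose_map(seed = 11)
  mask <- array(runif(prod(rd$dose$grid$shape)) < 0.4, rd$dose$grid$shape)
  comp <- compartment_set(list(tumor = mask,
                               whole_liver = array(TRUE, rd$dose$grid$shape)),
                          rd$dose$grid)
  oracle <- sum(rd$dose$values[mask]) / sum(mask)
  expect_equal(mean_dose(rd$dose, comp, "tumor"), oracle, tolerance = 1e-12)
  expect_equal(mean_dose(rd$dose, comp, "tumor"), mean(rd$dose$values[mask]))
  empty <- compartment_set(list(tumor = array(FALSE, rd$dose$grid$shape),
                                whole_liver = array(TRUE, rd$dose$grid$shape)),
                           rd$dose$grid)
  expect_error(mean_dose(rd$dose, empty, "tumor"), "empty")
})

test_that("T/N ratio divides tumour by perfused-normal mean dose", {
  g <- voxel_grid(c(2, 1, 1), c(10, 10, 10))
  dose <- scalar_volume(c(100, 40), g, "dose_Gy")
  comp <- compartment_set(list(
    perfused_tumor = array(c(TRUE, FALSE), c(2, 1, 1)),
    perfused_normal = array(c(FALSE, TRUE), c(2, 1, 1))
  ), g, check = FALSE)
  expect_equal(tn_ratio(dose, comp), 2.5)
  equal <- scalar_volume(c(60, 60), g, "dose_Gy")
  expect_equal(tn_ratio(equal, comp), 1.0)
  zero <- scalar_volume(c(10, 0), g, "dose_Gy")
  expect_error(tn_ratio(zero, comp), "undefined T/N")
})

test_that("DVH is the exact empirical survival curve", {
  # uniform field: 100% up to d, 0 above
  g <- voxel_grid(c(5, 5, 4), c(1, 1, 1))
  comp <- compartment_set(list(whole_liver = array(TRUE, c(5, 5, 4))), g)
  unif <- scalar_volume(rep(30, 100), g, "dose_Gy")
  h <- dvh(unif, comp, "whole_liver", n_bins = 11)
  expect_equal(h$volume_pct, rep(100, 11))  # grid spans 0..max = 0..30
  expect_equal(h$dose_Gy[1], 0)
  expect_equal(h$volume_pct[1], 100)

  # two-level field: DVH(50) = 50%
  two <- scalar_volume(rep(c(0, 100), each = 50), g, "dose_Gy")
  h2 <- dvh(two, comp, "whole_liver", n_bins = 201)
  expect_equal(h2$volume_pct[which.min(abs(h2$dose_Gy - 50))], 50)
  expect_true(all(diff(h2$volume_pct) <= 0))

  # random field: match the direct-counting oracle at every grid point
  rd <- random_dose_map(seed = 3)
  h3 <- dvh(rd$dose, rd$comp, "whole_liver", n_bins = 400)
  expect_equal(h3$volume_pct, dvh_oracle(as.vector(rd$dose$values), h3$dose_Gy))
})

test_that("D metrics are descending order statistics with ceiling indexing", {
  g <- voxel_grid(c(10, 1, 1), c(1, 1, 1))
  dose <- scalar_volume(seq(10, 100, by = 10), g, "dose_Gy")
  comp <- compartment_set(list(tumor = array(TRUE, c(10, 1, 1)),
                               whole_liver = array(TRUE, c(10, 1, 1))), g)
  expect_equal(unname(d_metric(dose, comp, "tumor", c(10, 50, 90))),
               c(100, 60, 20))
  expect_equal(unname(d_metric(dose, comp, "tumor", 100)), 10)  # the minimum
  unif <- scalar_volume(rep(42, 10), g, "dose_Gy")
  expect_equal(unname(d_metric(unif, comp, "tumor", c(1, 37, 100))),
               rep(42, 3))
})

test_that("D and V metrics agree with independent oracles on random maps", {
  for (seed in 1:5) {
    rd <- random_dose_map(shape = c(13, 9, 7), seed = seed)
    d <- as.vector(rd$dose$values)
    xs <- c(10, 50, 90)
    expect_identical(unname(d_metric(rd$dose, rd$comp, "whole_liver", xs)),
                     d_metric_oracle(d, xs))
    thr <- quantile(d, c(0.2, 0.5, 0.8), names = FALSE)
    expect_equal(unname(v_metric(rd$dose, rd$comp, "whole_liver", thr)),
                 vapply(thr, function(t) 100 * mean(d >= t), numeric(1)))
    dm <- unname(d_metric(rd$dose, rd$comp, "whole_liver", c(10, 50, 90, 100)))
    expect_true(all(diff(dm) <= 0))      # D10 >= D50 >= D90 >= D100
    expect_equal(dm[4], min(d))
  }
})

test_that("lung shunt fraction is the geometric-mean count fraction", {
  a <- matrix(0, 4, 4)
  a[1, 1] <- 100           # lung pixel
  a[3:4, 3:4] <- 225       # liver pixels, total 900
  lung <- matrix(FALSE, 4, 4); lung[1, 1] <- TRUE
  liver <- matrix(FALSE, 4, 4); liver[3:4, 3:4] <- TRUE
  res <- lung_shunt_fraction(a, a, lung, liver)
  expect_equal(res$gm_lung, 100)
  expect_equal(res$gm_liver, 900)
  expect_equal(res$lsf, 0.10)
  expect_equal(res$lsf, res$gm_lung / (res$gm_lung + res$gm_liver))

  a0 <- a; a0[1, 1] <- 0
  expect_equal(lung_shunt_fraction(a0, a0, lung, liver)$lsf, 0)
  zero_liver <- matrix(0, 4, 4)
  expect_error(lung_shunt_fraction(zero_liver, zero_liver, lung, liver),
               "liver ROI")
  # asymmetric views: gm is the geometric, not arithmetic, mean
  b <- a; b[3:4, 3:4] <- 100  # posterior liver total 400
  res2 <- lung_shunt_fraction(a, b, lung, liver)
  expect_equal(res2$gm_liver, sqrt(900 * 400))
})

test_that("lung dose applies the single-compartment conversion to the shunt", {
  expect_equal(lung_dose(1.0, 0, 1.0), 0)
  expect_equal(lung_dose(1.0, 0.10, 1.0), 4.967)
  # activity at which the 30 Gy per-treatment limit is reached at LSF 0.10
  a_limit <- 30 / (49.67 * 0.10)
  expect_equal(a_limit, 6.040, tolerance = 1e-3)
  expect_gt(lung_dose(a_limit * 1.01, 0.10, 1.0), 30)
  expect_lt(lung_dose(a_limit * 0.99, 0.10, 1.0), 30)
  expect_error(lung_dose(1, 0.1, 0), "positive")
})

test_that("dosimetry is linear in administered activity", {
  truth <- make_phantom(small_spec())
  counts <- simulate_modality(truth, truth$activity$grid, 0, "none", 1e6)
  comp <- truth$compartments
  k <- 2.7
  d1 <- ldm_dose(calibrate_activity(counts, 1.5), 1.03)
  d2 <- ldm_dose(calibrate_activity(counts, 1.5 * k), 1.03)
  expect_equal(d2$values, k * d1$values, tolerance = 1e-12)
  expect_equal(mean_dose(d2, comp, "perfused_tumor"),
               k * mean_dose(d1, comp, "perfused_tumor"), tolerance = 1e-12)
  expect_equal(unname(d_metric(d2, comp, "perfused_tumor", c(10, 90))),
               k * unname(d_metric(d1, comp, "perfused_tumor", c(10, 90))),
               tolerance = 1e-12)
  expect_equal(tn_ratio(d2, comp), tn_ratio(d1, comp), tolerance = 1e-12)
})

test_that("total energy bookkeeping: sum(D * m) = 49.67 J/GBq x activity", {
  truth <- make_phantom(small_spec())
  act <- truth$activity
  density <- 1.03
  dose <- ldm_dose(act, density)
  voxel_mass_kg <- density * voxel_volume_mL(act$grid) / 1000
  energy_J <- sum(dose$values) * voxel_mass_kg
  expect_equal(energy_J, 49.67 * volume_total(act), tolerance = 1e-9)
})

test_that("mean dose equals the DVH-implied mean within discretization error", {
  rd <- random_dose_map(seed = 8)
  h <- dvh(rd$dose, rd$comp, "whole_liver", n_bins = 4000)
  # E[D] = integral of the survival function over dose
  implied <- sum(h$volume_pct / 100) * diff(h$dose_Gy[1:2])
  expect_equal(implied, mean_dose(rd$dose, rd$comp, "whole_liver"),
               tolerance = 0.01)
})

test_that("dose reports satisfy the DVH and ordering invariants", {
  truth <- make_phantom(small_spec())
  dose <- ldm_dose(truth$activity, 1.03)
  rep <- dose_report(dose, truth$compartments, modality = "truth",
                     v_thresholds_Gy = c(50, 100))
  m <- tidy(rep)
  expect_true(all(c("role", "mean_dose_Gy", "D10", "D50", "D90") %in% names(m)))
  expect_true(all(m$D10 >= m$D50 & m$D50 >= m$D90))
  by_role <- split(rep$dvh, rep$dvh$role)
  for (b in by_role) {
    expect_equal(b$volume_pct[1], 100)
    expect_true(all(diff(b$volume_pct) <= 0))
  }
  g <- glance(rep)
  expect_equal(g$modality, "truth")
})
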