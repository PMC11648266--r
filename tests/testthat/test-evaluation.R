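test_that("percentile dose operators follow the sort-and-count convention", {
  v <- 1:10
  expect_equal(dose_at_volume(v, 50), 6)
  expect_equal(dose_at_volume(v, 100), 1)   # minimum dose
  expect_equal(dose_at_volume(rep(60, 7), 37), 60)
  expect_equal(volume_at_dose(v, 8), 30)
  expect_equal(volume_at_dose(v, 0), 100)
  expect_equal(volume_at_dose(v, 11), 0)
  expect_equal(dose_at_absolute_volume(c(5, 7, 9, 11), 1, 2), 9)
  expect_equal(dose_at_absolute_volume(c(5, 7, 9, 11), 1, 1), 11)  # max dose
  expect_equal(dose_at_absolute_volume(rep(4, 10), 0.5, 3), 4)
  expect_error(dose_at_absolute_volume(c(1, 2), 1, 5), "smaller")
  expect_error(dose_at_volume(numeric(0), 50), "empty")
})

test_that("homogeneity index matches the worked 1..100 example and scales out", {
  v <- 1:100
  expect_equal(homogeneity_index(v), 100 * (99 - 3) / 51)
  expect_equal(homogeneity_index(rep(42, 10)), 0)
  expect_equal(homogeneity_index(3.7 * v), homogeneity_index(v))
  expect_error(homogeneity_index(rep(0, 5)), "zero")
})

test_that("DVH operators agree with exhaustive oracles on random ROIs", {
  set.seed(123)
  for (rep in 1:5) {
    n <- sample(50:5000, 1)
    v <- round(runif(n, 0, 80), 2)          # ties occur at 2 decimals
    for (x in c(2, 35, 50, 98, 100))
      expect_equal(dose_at_volume(v, x), oracle_dose_at_volume(v, x))
    for (lev in c(0, 20, 55.5, 81))
      expect_equal(volume_at_dose(v, lev), oracle_volume_at_dose(v, lev))
    vv <- 0.1
    for (cc in c(0.1, 2, 5))
      expect_equal(dose_at_absolute_volume(v, vv, cc),
                   oracle_dose_at_cc(v, vv, cc))
    # ordering invariant
    expect_gte(dose_at_volume(v, 2), dose_at_volume(v, 50))
    expect_gte(dose_at_volume(v, 50), dose_at_volume(v, 98))
  }
})

test_that("DVH curves are monotone, start at 100% and end at 0%", {
  set.seed(4)
  v <- runif(500, 10, 70)
  dv <- dvh_curve(v, bin_width = 1)
  expect_equal(dv$volume[1], 100)
  expect_equal(dv$volume[length(dv$volume)], 0)
  expect_true(all(diff(dv$volume) <= 0))
})

test_that("median-dose scaling factor behaves as a ratio", {
  a <- rep(66.4, 50); b <- rep(57.6, 50)
  expect_equal(f_scal(a, b), 1.1528, tolerance = 1e-4)
  expect_equal(f_scal(b, a), 1 / f_scal(a, b))
  expect_equal(f_scal(a, a), 1)
  expect_error(f_scal(a, rep(0, 50)), "zero")
})

test_that("comparison maps handle difference, ratio and undefined voxels", {
  g <- voxel_grid(c(3, 1, 1), 10)
  a <- rbe_dose(c(2, 4, 6), g, "m1")
  b <- rbe_dose(c(2, 4, 6), g, "m2")
  expect_equal(dose_comparison_map(a, b, "difference"), c(0, 0, 0))
  expect_equal(dose_comparison_map(a, b, "ratio"), c(1, 1, 1))
  a2 <- rbe_dose(1.15 * b$values, g, "m1")
  expect_equal(dose_comparison_map(a2, b, "ratio"), rep(1.15, 3))
  b0 <- rbe_dose(c(0, 4, 6), g, "m2")
  rm <- dose_comparison_map(a, b0, "ratio")
  expect_true(is.na(rm[1]) && all(is.finite(rm[2:3])))
  g2 <- voxel_grid(c(4, 1, 1), 10)
  expect_error(dose_comparison_map(a, rbe_dose(rep(1, 4), g2, "m2")),
               "geometry")
})

test_that("goal checking is inclusive at the threshold", {
  g <- voxel_grid(c(40, 1, 1), 5)  # 0.125 cc voxels
  rois <- list(CTV = roi_mask("CTV", "target", rep(TRUE, 40), g))
  # exactly 95% of voxels at/above the level -> achieved 95.0 -> pass
  v95 <- c(rep(60, 38), rep(50, 2))
  doses <- list(m = rbe_dose(v95, g, "m"))
  goal <- clinical_goal("CTV", "m", "V", limit = 95, cmp = ">=", level = 57)
  gt <- check_goals(doses, rois, list(goal))
  expect_equal(gt$achieved, 95)
  expect_true(gt$pass)
  expect_true(attr(gt, "verdict"))
  # 93.3% achieved -> fail
  v93 <- c(rep(60, 37), rep(50, 3))   # 92.5%
  gt2 <- check_goals(list(m = rbe_dose(v93, g, "m")), rois, list(goal))
  expect_false(gt2$pass)
  expect_false(attr(gt2, "verdict"))
  # empty goal list: vacuous pass
  gt0 <- check_goals(doses, rois, list())
  expect_true(attr(gt0, "verdict"))
  expect_equal(nrow(gt0), 0)
  # missing model errors
  bad <- clinical_goal("CTV", "absent", "V", limit = 95, level = 57)
  expect_error(check_goals(doses, rois, list(bad)), "absent")
})

test_that("metric report obeys the percentile ordering invariant", {
  set.seed(9)
  g <- voxel_grid(c(30, 30, 4), 2)
  m1 <- rbe_dose(runif(n_voxels(g), 40, 70), g, "m1")
  rois <- list(R = roi_mask("R", "target", rep(TRUE, n_voxels(g)), g))
  rep_ <- metric_report(list(m1 = m1), rois)
  expect_true(rep_$D2 >= rep_$D50 && rep_$D50 >= rep_$D98)
  expect_true(rep_$D2cc <= max(m1$values))
  expect_gte(rep_$HI, 0)
})
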