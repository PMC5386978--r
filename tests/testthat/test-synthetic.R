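test_that("trajectory fractions follow the configured polynomials", {
  p <- aging_params()

  # calibration point: female cohort-mean GM fraction
  fr <- trajectory_fractions(p, "female", 9.43)
  expect_equal(fr$gm, 0.47, tolerance = 0.005)
  expect_equal(fr$gm + fr$wm + fr$csf, 1, tolerance = 1e-6)

  # linear female decline: GM(15) - GM(5) is exactly 10 x the slope
  g5 <- trajectory_fractions(p, "female", 5)$gm
  g15 <- trajectory_fractions(p, "female", 15)$gm
  expect_equal(g5 - g15, -p$gm_coef$female[2] * 10, tolerance = 1e-12)

  # GM monotone non-increasing for both sexes across the supported range
  ages <- seq(4, 22, by = 0.5)
  for (sex in c("female", "male")) {
    gm <- trajectory_fractions(p, sex, ages)$gm
    expect_true(all(diff(gm) <= 1e-12))
  }

  # zero MNR effect leaves fractions untouched
  p0 <- aging_params(mnr_gm_offset = 0)
  expect_identical(trajectory_fractions(p0, "female", 6, "CTR"),
                   trajectory_fractions(p0, "female", 6, "MNR"))

  # default MNR effect: GM down by exactly the configured offset, CSF up,
  # males unaffected
  ctr <- trajectory_fractions(p, "female", 5, "CTR")
  mnr <- trajectory_fractions(p, "female", 5, "MNR")
  expect_equal(ctr$gm - mnr$gm, p$mnr_gm_offset, tolerance = 1e-10)
  expect_gt(mnr$csf, ctr$csf)
  expect_identical(trajectory_fractions(p, "male", 5, "CTR"),
                   trajectory_fractions(p, "male", 5, "MNR"))

  expect_error(trajectory_fractions(p, "female", 30), "range")
})

test_that("rendered phantoms hit the requested composition and geometry", {
  p <- mid_params(noise_sd = 0, bias_amp = 0, slice_gain_sd = 0)
  sp <- phantom_spec("a", gm = 0.47, wm = 0.32, csf = 0.21, tiv = 195,
                     seed = 11, params = p)
  ph <- render_phantom(sp)

  # voxel-count fractions of the ground truth match the request within 2%
  voxml <- prod(ph$truth$voxel_size) / 1000
  vols <- vapply(1:3, function(c) sum(ph$truth$prob[, , , c]) * voxml,
                 numeric(1))
  tiv <- sum(vols)
  expect_equal(tiv, 195, tolerance = 0.02 * 195)
  expect_equal(vols / tiv, c(0.47, 0.32, 0.21), tolerance = 0.02)

  # noise-free rendering is piecewise constant with T1-like ordering
  vals <- ph$image$values
  m <- tapply(vals, ph$labels, mean)
  expect_lt(m["3"], m["1"])          # CSF < GM
  expect_lt(m["1"], m["2"])          # GM < WM
  within_sd <- tapply(vals, ph$labels, sd)
  expect_true(all(within_sd < 1e-12))

  # determinism: identical seed, bit-identical output
  ph2 <- render_phantom(sp)
  expect_identical(ph$image$values, ph2$image$values)
  expect_identical(ph$truth$prob, ph2$truth$prob)

  # noisy rendering differs but keeps the same truth
  pn <- mid_params(noise_sd = 0.03)
  phn <- render_phantom(phantom_spec("a", 0.47, 0.32, 0.21, 195, seed = 11,
                                     params = pn))
  expect_identical(phn$labels, ph$labels)
  expect_false(identical(phn$image$values, ph$image$values))

  # infeasible geometry errors
  expect_error(render_phantom(phantom_spec("big", 0.47, 0.32, 0.21,
                                           tiv = 5000, seed = 1,
                                           params = p)),
               "geometry|fit")
  expect_error(phantom_spec("bad", 0.5, 0.4, 0.2, 195, 1, p), "sum")
})

test_that("generate_cohort is seeded, sized and writes valid files", {
  p <- small_params()
  co <- generate_cohort(p, c(3, 2), master_seed = 21, render_image = FALSE)
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(nrow(co$metadata), 5)
  expect_equal(sum(co$metadata$sex == "female"), 3)
  expect_false(any(duplicated(co$metadata$id)))
  expect_true(all(co$metadata$age >= 4 & co$metadata$age <= 22))

  # determinism of the metadata table under one master seed
  co2 <- generate_cohort(p, c(3, 2), master_seed = 21, render_image = FALSE)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$truth[[2]]$prob, co2$truth[[2]]$prob)

  # a different master seed changes the draw
  co3 <- generate_cohort(p, c(3, 2), master_seed = 22, render_image = FALSE)
  expect_false(identical(co$metadata$age, co3$metadata$age))

  # single-subject cohort
  co1 <- generate_cohort(p, c(1, 0), master_seed = 1, render_image = FALSE)
  expect_equal(nrow(co1$metadata), 1)

  # NIfTI + CSV round trip
  dir <- withr::local_tempdir()
  co4 <- generate_cohort(p, c(1, 1), master_seed = 5, dir = dir)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_named(meta, c("id", "sex", "age", "group", "birth_weight",
                       "weight_at_scan"))
  img <- read_volume(file.path(dir, paste0(meta$id[1], ".nii.gz")))
  expect_equal(img$values, co4$images[[1]]$values, tolerance = 1e-6)
  expect_equal(img$voxel_size, co4$images[[1]]$voxel_size, tolerance = 1e-6)
})

test_that("ground-truth cohort recovers the programmed GM-age slope", {
  # parameter recovery: regressing true fractional GM on age in a large
  # female cohort returns the configured linear coefficient within 2 SE
  p <- small_params()
  co <- generate_cohort(p, c(60, 0), master_seed = 33, render_image = FALSE)
  m <- co$metadata
  fit <- summary(lm(gm_frac_true ~ age, data = m))
  est <- fit$coefficients["age", ]
  expect_lt(abs(est["Estimate"] - p$gm_coef$female[2]), 2 * est["Std. Error"])

  # voxel-count TIV matches the drawn TIV within 2%
  voxml <- prod(co$truth[[1]]$voxel_size) / 1000
  tiv_vox <- sum(co$truth[[1]]$prob[, , , 1:3]) * voxml
  expect_equal(tiv_vox, m$tiv_true[1], tolerance = 0.02 * m$tiv_true[1])
})
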