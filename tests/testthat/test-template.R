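test_that("template initialization scales a reference to the target volume", {
  ref <- synthetic_reference_tpm(brain_volume_ml = 1400, grid_dim = 32,
                                 voxel_size = 5)
  v0 <- tpm_volume_ml(ref)

  # target = the reference's own volume: identity scaling
  t_id <- initialize_template(ref, v0, voxel_size = 5)
  expect_equal(tpm_volume_ml(t_id$tpm), v0, tolerance = 0.01 * v0)

  # target = reference / 8: linear scale factor 0.5 (cube-root relation)
  t_8 <- initialize_template(ref, v0 / 8, voxel_size = 3)
  expect_equal(tpm_volume_ml(t_8$tpm), v0 / 8, tolerance = 0.01 * v0 / 8)
  ext_ref <- sum(ref$prob[, , , 1:3] > 0.5)^(1 / 3) * ref$voxel_size[1]
  ext_new <- sum(t_8$tpm$prob[, , , 1:3] > 0.5)^(1 / 3) * 3
  expect_equal(ext_new / ext_ref, 0.5, tolerance = 0.05)

  # species default: 200 ml within 1%
  t200 <- initialize_template(ref, 200, voxel_size = 3)
  expect_equal(tpm_volume_ml(t200$tpm), 200, tolerance = 2)

  # per-voxel probabilities renormalized
  tot <- apply(t200$tpm$prob, 1:3, sum)
  expect_lt(max(abs(tot - 1)), 1e-6)

  expect_error(initialize_template(ref, -5, 3), "positive")
})

test_that("single clean subject is a fixed point of the iteration", {
  p <- mid_params(noise_sd = 0.01)
  co <- generate_cohort(p, c(1, 0), master_seed = 13)
  tmpl0 <- initialize_template(synthetic_reference_tpm(grid_dim = 32,
                                                       voxel_size = 5),
                               200, voxel_size = p$voxel_size)
  img <- resample_volume(co$images[[1]], target = tmpl0$t1_average)
  tm <- iterate_template(list(img), tmpl0, max_iter = 4, register = FALSE)
  expect_true(length(tm$history) <= 2 || tm$history[2] < 1e-3)
  # the converged template segments its own subject back to the programmed
  # composition
  seg <- segment_tpm(img, tm$tpm)
  m <- co$metadata
  expect_equal(unname(seg$fractions),
               c(m$gm_frac_true[1], m$wm_frac_true[1], m$csf_frac_true[1]),
               tolerance = 0.05)
})

test_that("median aggregation resists a corrupted subject", {
  p <- small_params(noise_sd = 0.01)
  base <- render_phantom(phantom_spec("m", 0.47, 0.32, 0.21, 195, seed = 44,
                                      params = p))
  imgs <- lapply(1:9, function(i) base$image)
  corrupted <- base$image
  corrupted$values <- max(base$image$values) - base$image$values  # inverted
  tmpl0 <- template_set(smooth_tpm(base$truth, 4), clean_intensity(base),
                        tpm_brain_mask(base$truth))

  t_clean <- iterate_template(imgs, tmpl0, max_iter = 1, register = FALSE)
  t_mixed <- iterate_template(c(imgs, list(corrupted)), tmpl0, max_iter = 1,
                              register = FALSE)
  # the corrupted tenth subject moves the median template by < 2%
  diff <- mean(abs(t_mixed$tpm$prob - t_clean$tpm$prob))
  expect_lt(diff, 0.02)

  # where a majority of subjects agree exactly and the rest straddle the
  # agreed value, the cohort median is untouched by one arbitrary
  # corrupted subject
  set.seed(90)
  agree <- matrix(0.4, 5, 5)                      # 5 of 9 agree at 0.4
  below <- matrix(runif(10, 0, 0.3), 5, 2)
  above <- matrix(runif(10, 0.5, 0.9), 5, 2)
  m9 <- cbind(agree, below, above)
  med9 <- apply(m9, 1, median)
  med10 <- apply(cbind(m9, runif(5, -10, 10)), 1, median)
  expect_equal(med9, rep(0.4, 5))
  expect_equal(med10, med9, tolerance = 1e-12)
})

test_that("iteration change metric settles on clean cohorts", {
  p <- small_params(noise_sd = 0.02)
  co <- generate_cohort(p, c(3, 2), master_seed = 55)
  tmpl0 <- initialize_template(synthetic_reference_tpm(grid_dim = 32,
                                                       voxel_size = 5),
                               200, voxel_size = p$voxel_size)
  imgs <- lapply(co$images, resample_volume, target = tmpl0$t1_average)
  tm <- iterate_template(imgs, tmpl0, max_iter = 4, stop_tol = 1e-5,
                         register = FALSE)
  h <- tm$history
  expect_true(all(is.finite(h)) && all(h >= 0))
  if (length(h) >= 3) expect_true(all(diff(h[-1]) <= 1e-3))
  # template volume lands near the cohort's mean TIV
  expect_equal(tpm_volume_ml(tm$tpm), mean(co$metadata$tiv_true),
               tolerance = 0.15 * mean(co$metadata$tiv_true))
})
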