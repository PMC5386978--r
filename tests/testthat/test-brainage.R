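test_that("BrainAGE score and MAE identities hold exactly", {
  ca <- c(4.2, 7.5, 12.1, 19.8)
  # perfect prediction: MAE 0, all scores 0
  r0 <- brainage_result(paste0("s", 1:4), ca, ca)
  expect_equal(attr(r0, "mae"), 0)
  expect_equal(r0$score, rep(0, 4))

  # uniform +2-year offset: MAE exactly 2, every score +2
  r2 <- brainage_result(paste0("s", 1:4), ca, ca + 2)
  expect_equal(attr(r2, "mae"), 2)
  expect_equal(r2$score, rep(2, 4))

  # score == brain_age - age for arbitrary predictions
  set.seed(10)
  ba <- ca + rnorm(4)
  r <- brainage_result(paste0("s", 1:4), ca, ba)
  expect_equal(r$score, ba - ca)
  expect_equal(attr(r, "mae"), mean(abs(ba - ca)))
  expect_lte(abs(attr(r, "r")), 1)
})

test_that("human-equivalent age uses the 3.5 factor", {
  expect_equal(human_equivalent_age(4), 14)
  expect_equal(human_equivalent_age(22), 77)
  expect_equal(human_equivalent_age(5), 17.5)
  expect_error(human_equivalent_age(-1), "non-negative")
})

test_that("LOOCV recovers a noiseless age signal without leakage", {
  # maps whose voxel values are an exactly linear, noise-free function of
  # age: construction guarantees recoverability
  set.seed(17)
  d <- 12
  ages <- runif(15, 4, 22)
  base <- array(runif(d^3, 0.2, 0.4), c(d, d, d))
  slope <- array(rnorm(d^3, 0, 0.01), c(d, d, d))
  maps <- lapply(ages, function(a) volume_image(base + slope * a, 4))
  cohort <- list(gm_maps = maps,
                 metadata = data.frame(id = sprintf("x%02d",
                                                    seq_along(ages)),
                                       age = ages))
  res <- loocv_brainage(cohort, fwhm = 0, resample = 4)
  acc <- brainage_accuracy(res)
  expect_lt(acc$mae, 0.1)
  expect_gt(acc$r, 0.999)
  expect_equal(res$score, res$brain_age - res$age)
})

test_that("LOOCV on pure-noise ages does no better than a mean predictor", {
  # leakage guard: with ages unrelated to the maps, pooled LOOCV MAE must be
  # close to that of predicting each fold's training mean
  # averaged over shuffles so a single chance alignment cannot dominate
  p <- small_params()
  co <- generate_cohort(p, c(6, 6), master_seed = 23, render_image = FALSE)
  meta <- co$metadata
  n <- nrow(meta)
  set.seed(99)
  ratios <- vapply(1:4, function(k) {
    meta$age <- sample(meta$age)            # break the age-map link
    res <- loocv_brainage(list(gm_maps = cohort_gm_maps(co),
                               metadata = meta))
    mean_pred_mae <- mean(vapply(seq_len(n), function(i)
      abs(mean(meta$age[-i]) - meta$age[i]), numeric(1)))
    brainage_accuracy(res)$mae / mean_pred_mae
  }, numeric(1))
  expect_gt(mean(ratios), 0.6)
  expect_lt(mean(ratios), 2)
})

test_that("apply_trained_model scores a test cohort consistently", {
  p <- small_params()
  train <- generate_cohort(p, c(6, 6), master_seed = 31,
                           render_image = FALSE)
  fit <- apply_trained_model(train, train)
  # test = train: predictions equal fitted values
  expect_equal(fit$result$brain_age, fitted(fit$model), tolerance = 1e-9)

  ctr <- generate_cohort(p, c(4, 0), age_range = c(4, 7), group = "CTR",
                         master_seed = 32, render_image = FALSE,
                         id_prefix = "C")
  mnr <- generate_cohort(p, c(4, 0), age_range = c(4, 7), group = "MNR",
                         master_seed = 33, render_image = FALSE,
                         id_prefix = "M")
  test <- list(gm_maps = c(cohort_gm_maps(ctr), cohort_gm_maps(mnr)),
               metadata = rbind(ctr$metadata, mnr$metadata))
  fit2 <- apply_trained_model(train, test)
  expect_equal(nrow(fit2$result), 8)
  expect_true(all(c("sex", "group") %in% colnames(fit2$result)))
  expect_true(all(is.finite(fit2$result$brain_age)))

  # model serialization round trip produces the documented bundle
  dir <- withr::local_tempdir()
  write_brainage_model(fit2, dir)
  expect_true(all(file.exists(file.path(dir, c("model.json",
                                               "relevance_vectors.csv",
                                               "pca_basis.csv")))))
  mj <- jsonlite::read_json(file.path(dir, "model.json"))
  expect_equal(mj$kernel, "linear")
})
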