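test_that("EM segmentation is self-consistent on clean phantoms", {
  p <- mid_params(noise_sd = 0, bias_amp = 0, slice_gain_sd = 0)
  ph <- render_phantom(phantom_spec("s", 0.47, 0.32, 0.21, 195, seed = 12,
                                    params = p))
  seg <- segment_tpm(ph$image, ph$truth)
  dc <- dice_coefficient(seg$posterior, ph$truth)
  expect_true(all(dc >= 0.99))
  voxml <- prod(ph$truth$voxel_size) / 1000
  true_vols <- vapply(1:3, function(c) sum(ph$truth$prob[, , , c]) * voxml,
                      numeric(1))
  expect_equal(unname(seg$volumes_ml), true_vols,
               tolerance = 0.01 * max(true_vols))

  # invariants: posterior normalization, fraction normalization, TIV sum
  tot <- apply(seg$posterior$prob, 1:3, sum)
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_equal(sum(seg$fractions), 1, tolerance = 1e-6)
  expect_equal(seg$tiv_ml, sum(seg$volumes_ml), tolerance = 1e-6)
})

test_that("segmentation stays accurate at 3% noise with a softened prior", {
  ph <- test_phantom()
  corrected <- denoise_nlm(correct_slice_inhomogeneity(ph$image)$image)
  seg <- segment_tpm(corrected, smooth_tpm(ph$truth, 3))
  dc <- dice_coefficient(seg$posterior, ph$truth)
  expect_true(all(dc >= 0.95))
})

test_that("EM matches a brute-force oracle on a flat-prior mixture", {
  # independent oracle: plain two-class EM on the same 1D data, written as
  # direct loops over the responsibilities
  set.seed(5)
  n <- 4000
  y <- c(rnorm(n / 2, 0.2, 0.05), rnorm(n / 2, 0.8, 0.05))
  oracle_em <- function(y, mu, sig, iters = 200) {
    floor_ <- max(0.02 * (max(y) - min(y)), 1e-8)
    for (i in seq_len(iters)) {
      d1 <- 0.5 * dnorm(y, mu[1], sig[1])
      d2 <- 0.5 * dnorm(y, mu[2], sig[2])
      r <- d1 / (d1 + d2)
      mu <- c(sum(r * y) / sum(r), sum((1 - r) * y) / sum(1 - r))
      sig <- pmax(c(sqrt(sum(r * (y - mu[1])^2) / sum(r)),
                    sqrt(sum((1 - r) * (y - mu[2])^2) / sum(1 - r))),
                  floor_)
    }
    list(mu = mu, sig = sig)
  }
  # embed the sample in a 3D grid with two active classes and a flat prior
  d <- c(20, 20, 10)
  stopifnot(prod(d) == n)
  img <- volume_image(array(y, d), 2)
  prob <- array(0, c(d, 4))
  prob[, , , 1] <- 0.5
  prob[, , , 3] <- 0.5
  tpm <- tissue_prob_map(prob, 2)
  seg <- suppressWarnings(segment_tpm(img, tpm, max_iter = 200, tol = 1e-12))
  orc <- oracle_em(y, mu = seg_init <- c(0.3, 0.7), sig = c(0.2, 0.2))
  expect_equal(sort(seg$mu[c(1, 3)]), sort(orc$mu), tolerance = 1e-6)

  # empty classes are dropped with a warning
  expect_warning(segment_tpm(img, tpm), "dropping empty class")
})

test_that("the fixed preprocessing order is idempotent-safe on clean input", {
  p <- mid_params(noise_sd = 0, bias_amp = 0, slice_gain_sd = 0)
  ph <- render_phantom(phantom_spec("c", 0.47, 0.32, 0.21, 195, seed = 3,
                                    params = p))
  tmpl <- template_set(smooth_tpm(ph$truth, 3),
                       clean_intensity(ph), tpm_brain_mask(ph$truth))
  res <- preprocess_subject(ph$image, tmpl, denoise = TRUE,
                            register = FALSE)
  # each stage changes an already-clean image by at most 1%
  rng <- diff(range(ph$image$values))
  expect_lt(mean(abs(res$image$values - ph$image$values)) / rng, 0.01)
  expect_true(all(dice_coefficient(res$segmentation$posterior,
                                   ph$truth) >= 0.95))
})
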