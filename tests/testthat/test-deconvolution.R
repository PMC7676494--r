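test_that("psf_model enforces the unit-flux contract", {
  k <- array(runif(3 * 3 * 3), c(3, 3, 3))
  p <- psf_model(k)
  expect_equal(sum(p$kernel), 1)
  expect_error(psf_model(array(-1, c(3, 3, 3))), "non-negative")
  expect_error(psf_model(array(0, c(3, 3, 3))), "positive total flux")
  expect_error(psf_model(k, normalize = FALSE), "sum to 1")

  # richardson_lucy refuses a non-normalized kernel
  bad <- psf_model(k)
  bad$kernel <- bad$kernel * 2
  obs <- array(1, c(8, 8, 8))
  expect_error(richardson_lucy(obs, bad), "sum to 1")
})

test_that("delta PSF is a fixed point of the RL update", {
  delta <- psf_model(array(1, c(1, 1, 1)))
  obs <- biopsy3d:::with_seed(3, array(runif(10 * 12 * 8, 0.1, 2),
                                       c(10, 12, 8)))
  out <- richardson_lucy(obs, delta, iterations = 7, tol = 0)
  expect_equal(out, obs, tolerance = 1e-10)
})

test_that("RL conserves flux and non-negativity with a unit-sum PSF", {
  psf <- defocus_psf(defocus_model(0.5, 0.15), c(dz = 1, dy = 1, dx = 1),
                     axial_sigma_um = 2)
  obs <- biopsy3d:::with_seed(5, {
    v <- array(0, c(24, 24, 24))
    v[8:16, 8:16, 8:16] <- runif(9^3, 0, 2)
    pmax(biopsy3d:::conv3_fft(v, psf$kernel), 0)
  })
  out10 <- richardson_lucy(obs, psf, iterations = 10, tol = 0)
  expect_true(all(out10 >= 0))
  # interior flux (signal sits well away from the boundaries)
  expect_lt(abs(sum(out10) - sum(obs)) / sum(obs), 1e-3)
})

test_that("KL divergence between observed and re-blurred estimate never rises", {
  psf <- defocus_psf(defocus_model(0.5, 0.2), c(dz = 1, dy = 1, dx = 1),
                     axial_sigma_um = 2)
  obs <- biopsy3d:::with_seed(6, {
    v <- array(0, c(32, 32, 32))
    v[10:22, 10:22, 10:22] <- runif(13^3, 0, 1)
    pmax(biopsy3d:::conv3_fft(v, psf$kernel) +
           array(rnorm(32^3, sd = 1e-3), c(32, 32, 32)), 0)
  })
  kl <- vapply(1:6, function(k) {
    est <- richardson_lucy(obs, psf, iterations = k, tol = 0)
    kl_reblur(obs, est, psf)
  }, numeric(1))
  expect_true(all(diff(kl) <= 1e-8 * abs(kl[-6]) + 1e-10))
})

test_that("deconvolution reconcentrates a blurred point source", {
  psf <- defocus_psf(defocus_model(), default_spacing())
  truth <- array(0, c(48, 48, 24))
  truth[24, 24, 12] <- 50
  obs <- pmax(biopsy3d:::conv3_fft(truth, psf$kernel), 0)
  dec <- richardson_lucy(obs, psf, iterations = 25, tol = 0)
  enclosed <- function(v, r = 3) {
    idx <- arrayInd(seq_along(v), dim(v))
    d <- sqrt((idx[, 1] - 24)^2 + (idx[, 2] - 24)^2 + (idx[, 3] - 12)^2)
    sum(v[d <= r]) / sum(v)
  }
  expect_gt(enclosed(dec), 0.60)
  expect_lt(enclosed(obs), enclosed(dec))
})

test_that("bead-derived PSF estimation recovers the bead image", {
  psf <- defocus_psf(defocus_model(0.5, 0.25), default_spacing(),
                     axial_sigma_um = 4)
  # noiseless single centered bead: the extracted kernel must correlate
  # almost perfectly with sphere (x) PSF
  bead <- matrix(c(45, 60, 60), 1)  # on a voxel center
  bs <- simulate_bead_stack(bead, psf, volume_shape = c(32, 120, 120),
                            noise_sd = 0, seed = 1L)
  est1 <- estimate_psf(bs, patch_radius_um = 10)
  truth_img <- simulate_bead_stack(bead, psf, volume_shape = c(32, 120, 120),
                                   noise_sd = 0, seed = 2L)
  ctr <- c(61, 61, 16)  # (y, x, z) voxel of the bead
  rv <- round(10 / default_spacing())[c("dy", "dx", "dz")]
  patch <- truth_img$data[(ctr[1] - rv[1]):(ctr[1] + rv[1]),
                          (ctr[2] - rv[2]):(ctr[2] + rv[2]),
                          (ctr[3] - rv[3]):(ctr[3] + rv[3])]
  expect_gt(cor(as.vector(est1$kernel), as.vector(patch)), 0.99)

  # two well-separated beads average to the single-bead result
  psf_small <- defocus_psf(defocus_model(0.5, 0.1), default_spacing(),
                           axial_sigma_um = 3)
  beads2 <- rbind(c(46.5, 45, 45), c(46.5, 150, 150))
  bs2 <- simulate_bead_stack(beads2, psf_small,
                             volume_shape = c(32, 196, 196),
                             noise_sd = 1e-4, seed = 3L)
  est2 <- estimate_psf(bs2, patch_radius_um = 10)
  bs1 <- simulate_bead_stack(beads2[1, , drop = FALSE], psf_small,
                             volume_shape = c(32, 196, 196),
                             noise_sd = 1e-4, seed = 4L)
  est_single <- estimate_psf(bs1, patch_radius_um = 10)
  expect_gt(cor(as.vector(est2$kernel), as.vector(est_single$kernel)),
            0.995)

  # degenerate inputs
  flat <- channel_stack(array(0.5, c(16, 32, 32)))
  expect_error(estimate_psf(flat), "no beads")
})
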