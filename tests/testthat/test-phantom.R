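test_that("phantom generation is deterministic and geometrically sound", {
  spec <- phantom_spec(volume_shape = c(24, 64, 64),
                       cavities = NULL, seed = 3L)
  t1 <- generate_phantom(spec)
  t2 <- generate_phantom(spec)
  expect_identical(t1$tissue_mask, t2$tissue_mask)
  expect_identical(t1$texture, t2$texture)

  # no cavities: labels all zero, mask equals the tissue box
  expect_true(all(t1$cavity_labels == 0L))
  co <- biopsy3d:::axis_coords(spec)
  box <- outer(outer(co$y >= spec$tissue_extent$y[1] &
                       co$y <= spec$tissue_extent$y[2],
                     co$x >= spec$tissue_extent$x[1] &
                       co$x <= spec$tissue_extent$x[2], `&`),
               co$z >= spec$tissue_extent$z[1] &
                 co$z <= spec$tissue_extent$z[2], `&`)
  expect_identical(unname(t1$tissue_mask), unname(box))

  # fluorescence truths live inside tissue only
  spec2 <- phantom_spec(volume_shape = c(32, 96, 96),
                        cavities = tibble::tibble(
                          shape = "sphere", diameter_um = 45, z_um = 46.5,
                          y_um = 47, x_um = 47, axis = NA_character_),
                        seed = 5L)
  tr <- generate_phantom(spec2)
  expect_true(all(tr$fl1_truth[!tr$tissue_mask] == 0))
  expect_true(all(tr$fl2_truth[!tr$tissue_mask] == 0))
  expect_true(sum(tr$fl1_truth) > 0)
  expect_true(all(!(tr$cavity_labels > 0 & tr$tissue_mask)))

  # cavity outside the tissue extent is refused
  bad <- phantom_spec(volume_shape = c(32, 96, 96),
                      cavities = tibble::tibble(
                        shape = "sphere", diameter_um = 60, z_um = 10,
                        y_um = 47, x_um = 47, axis = NA_character_),
                      seed = 1L)
  expect_error(generate_phantom(bad), "outside the tissue extent")
})

test_that("voxelized sphere volume matches the analytic value within 10%", {
  spec <- phantom_spec(seed = 1L)  # default graded layout includes 80 um
  truth <- generate_phantom(spec)
  tab <- truth$cavity_table
  v80 <- tab$voxels[tab$diameter_um == 80]
  analytic <- (pi / 6) * 80^3 / prod(spec$spacing_um)
  expect_lt(abs(v80 - analytic) / analytic, 0.10)
  # equivalent-diameter formula consistency
  expect_equal(tab$equivalent_diameter_um,
               (6 * tab$voxels * prod(spec$spacing_um) / pi)^(1 / 3))
})

test_that("bright-field simulation obeys its degenerate limits", {
  # empty truth: constant planes plus noise, energy flat across planes
  empty <- phantom_spec(volume_shape = c(16, 48, 48),
                        tissue_extent = list(z = c(-2, -1), y = c(0, 47),
                                             x = c(0, 47)),
                        cavities = NULL, seed = 2L)
  te <- generate_phantom(empty)
  expect_equal(sum(te$tissue_mask), 0)
  bf <- simulate_bf_stack(te)
  em <- apply(bf$data, 3, function(p) mean(local_highfreq_energy(p, 3)))
  expect_lt(sd(em) / mean(em), 0.1)

  # zero blur growth: all planes identical in the noiseless limit
  spec <- phantom_spec(volume_shape = c(12, 48, 48), cavities = NULL,
                       noise_sd = 0, seed = 4L)
  tr <- generate_phantom(spec)
  bf0 <- simulate_bf_stack(tr, defocus_model(0.5, 0))
  for (k in 2:12) expect_equal(bf0$data[, , k], bf0$data[, , 1],
                               tolerance = 1e-12)

  # determinism under a fixed seed
  bfa <- simulate_bf_stack(tr, seed = 11L)
  bfb <- simulate_bf_stack(tr, seed = 11L)
  expect_identical(bfa$data, bfb$data)
})

test_that("defocus attenuates in-focus high-frequency energy monotonically", {
  # textured slab: the in-focus plane's mean local high-frequency energy
  # strictly exceeds that of planes >= 5 steps away, in >= 95% of 20
  # seeded replicates
  wins <- 0
  trials <- 0
  for (s in 1:20) {
    spec <- phantom_spec(volume_shape = c(24, 48, 48),
                         tissue_extent = list(z = c(27, 42), y = c(4, 43),
                                              x = c(4, 43)),
                         cavities = NULL, noise_sd = 0, seed = s)
    tr <- generate_phantom(spec)
    bf <- simulate_bf_stack(tr)
    mid <- 12  # inside the slab (z = 33 um)
    e_mid <- mean(local_highfreq_energy(bf$data[, , mid], 7))
    for (far in c(mid - 7, mid + 7, mid - 9, mid + 9)) {
      trials <- trials + 1
      e_far <- mean(local_highfreq_energy(bf$data[, , far], 7))
      if (e_mid > e_far) wins <- wins + 1
    }
  }
  expect_gte(wins / trials, 0.95)
})

test_that("dark-field signal is gradient-driven", {
  # homogeneous tissue (zero texture contrast): signal only near borders
  spec <- phantom_spec(volume_shape = c(16, 48, 48), cavities = NULL,
                       texture_contrast = 0, noise_sd = 0, seed = 6L)
  tr <- generate_phantom(spec)
  df <- simulate_df_stack(tr)
  interior <- df$data[23:26, 23:26, 8]   # deep inside the slab
  border <- df$data[16:18, 20:28, 8]     # across the lateral tissue wall
  expect_lt(mean(interior), mean(border) / 5)
})

test_that("fluorescence image formation is linear with PSF blur", {
  tr <- small_truth()
  psf <- defocus_psf(defocus_model(), tr$spec$spacing_um)
  fl1 <- simulate_fl_stacks(tr, psf = psf, noise_sd = 0)
  tr2 <- tr
  tr2$fl1_truth <- 2 * tr$fl1_truth
  tr2$fl2_truth <- 2 * tr$fl2_truth
  fl2 <- simulate_fl_stacks(tr2, psf = psf, noise_sd = 0)
  expect_equal(fl2$FL1$data, 2 * fl1$FL1$data, tolerance = 1e-10)

  # all-zero truth gives a pure-noise stack
  tr0 <- tr
  tr0$fl1_truth[] <- 0
  tr0$fl2_truth[] <- 0
  fl0 <- simulate_fl_stacks(tr0, psf = psf, noise_sd = 1e-3)
  expect_lt(max(fl0$FL1$data), 1e-2)

  # a single point source reproduces the PSF kernel up to noise
  trp <- tr
  trp$fl1_truth[] <- 0
  trp$fl1_truth[48, 48, 16] <- 1
  trp$fl2_truth[] <- 0
  flp <- simulate_fl_stacks(trp, psf = psf, noise_sd = 0)
  dk <- dim(psf$kernel)
  patch <- flp$FL1$data[48 + (-(dk[1] %/% 2)):(dk[1] %/% 2),
                        48 + (-(dk[2] %/% 2)):(dk[2] %/% 2),
                        16 + (-(dk[3] %/% 2)):(dk[3] %/% 2)]
  expect_gt(cor(as.vector(patch), as.vector(psf$kernel)), 0.999)
})

test_that("bead stacks are PSF copies with separation enforcement", {
  psf <- defocus_psf(defocus_model(), default_spacing())
  # zero beads: pure noise
  b0 <- simulate_bead_stack(matrix(numeric(0), 0, 3), psf,
                            volume_shape = c(16, 48, 48), noise_sd = 1e-3)
  expect_lt(max(b0$data), 1e-2)

  # two distant beads: local patches agree within noise
  beads <- rbind(c(24, 24, 24), c(24, 120, 120))
  bs <- simulate_bead_stack(beads, psf, volume_shape = c(16, 144, 144),
                            noise_sd = 1e-4, seed = 8L)
  p1 <- bs$data[25 + (-8:8), 25 + (-8:8), 9 + (-4:4)]
  p2 <- bs$data[121 + (-8:8), 121 + (-8:8), 9 + (-4:4)]
  expect_gt(cor(as.vector(p1), as.vector(p2)), 0.99)

  # refuse beads closer than 4x the PSF support radius
  expect_error(simulate_bead_stack(rbind(c(24, 24, 24), c(24, 30, 30)),
                                   psf, volume_shape = c(16, 64, 64)),
               "too close")
})
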