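test_that("local energy obeys its closed forms and invariances", {
  # constant plane: no spatial variation, zero energy
  expect_true(all(local_highfreq_energy(matrix(5, 20, 20), 3) == 0))

  # unit impulse: energy at the impulse equals the squared-coefficient
  # sum of the operator once the window covers its support
  pl <- matrix(0, 21, 21)
  pl[11, 11] <- 1
  e <- local_highfreq_energy(pl, 3, "laplacian")
  expect_equal(e[11, 11], sum(highpass_kernel("laplacian")^2))
  expect_equal(max(e), e[11, 11])

  # Nyquist checkerboard outranks an equal-amplitude period-32 sinusoid
  n <- 64
  cb <- outer(1:n, 1:n, function(i, j) (-1)^(i + j))
  sine <- outer(1:n, 1:n, function(i, j) sin(2 * pi * i / 32))
  expect_gt(mean(local_highfreq_energy(cb + 2, 5)),
            mean(local_highfreq_energy(sine + 2, 5)))

  # shift invariance to an additive constant; quadratic intensity scaling
  pl2 <- textured_plane(9, 32)
  e0 <- local_highfreq_energy(pl2, 4)
  expect_equal(local_highfreq_energy(pl2 + 17, 4), e0, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(local_highfreq_energy(3 * pl2, 4), 9 * e0,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(local_highfreq_energy(matrix(0, 5, 5), 3), "window larger")
})

test_that("segmentation matches the brute-force per-voxel oracle bit-exactly", {
  st <- biopsy3d:::with_seed(21, channel_stack(
    array(runif(8 * 16 * 16), c(16, 16, 8)), spacing_um = c(1, 1, 1)))
  for (fid in c("laplacian", "dog")) {
    kern <- highpass_kernel(fid)
    seg <- segment_tissue(st, window_radius_px = 3, threshold = 0.5,
                          filter_id = fid, cleanup_radius = 0)
    for (k in seq_len(8)) {
      oracle <- naive_local_energy(st$data[, , k], 3, kern)
      expect_identical(seg$energy[, , k], oracle)
      expect_identical(seg$mask[, , k], oracle > 0.5)
    }
  }
})

test_that("thresholding semantics: monotonicity, noise floor, degeneracy", {
  st <- biopsy3d:::with_seed(13, channel_stack(
    array(runif(4 * 24 * 24, 0, 1e-3), c(24, 24, 4))))
  # all-noise stack below an explicit threshold: empty mask
  seg <- segment_tissue(st, threshold = 1, cleanup_radius = 0)
  expect_equal(sum(seg$mask), 0)

  # raising the threshold never adds tissue voxels
  bf <- small_bf()
  s1 <- segment_tissue(bf, threshold = 1e-4, cleanup_radius = 0)
  s2 <- segment_tissue(bf, threshold = 1e-3, cleanup_radius = 0)
  expect_true(all(s1$mask | !s2$mask))
  expect_lte(sum(s2$mask), sum(s1$mask))

  # constant stack cannot be auto-thresholded
  flat <- channel_stack(array(1, c(16, 16, 8)))
  expect_error(segment_tissue(flat, threshold = "auto"),
               "degenerate energy histogram")

  expect_s3_class(glance(s1), "tbl_df")
  expect_equal(glance(s1)$n_tissue_voxels, sum(s1$mask))
})

test_that("simulated cavity is recovered as an enclosed component", {
  truth <- small_truth()
  seg <- segment_tissue(small_bf())
  expect_gt(dice_coefficient(seg$mask, truth$tissue_mask), 0.7)
  cav <- extract_cavities(seg, min_diameter_um = 20)
  found <- match_cavities(cav$report, truth$cavity_table, tol_um = 10)
  expect_true(all(found))
})

test_that("cavity extraction follows its morphometry contract", {
  sp <- c(dz = 1, dy = 1, dx = 1)
  # all tissue: empty report
  seg_all <- structure(list(mask = array(TRUE, c(10, 10, 10)),
                            threshold = 0, spacing_um = sp),
                       class = "tissue_segmentation")
  expect_equal(nrow(extract_cavities(seg_all)$report), 0)

  # single interior voxel at unit spacing: closed-form diameter
  m <- array(TRUE, c(7, 7, 7))
  m[4, 4, 4] <- FALSE
  seg1 <- structure(list(mask = m, threshold = 0, spacing_um = sp),
                    class = "tissue_segmentation")
  rep1 <- extract_cavities(seg1, min_diameter_um = 0)$report
  expect_equal(rep1$equivalent_diameter_um, (6 / pi)^(1 / 3),
               tolerance = 1e-12)
  expect_true(rep1$enclosed)
  expect_equal(rep1$centroid_z_um, 3)  # 0-based index times spacing

  # two spherical cavities of 60 and 30 um with a 50 um floor:
  # exactly one enclosed cavity survives the filter
  d <- c(96, 96, 96)
  mask <- array(TRUE, d)
  carve <- function(mask, c0, r) {
    co <- lapply(d, function(n) seq_len(n) - 1)
    d2 <- outer(outer((co[[1]] - c0[1])^2, (co[[2]] - c0[2])^2, `+`),
                (co[[3]] - c0[3])^2, `+`)
    mask[d2 <= r^2] <- FALSE
    mask
  }
  mask <- carve(mask, c(32, 32, 48), 30)
  mask <- carve(mask, c(70, 70, 48), 15)
  seg2 <- structure(list(mask = mask, threshold = 0, spacing_um = sp),
                    class = "tissue_segmentation")
  rep2 <- extract_cavities(seg2, min_diameter_um = 50)$report
  expect_equal(nrow(rep2), 1)
  expect_true(rep2$enclosed)
  expect_equal(rep2$centroid_y_um, 32, tolerance = 0.1)

  # a component touching the volume boundary is surrounding medium
  m3 <- array(TRUE, c(20, 20, 20))
  m3[1:5, 10, 10] <- FALSE
  rep3 <- extract_cavities(structure(
    list(mask = m3, threshold = 0, spacing_um = sp),
    class = "tissue_segmentation"), min_diameter_um = 0)$report
  expect_false(rep3$enclosed)

  # labels are nonzero only where the mask is false
  cav2 <- extract_cavities(seg2, min_diameter_um = 0)
  expect_true(all(cav2$labels[mask] == 0L))
  expect_s3_class(tidy(cav2), "tbl_df")
})
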