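test_that("empty volumes render pure background", {
  ch <- render_channel(array(0, c(16, 16, 16)), color = c(1, 0, 0),
                       tf = tf_linear(0.1, 1, 0.5))
  st <- render_settings(width = 24, height = 24,
                        background = c(0.2, 0.3, 0.4),
                        spacing_um = c(1, 1, 1))
  img <- render(ch, st)
  expect_equal(max(abs(sweep(unclass(img), 3, c(0.2, 0.3, 0.4)))), 0)
  expect_error(render(list(), st), "empty channel")
})

test_that("a single opaque voxel projects to its predicted pixel", {
  vol <- array(0, c(16, 16, 16))
  vol[5, 11, 8] <- 1   # (y, x, z) = (4, 10, 7) 0-based
  ch <- render_channel(vol, color = c(1, 1, 1), tf = tf_step(0.5, 1))
  st <- render_settings(width = 32, height = 32, step_vox = 1,
                        spacing_um = c(1, 1, 1), pixel_um = 1)
  img <- render(ch, st)
  lit <- which(unclass(img)[, , 1] > 0.2, arr.ind = TRUE)
  expect_gt(nrow(lit), 0)
  pred <- project_voxel(st, c(16, 16, 16), c(7, 4, 10))
  ctr <- colMeans(lit) - 1   # 0-based
  expect_lt(abs(ctr[1] - pred["row"]), 1.1)
  expect_lt(abs(ctr[2] - pred["col"]), 1.1)
  # the lit region is a single compact patch
  expect_lt(max(lit[, 1]) - min(lit[, 1]), 3)
  expect_lt(max(lit[, 2]) - min(lit[, 2]), 3)
})

test_that("front-to-back compositing matches the closed form", {
  vol <- array(0, c(8, 8, 8))
  vol[4, 4, 2] <- 1
  vol[4, 4, 5] <- 1   # two voxels on one head-on ray
  ch <- render_channel(vol, color = c(0.8, 0.4, 0.2),
                       tf = tf_step(0.5, 0.5))
  st <- render_settings(width = 8, height = 8, step_vox = 1,
                        background = c(0, 0, 1), spacing_um = c(1, 1, 1),
                        pixel_um = 1)
  img <- unclass(render(ch, st))
  # alpha 0.5 twice: C = 0.5 c + 0.25 c + 0.25 bg
  expect_equal(img[4, 4, ], 0.75 * c(0.8, 0.4, 0.2) + 0.25 * c(0, 0, 1),
               tolerance = 1e-6)
  # off-ray pixels show the background
  expect_equal(img[1, 1, ], c(0, 0, 1), tolerance = 1e-6)
})

test_that("binary-alpha rendering equals the mask silhouette", {
  mask <- small_truth()$cavity_labels > 0
  d <- dim(mask)
  ch <- render_channel(mask, color = c(1, 1, 1), tf = tf_step(0.5, 1))
  st <- render_settings(width = d[2], height = d[1], step_vox = 1,
                        spacing_um = c(1, 1, 1), pixel_um = 1)
  img <- unclass(render(ch, st))
  sil <- apply(mask, c(1, 2), any)
  expect_identical(img[, , 1] > 0.5, sil)
})

test_that("low-opacity compositing is approximately linear", {
  vol <- small_truth()$fl1_truth
  ch_hi <- render_channel(vol, c(0, 1, 0), tf_linear(0, 1, 0.02))
  ch_lo <- render_channel(vol, c(0, 1, 0), tf_linear(0, 1, 0.01))
  st <- render_settings(width = 48, height = 48, spacing_um = c(3, 1, 1))
  hi <- sum(unclass(render(ch_hi, st)))
  lo <- sum(unclass(render(ch_lo, st)))
  expect_lt(abs(hi / lo - 2), 0.2)
})

test_that("rotation series geometry and determinism hold", {
  vol <- array(0, c(32, 32, 32))
  vol[16, 24, 16] <- 1  # off-center blob (x offset +8 voxels)
  ch <- render_channel(vol, c(1, 1, 1), tf_step(0.5, 1))
  st <- render_settings(width = 48, height = 48, step_vox = 0.5,
                        spacing_um = c(1, 1, 1), pixel_um = 1)
  frames <- render_rotation_series(ch, st, n_frames = 4)
  expect_length(frames, 4)
  expect_identical(unclass(frames[[1]]), unclass(render(ch, st)))

  # the blob's projected centroid stays on a circle around the image
  # center as the sample rotates about the vertical axis
  cents <- lapply(frames, function(f) {
    lit <- which(unclass(f)[, , 1] > 0.2, arr.ind = TRUE)
    colMeans(lit)
  })
  ctr <- (48 + 1) / 2
  radii <- vapply(cents, function(cc) abs(cc[2] - ctr), numeric(1))
  expect_lt(max(abs(radii[c(1, 3)] - 7.5)), 1.5)  # head-on and reversed
  expect_lt(radii[2], 1.5)                  # side views project on-center
  expect_lt(radii[4], 1.5)
  # vertical coordinate is unchanged by azimuthal rotation
  rows <- vapply(cents, function(cc) cc[1], numeric(1))
  expect_lt(max(rows) - min(rows), 1.5)

  # determinism
  expect_identical(unclass(render(ch, st)), unclass(render(ch, st)))

  # a centered sphere renders rotation-invariantly (histograms within 2%)
  sph <- array(0, c(32, 32, 32))
  co <- (1:32) - 16.5
  d2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  sph[d2 <= 100] <- 1
  chs <- render_channel(sph, c(1, 1, 1), tf_linear(0, 1, 0.05))
  fr <- render_rotation_series(chs, st, n_frames = 3)
  sums <- vapply(fr, function(f) sum(unclass(f)), numeric(1))
  expect_lt(max(abs(sums / mean(sums) - 1)), 0.02)
})
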