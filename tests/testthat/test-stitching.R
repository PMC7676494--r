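test_that("affine transforms compose, invert and serialize", {
  t <- affine3d(matrix(c(1.02, 0.01, 0, -0.02, 0.98, 0.01, 0, 0, 1),
                       3, 3, byrow = TRUE), c(2.5, -1, 7))
  p <- matrix(c(3, 4, 5, -1, 0, 2), 2, 3, byrow = TRUE)
  back <- apply_affine(invert_affine(t), apply_affine(t, p))
  expect_equal(back, p, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".txt")
  write_affine(t, path)
  t2 <- read_affine(path)
  expect_equal(t2$matrix, t$matrix, ignore_attr = TRUE)
  expect_equal(t2$translation, t$translation)

  expect_error(affine3d(matrix(0, 3, 3)), "singular")
})

test_that("affine estimation is exact on clean data and robust to outliers", {
  truth <- affine3d(matrix(c(0.98, 0.03, -0.01,
                             -0.02, 1.05, 0.02,
                             0.01, 0.00, 0.97), 3, 3, byrow = TRUE),
                    c(4, -12, 30))
  mkmatches <- function(B, A) {
    tibble::tibble(idx_a = seq_len(nrow(A)), idx_b = seq_len(nrow(B)),
                   dist = 0, za = A[, 1], ya = A[, 2], xa = A[, 3],
                   zb = B[, 1], yb = B[, 2], xb = B[, 3])
  }
  B <- biopsy3d:::with_seed(10, matrix(runif(60, 0, 60), 20, 3))
  A <- apply_affine(truth, B)

  est <- estimate_affine(mkmatches(B, A), inlier_tol_voxels = 1, seed = 1)
  expect_equal(est$matrix, truth$matrix, tolerance = 1e-6)
  expect_equal(est$translation, truth$translation, tolerance = 1e-6)

  # identity correspondences give the identity transform
  id <- estimate_affine(mkmatches(B, B), inlier_tol_voxels = 1, seed = 1)
  expect_equal(id$matrix, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)

  # 30% scattered outliers: inlier residuals below half a voxel,
  # across 20 seeded trials
  for (s in 1:20) {
    Bs <- biopsy3d:::with_seed(100 + s, matrix(runif(90, 0, 60), 30, 3))
    As <- apply_affine(truth, Bs)
    out_idx <- biopsy3d:::with_seed(200 + s, sample.int(30, 9))
    As[out_idx, ] <- As[out_idx, ] +
      biopsy3d:::with_seed(300 + s, matrix(runif(27, 5, 25), 9, 3))
    est_s <- estimate_affine(mkmatches(Bs, As), inlier_tol_voxels = 1,
                             seed = s)
    resid <- attr(est_s, "residuals")
    expect_lt(max(resid[setdiff(seq_len(30), out_idx)]), 0.5)
  }

  # degenerate configurations are refused
  flatB <- cbind(0, matrix(runif(20), 10, 2))
  expect_error(estimate_affine(mkmatches(flatB, flatB), seed = 1),
               "coplanar|degenerate")
  expect_error(estimate_affine(mkmatches(B[1:3, ], A[1:3, ]), seed = 1),
               "at least 4")
})

test_that("keypoint detection finds blobs and is translation-equivariant", {
  # constant volume: nothing to detect
  expect_equal(nrow(detect_keypoints(array(1, c(32, 32, 32)))), 0)

  d <- c(64, 64, 64)
  centers <- biopsy3d:::with_seed(5, cbind(sample(15:50, 10),
                                           sample(15:50, 10),
                                           sample(15:50, 10)))
  co <- 1:64
  vol <- array(0, d)
  for (i in 1:10) {
    vol <- vol + outer(outer(exp(-(co - centers[i, 1])^2 / 8),
                             exp(-(co - centers[i, 2])^2 / 8)),
                       exp(-(co - centers[i, 3])^2 / 8))
  }
  kp <- detect_keypoints(vol, n_octaves = 2)
  expect_gte(nrow(kp), 10)
  for (i in 1:10) {
    dmin <- min(sqrt((kp$y - (centers[i, 1] - 1))^2 +
                     (kp$x - (centers[i, 2] - 1))^2 +
                     (kp$z - (centers[i, 3] - 1))^2))
    expect_lt(dmin, 2)
  }
  expect_true(all(vapply(kp$descriptor,
                         function(v) abs(sum(v^2) - 1) < 1e-9,
                         logical(1))))

  # integer translation moves matched keypoints by the same offset
  off <- c(5, 3, 8)  # (y, x, z)
  vol2 <- array(0, d)
  vol2[(off[1] + 1):64, (off[2] + 1):64, (off[3] + 1):64] <-
    vol[1:(64 - off[1]), 1:(64 - off[2]), 1:(64 - off[3])]
  kp2 <- detect_keypoints(vol2, n_octaves = 2)
  mm <- match_landmarks(kp, kp2)
  expect_gte(nrow(mm), 8)
  expect_lt(median(abs(mm$yb - mm$ya - off[1])), 0.5)
  expect_lt(median(abs(mm$xb - mm$xa - off[2])), 0.5)
  expect_lt(median(abs(mm$zb - mm$za - off[3])), 0.5)

  expect_error(detect_keypoints(array(0, c(8, 32, 32))), "at least 16")
})

test_that("descriptor matching honors identity, orthogonality and ratio", {
  mkkp <- function(desc, n) {
    tibble::tibble(z = seq_len(n), y = seq_len(n), x = seq_len(n),
                   sigma_um = 1, octave = 1L, response = 1,
                   descriptor = desc)
  }
  base <- lapply(1:6, function(i) {
    v <- numeric(16); v[i] <- 1; v
  })
  kpa <- mkkp(base, 6)
  mm <- match_landmarks(kpa, kpa)
  expect_equal(nrow(mm), 6)
  expect_equal(mm$idx_a, mm$idx_b)

  # orthogonal descriptors across sets: every pairing is equally bad,
  # so the ratio test filters everything
  other <- lapply(7:12, function(i) {
    v <- numeric(16); v[i] <- 1; v
  })
  expect_equal(nrow(match_landmarks(kpa, mkkp(other, 6))), 0)
  expect_error(match_landmarks(kpa[0, ], kpa), "non-empty")
})

test_that("stitching is lossless on identity and exact on translation", {
  st <- small_bf()
  # identity on identical volumes: reference voxels verbatim
  sr <- stitch_volumes(st, st, affine3d())
  expect_identical(sr$stack$data, st$data)
  expect_true(all(sr$provenance == 3L))

  # disjoint tiles under pure integer translation: voxel-exact union
  a <- channel_stack(st$data[, , 1:8], spacing_um = st$spacing_um)
  b <- channel_stack(st$data[, , 9:16], spacing_um = st$spacing_um)
  t_shift <- affine3d(diag(3), c(8, 0, 0))  # mov z0 sits at ref z8
  sr2 <- stitch_volumes(a, b, t_shift)
  expect_equal(unname(stack_dim(sr2$stack)), c(16, 96, 96))
  expect_equal(sr2$stack$data[, , 1:8], a$data, tolerance = 1e-12)
  expect_equal(sr2$stack$data[, , 9:16], b$data, tolerance = 1e-12)
  expect_true(all(sr2$provenance[, , 1:8] == 1L))
  expect_true(all(sr2$provenance[, , 9:16] == 2L))

  expect_error(stitch_volumes(a, b, affine3d(matrix(1e-20 * diag(3), 3))),
               "singular")
})
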