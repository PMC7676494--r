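#' 3D affine transform
#'
#' A 12-parameter mapping between tile coordinate frames. Points are rows
#' of `(z, y, x)` 0-based voxel coordinates; the transform maps moving-tile
#' coordinates into the reference frame: `p_ref = p_mov %*% t(matrix) +
#' translation`.
#'
#' @param matrix Invertible 3x3 linear part (rows/cols ordered z, y, x).
#' @param translation Length-3 offset.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(3, 3)), length(translation) == 3L)
  if (abs(det(matrix)) < 1e-12)
    stop("affine linear part is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> linear part:\n")
  print(round(x$matrix, 6))
  cat("translation:", round(x$translation, 4), "\n")
  invisible(x)
}

#' Apply an affine transform to points
#' @param t An `affine3d`.
#' @param points Matrix with rows `(z, y, x)`.
#' @return Transformed points.
#' @export
apply_affine <- function(t, points) {
  points <- rbind(points)
  sweep(points %*% t(t$matrix), 2, t$translation, `+`)
}

#' Invert an affine transform
#' @param t An `affine3d`.
#' @return The inverse `affine3d`.
#' @export
invert_affine <- function(t) {
  li <- solve(t$matrix)
  affine3d(li, -as.numeric(li %*% t$translation))
}

#' Serialize / deserialize an affine transform as 12 numbers
#'
#' Row-major 3x4 `[linear | translation]` in a plain text file.
#'
#' @param t An `affine3d`.
#' @param path File path.
#' @return `path` / the `affine3d`.
#' @export
write_affine <- function(t, path) {
  m <- cbind(t$matrix, t$translation)
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 17),
                                           collapse = " ")), path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(all(dim(m) == c(3, 4)))
  affine3d(m[, 1:3], m[, 4])
}

# max over the 26 spatial neighbors (and optionally the center) using
# array shifts; borders padded with -Inf so they can never be extrema
shift_pad <- function(a, dz, dy, dx, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  rng <- function(n, off) {
    list(dst = max(1, 1 + off):min(n, n + off),
         src = max(1, 1 - off):min(n, n - off))
  }
  ry <- rng(d[1], dy); rx <- rng(d[2], dx); rz <- rng(d[3], dz)
  out[ry$dst, rx$dst, rz$dst] <- a[ry$src, rx$src, rz$src]
  out
}

neighborhood_extreme <- function(a, include_center, fun = pmax) {
  init <- if (identical(fun, pmax)) -Inf else Inf
  acc <- array(init, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!include_center && dz == 0 && dy == 0 && dx == 0) next
    acc <- fun(acc, shift_pad(a, dz, dy, dx, fill = init))
  }
  acc
}

#' Detect 3D scale-invariant keypoints
#'
#' Difference-of-Gaussians scale-space extrema in a volume, with
#' low-contrast rejection and suppression of edge-like responses via the
#' ratio of Hessian eigenvalues. Anisotropic voxels are handled by
#' resampling to an isotropic grid at the coarsest spacing before
#' detection; returned positions are in the input volume's 0-based voxel
#' coordinates. Descriptors are magnitude-weighted gradient orientation
#' histograms (8 azimuth x 4 elevation bins over 2x2x2 subblocks of a
#' 8-voxel cube), normalized to unit length.
#'
#' @param volume A `channel_stack` or 3D array (then treated as
#'   isotropic).
#' @param n_octaves Number of scale-space octaves.
#' @param contrast_threshold Minimum absolute DoG response (volume is
#'   min-max normalized first).
#' @param edge_ratio Maximum allowed ratio of largest to smallest
#'   absolute Hessian eigenvalue.
#' @param base_sigma Base scale in (isotropic) voxels.
#' @param n_scales DoG levels searched per octave.
#' @param max_keypoints Keep at most this many, strongest first.
#' @return A tibble with `z`, `y`, `x` (0-based input voxel coordinates),
#'   `sigma_um` (detection scale), `octave`, `response`, and `descriptor`
#'   (list-column of unit-norm numeric vectors).
#' @export
detect_keypoints <- function(volume, n_octaves = 3,
                             contrast_threshold = 0.002, edge_ratio = 20,
                             base_sigma = 1.6, n_scales = 3,
                             max_keypoints = 2000) {
  if (inherits(volume, "channel_stack")) {
    vol <- volume$data
    sp <- volume$spacing_um
  } else {
    vol <- volume
    sp <- c(dz = 1, dy = 1, dx = 1)
  }
  d <- dim(vol)
  if (any(d < 16)) stop("volume must be at least 16 voxels per axis")

  iso <- max(sp)
  fac <- c(sp["dy"], sp["dx"], sp["dz"]) / iso  # array-axis order
  if (any(fac != 1)) {
    nd <- pmax(2L, as.integer(round((d - 1) * fac)) + 1L)
    A <- matrix(0, 3, 4)
    A[1, 1] <- iso / sp["dz"]; A[2, 2] <- iso / sp["dy"]
    A[3, 3] <- iso / sp["dx"]
    vol <- cpp_affine_resample(vol, d, nd, A, 0)$values
  }
  di <- dim(vol)
  if (min(di) / 2^(n_octaves - 1) < 8)
    stop("volume too small for ", n_octaves, " octaves")
  rng <- range(vol)
  if (rng[2] <= rng[1]) {
    return(tibble::tibble(z = numeric(), y = numeric(), x = numeric(),
                          sigma_um = numeric(), octave = integer(),
                          response = numeric(), descriptor = list()))
  }
  vol <- (vol - rng[1]) / (rng[2] - rng[1])

  kps <- list()
  base <- vol
  for (o in seq_len(n_octaves)) {
    sig <- base_sigma * 2^((seq_len(n_scales + 3) - 1) / n_scales)
    gs <- lapply(sig, function(s) gauss_blur3(base, rep(s, 3)))
    dogs <- lapply(seq_len(n_scales + 2),
                   function(k) gs[[k + 1]] - gs[[k]])
    for (k in seq_len(n_scales + 2)) {
      dk <- dogs[[k]]
      up <- neighborhood_extreme(dk, include_center = FALSE, pmax)
      lo <- neighborhood_extreme(dk, include_center = FALSE, pmin)
      # spatial extremum at its own level, with (tolerant) magnitude
      # dominance over the adjacent levels' responses at the same
      # position: adjacent DoG levels are strongly correlated, so the
      # classical strict 3x3x3x3 extremum test rejects nearly
      # everything on volumetric data
      cand <- (dk > up | dk < lo) & abs(dk) > contrast_threshold
      if (k > 1) cand <- cand & abs(dk) >= 0.9 * abs(dogs[[k - 1]])
      if (k < n_scales + 2) cand <- cand & abs(dk) >= 0.9 * abs(dogs[[k + 1]])
      # exclude a border margin (no full neighborhood / descriptor)
      db <- dim(dk)
      margin <- 5L
      cand[c(seq_len(min(margin, db[1])),
             seq(max(1, db[1] - margin + 1), db[1])), , ] <- FALSE
      cand[, c(seq_len(min(margin, db[2])),
               seq(max(1, db[2] - margin + 1), db[2])), ] <- FALSE
      cand[, , c(seq_len(min(margin, db[3])),
                 seq(max(1, db[3] - margin + 1), db[3]))] <- FALSE
      idx <- which(cand)
      if (length(idx) == 0) next
      ai <- arrayInd(idx, db)
      keep <- logical(nrow(ai))
      offs <- matrix(0, nrow(ai), 3)  # subvoxel offsets (y, x, z)
      for (i in seq_len(nrow(ai))) {
        y <- ai[i, 1]; x <- ai[i, 2]; z <- ai[i, 3]
        H <- matrix(0, 3, 3)
        H[1, 1] <- dk[y + 1, x, z] - 2 * dk[y, x, z] + dk[y - 1, x, z]
        H[2, 2] <- dk[y, x + 1, z] - 2 * dk[y, x, z] + dk[y, x - 1, z]
        H[3, 3] <- dk[y, x, z + 1] - 2 * dk[y, x, z] + dk[y, x, z - 1]
        H[1, 2] <- H[2, 1] <- (dk[y + 1, x + 1, z] - dk[y + 1, x - 1, z] -
                               dk[y - 1, x + 1, z] + dk[y - 1, x - 1, z]) / 4
        H[1, 3] <- H[3, 1] <- (dk[y + 1, x, z + 1] - dk[y + 1, x, z - 1] -
                               dk[y - 1, x, z + 1] + dk[y - 1, x, z - 1]) / 4
        H[2, 3] <- H[3, 2] <- (dk[y, x + 1, z + 1] - dk[y, x + 1, z - 1] -
                               dk[y, x - 1, z + 1] + dk[y, x - 1, z - 1]) / 4
        ev <- abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
        keep[i] <- min(ev) > 0 && max(ev) / min(ev) <= edge_ratio
        if (keep[i]) {
          # quadratic subvoxel localization of the extremum
          grad <- c((dk[y + 1, x, z] - dk[y - 1, x, z]) / 2,
                    (dk[y, x + 1, z] - dk[y, x - 1, z]) / 2,
                    (dk[y, x, z + 1] - dk[y, x, z - 1]) / 2)
          off <- tryCatch(-solve(H, grad), error = function(e) c(0, 0, 0))
          offs[i, ] <- pmax(-1, pmin(1, off))
        }
      }
      ai <- ai[keep, , drop = FALSE]
      offs <- offs[keep, , drop = FALSE]
      idx <- idx[keep]
      if (nrow(ai) == 0) next
      g_img <- gs[[k]]
      for (i in seq_len(nrow(ai))) {
        desc <- sift_descriptor(g_img, ai[i, ])
        if (is.null(desc)) next
        pos_iso <- (ai[i, c(3, 1, 2)] - 1 + offs[i, c(3, 1, 2)]) *
          2^(o - 1)  # (z, y, x), 0-based
        kps[[length(kps) + 1]] <- list(
          pos = pos_iso, sigma_um = sig[k] * 2^(o - 1) * iso,
          octave = o, response = dogs[[k]][idx[i]], descriptor = desc)
      }
    }
    # next octave: subsample the doubled-scale image
    base <- gs[[n_scales + 1]][seq(1, dim(base)[1], by = 2),
                               seq(1, dim(base)[2], by = 2),
                               seq(1, dim(base)[3], by = 2), drop = FALSE]
    if (min(dim(base)) < 16) break
  }
  if (length(kps) == 0) {
    return(tibble::tibble(z = numeric(), y = numeric(), x = numeric(),
                          sigma_um = numeric(), octave = integer(),
                          response = numeric(), descriptor = list()))
  }
  resp <- vapply(kps, function(k) abs(k$response), numeric(1))
  ord <- order(-resp)
  kps <- kps[ord]
  # deduplicate near-coincident detections across levels/octaves,
  # keeping the strongest response
  pos_all <- do.call(rbind, lapply(kps, `[[`, "pos"))
  keep <- rep(TRUE, nrow(pos_all))
  for (i in seq_len(nrow(pos_all))) {
    if (!keep[i]) next
    if (i < nrow(pos_all)) {
      later <- (i + 1):nrow(pos_all)
      d2 <- rowSums((pos_all[later, , drop = FALSE] -
                       matrix(pos_all[i, ], length(later), 3,
                              byrow = TRUE))^2)
      keep[later][d2 < 4] <- FALSE
    }
  }
  kps <- kps[keep]
  if (length(kps) > max_keypoints) kps <- kps[seq_len(max_keypoints)]
  pos <- do.call(rbind, lapply(kps, `[[`, "pos"))
  # map isotropic-grid coordinates back to input voxel coordinates
  tibble::tibble(
    z = pos[, 1] * iso / sp["dz"],
    y = pos[, 2] * iso / sp["dy"],
    x = pos[, 3] * iso / sp["dx"],
    sigma_um = vapply(kps, `[[`, numeric(1), "sigma_um"),
    octave = vapply(kps, `[[`, integer(1), "octave"),
    response = vapply(kps, function(k) k$response, numeric(1)),
    descriptor = lapply(kps, `[[`, "descriptor")
  )
}

# 256-dim orientation-histogram descriptor around voxel `at` (y, x, z)
# of a Gaussian-smoothed volume; NULL if the window exits the volume.
sift_descriptor <- function(g, at) {
  d <- dim(g)
  y <- at[1]; x <- at[2]; z <- at[3]
  if (y - 4 < 1 || y + 4 > d[1] || x - 4 < 1 || x + 4 > d[2] ||
      z - 4 < 1 || z + 4 > d[3]) return(NULL)
  w <- g[(y - 4):(y + 4), (x - 4):(x + 4), (z - 4):(z + 4)]
  gy <- (w[3:9, 2:8, 2:8] - w[1:7, 2:8, 2:8]) / 2
  gx <- (w[2:8, 3:9, 2:8] - w[2:8, 1:7, 2:8]) / 2
  gz <- (w[2:8, 2:8, 3:9] - w[2:8, 2:8, 1:7]) / 2
  mag <- sqrt(gy^2 + gx^2 + gz^2)
  az <- atan2(gy, gx)                       # (-pi, pi]
  el <- atan2(gz, sqrt(gy^2 + gx^2))        # [-pi/2, pi/2]
  bin_az <- pmin(8L, 1L + floor((az + pi) / (2 * pi) * 8))
  bin_el <- pmin(4L, 1L + floor((el + pi / 2) / pi * 4))
  # 2x2x2 spatial subblocks over the 7^3 gradient grid (split at 4)
  sub <- function(i) ifelse(i <= 4, 1L, 2L)
  iy <- sub(slice.index(mag, 1)); ix <- sub(slice.index(mag, 2))
  iz <- sub(slice.index(mag, 3))
  code <- (((iz - 1L) * 2L + (iy - 1L)) * 2L + (ix - 1L)) * 32L +
    (bin_el - 1L) * 8L + bin_az
  desc <- vapply(seq_len(256), function(b) 0, numeric(1))
  sums <- rowsum(as.vector(mag), as.vector(code))
  desc[as.integer(rownames(sums))] <- sums[, 1]
  n <- sqrt(sum(desc^2))
  if (n == 0) return(NULL)
  desc <- pmin(desc / n, 0.2)
  desc / sqrt(sum(desc^2))
}

#' Match keypoints between two volumes
#'
#' Nearest-neighbor descriptor matching with Lowe's ratio test and
#' mutual-best filtering.
#'
#' @param kpA,kpB Keypoint tibbles from [detect_keypoints()] (reference
#'   and moving tile).
#' @param ratio_threshold Maximum allowed ratio of best to second-best
#'   descriptor distance (default 0.8).
#' @return A tibble of correspondences with columns `idx_a`, `idx_b`,
#'   `dist`, and the matched positions `za, ya, xa, zb, yb, xb`.
#' @export
match_landmarks <- function(kpA, kpB, ratio_threshold = 0.8) {
  if (nrow(kpA) == 0 || nrow(kpB) == 0)
    stop("both keypoint sets must be non-empty")
  A <- do.call(rbind, kpA$descriptor)
  B <- do.call(rbind, kpB$descriptor)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  nn_b_for_a <- apply(d2, 1, which.min)
  nn_a_for_b <- apply(d2, 2, which.min)
  rows <- list()
  for (i in seq_len(nrow(A))) {
    j <- nn_b_for_a[i]
    if (nn_a_for_b[j] != i) next          # mutual best
    ds <- sort(d2[i, ], partial = min(2, ncol(d2)))
    best <- sqrt(ds[1])
    second <- if (ncol(d2) >= 2) sqrt(ds[2]) else Inf
    if (second > 0 && best / second > ratio_threshold) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      idx_a = i, idx_b = j, dist = best,
      za = kpA$z[i], ya = kpA$y[i], xa = kpA$x[i],
      zb = kpB$z[j], yb = kpB$y[j], xb = kpB$x[j])
  }
  if (length(rows) == 0) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer(),
                          dist = numeric(), za = numeric(), ya = numeric(),
                          xa = numeric(), zb = numeric(), yb = numeric(),
                          xb = numeric()))
  }
  dplyr::bind_rows(rows)
}

# closed-form least-squares affine fit mapping B points onto A points;
# NULL if the configuration is rank-deficient (coplanar)
fit_affine_ls <- function(A_pts, B_pts) {
  X <- cbind(B_pts, 1)
  if (qr(X)$rank < 4) return(NULL)
  M <- solve(crossprod(X), crossprod(X, A_pts))
  affine3d(t(M[1:3, ]), M[4, ])
}

#' Robust affine estimation from correspondences
#'
#' Repeated minimal samples of 4 correspondences, closed-form affine
#' solve, consensus counting at `inlier_tol_voxels`, and a final
#' least-squares refit on the largest consensus set. Deterministic given
#' `seed`. Descriptor matching always yields outliers, so robust
#' consensus wraps the plain linear solve.
#'
#' @param correspondences Tibble from [match_landmarks()].
#' @param inlier_tol_voxels Residual (voxels) below which a
#'   correspondence supports a candidate transform.
#' @param seed Integer seed for the sampling.
#' @param n_iter Number of minimal samples.
#' @return An `affine3d` mapping moving-tile coordinates into the
#'   reference frame, with attributes `inliers` (logical vector) and
#'   `residuals`.
#' @export
estimate_affine <- function(correspondences, inlier_tol_voxels = 1,
                            seed = 1L, n_iter = 1000) {
  m <- correspondences
  if (nrow(m) < 4) stop("need at least 4 correspondences")
  A_pts <- cbind(m$za, m$ya, m$xa)
  B_pts <- cbind(m$zb, m$yb, m$xb)
  if (qr(cbind(B_pts, 1))$rank < 4)
    stop("degenerate (coplanar) correspondence configuration")
  n <- nrow(m)
  resid_of <- function(t) {
    pred <- apply_affine(t, B_pts)
    sqrt(rowSums((pred - A_pts)^2))
  }
  best <- NULL; best_n <- -1L; best_err <- Inf
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 4)
      t <- fit_affine_ls(A_pts[s, , drop = FALSE], B_pts[s, , drop = FALSE])
      if (is.null(t)) next
      r <- resid_of(t)
      inl <- r < inlier_tol_voxels
      ni <- sum(inl)
      if (ni > best_n || (ni == best_n && mean(r[inl]) < best_err)) {
        best <- inl; best_n <- ni
        best_err <- if (ni > 0) mean(r[inl]) else Inf
      }
    }
  })
  if (is.null(best) || best_n < 4)
    stop("no consensus found: fewer than 4 inliers")
  t <- fit_affine_ls(A_pts[best, , drop = FALSE], B_pts[best, , drop = FALSE])
  if (is.null(t)) stop("degenerate consensus set")
  r <- resid_of(t)
  attr(t, "inliers") <- r < inlier_tol_voxels
  attr(t, "residuals") <- r
  t
}

#' Estimate the transform between two overlapping tiles
#'
#' Convenience wrapper chaining keypoint detection on the bright-field
#' volumes of both tiles, descriptor matching and robust affine
#' estimation.
#'
#' @param ref_bf,mov_bf `channel_stack`s of the two tiles' bright-field
#'   channel.
#' @param ... Passed to [detect_keypoints()].
#' @param ratio_threshold Passed to [match_landmarks()].
#' @param inlier_tol_voxels,seed,n_iter Passed to [estimate_affine()].
#' @return An `affine3d` (moving to reference frame) with attribute
#'   `matches` (the correspondence tibble).
#' @export
estimate_tile_transform <- function(ref_bf, mov_bf, ...,
                                    ratio_threshold = 0.8,
                                    inlier_tol_voxels = 2, seed = 1L,
                                    n_iter = 1000) {
  kpa <- detect_keypoints(ref_bf, ...)
  kpb <- detect_keypoints(mov_bf, ...)
  mm <- match_landmarks(kpa, kpb, ratio_threshold)
  t <- estimate_affine(mm, inlier_tol_voxels, seed = seed, n_iter = n_iter)
  attr(t, "matches") <- mm
  t
}

#' Stitch two overlapping tiles
#'
#' The output grid is the union bounding box of both tiles in the
#' reference frame. Reference voxels are copied verbatim; the moving tile
#' is resampled by tri-linear interpolation under the affine transform;
#' where both tiles are defined the reference tile's voxels are kept
#' (seam-visible and deterministic; `blend = "linear"` averages instead).
#'
#' @param ref,mov `channel_stack`s of the same channel.
#' @param t An `affine3d` mapping `mov` coordinates into `ref`'s frame.
#' @param blend `"reference"` (default) or `"linear"`.
#' @return A list of class `stitch_result`: `stack` (the fused
#'   `channel_stack`), `provenance` (integer array: 0 none, 1 ref, 2 mov,
#'   3 overlap), and `offset_voxels`, the `(z, y, x)` coordinate of the
#'   output origin in the reference frame.
#' @export
stitch_volumes <- function(ref, mov, t, blend = c("reference", "linear")) {
  blend <- match.arg(blend)
  stopifnot(inherits(ref, "channel_stack"), inherits(mov, "channel_stack"))
  dr <- dim(ref$data); dm <- dim(mov$data)
  nref <- c(dr[3], dr[1], dr[2])  # (z, y, x)
  nmov <- c(dm[3], dm[1], dm[2])
  corners <- as.matrix(expand.grid(z = c(0, nmov[1] - 1),
                                   y = c(0, nmov[2] - 1),
                                   x = c(0, nmov[3] - 1)))
  tc <- apply_affine(t, corners)
  lo <- floor(pmin(apply(tc, 2, min), 0))
  hi <- ceiling(pmax(apply(tc, 2, max), nref - 1))
  nout <- as.integer(hi - lo + 1)              # (z, y, x)
  odim <- c(nout[2], nout[3], nout[1])         # array (ny, nx, nz)

  ti <- invert_affine(t)
  A <- cbind(ti$matrix, as.numeric(ti$matrix %*% lo) + ti$translation)
  rs <- cpp_affine_resample(mov$data, dim(mov$data), odim, A, 0)
  out <- rs$values
  prov <- array(0L, odim)
  prov[rs$inside] <- 2L

  # reference block position inside the output grid (integer placement)
  oz <- seq_len(nref[1]) - lo[1]; oy <- seq_len(nref[2]) - lo[2]
  ox <- seq_len(nref[3]) - lo[3]
  mov_block <- out[oy, ox, oz, drop = FALSE]
  prov_block <- prov[oy, ox, oz, drop = FALSE]
  both <- prov_block == 2L
  ref_block <- ref$data
  if (blend == "linear")
    ref_block[both] <- (ref$data[both] + mov_block[both]) / 2
  prov_block[] <- ifelse(both, 3L, 1L)
  out[oy, ox, oz] <- ref_block
  prov[oy, ox, oz] <- prov_block

  structure(list(
    stack = channel_stack(pmax(out, 0), spacing_um = ref$spacing_um,
                          channel = ref$channel,
                          wavelength_nm = ref$wavelength_nm),
    provenance = prov, offset_voxels = as.numeric(lo)
  ), class = "stitch_result")
}
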