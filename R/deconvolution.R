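#' 3D point-spread-function model
#'
#' A normalized, non-negative 3D blur kernel with physical voxel spacing.
#' The kernel array uses dim `(ny, nx, nz)` with odd extents; `center` is
#' the 1-based voxel index `(z, y, x)` of the peak.
#'
#' @param kernel Non-negative 3D array.
#' @param spacing_um `(dz, dy, dx)` in um.
#' @param normalize If `TRUE` (default), scale the kernel to unit sum;
#'   otherwise require it to already sum to 1.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(kernel, spacing_um = default_spacing(),
                      normalize = TRUE) {
  stopifnot(length(dim(kernel)) == 3L)
  if (any(!is.finite(kernel)) || any(kernel < 0))
    stop("PSF kernel must be finite and non-negative")
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel must have positive total flux")
  if (normalize) kernel <- kernel / s
  else if (abs(s - 1) > 1e-8) stop("PSF kernel does not sum to 1")
  peak <- which.max(kernel)
  idx <- arrayInd(peak, dim(kernel))
  structure(list(kernel = kernel,
                 spacing_um = check_spacing(spacing_um),
                 center = c(z = idx[3], y = idx[1], x = idx[2])),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<psf_model> %d x %d x %d voxels (ny, nx, nz), peak at (z, y, x) = (%d, %d, %d)\n",
              d[1], d[2], d[3], x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Gaussian defocus PSF
#'
#' Synthesizes a 3D PSF from a [defocus_model()]: each axial slice is a
#' lateral Gaussian whose sd grows with the slice's defocus distance,
#' under a Gaussian axial envelope. This is the blur model the phantom's
#' fluorescence simulation uses; it is also a convenient stand-in when no
#' bead stack is available.
#'
#' @param defocus A [defocus_model()].
#' @param spacing_um `(dz, dy, dx)` um.
#' @param axial_sigma_um Axial envelope sd in um.
#' @param truncate Kernel support is cut at `truncate` sd.
#' @return A `psf_model`.
#' @export
defocus_psf <- function(defocus = defocus_model(),
                        spacing_um = default_spacing(),
                        axial_sigma_um = 6, truncate = 3) {
  spacing_um <- check_spacing(spacing_um)
  kz <- ceiling(truncate * axial_sigma_um / spacing_um["dz"])
  zoff <- (-kz:kz) * spacing_um["dz"]
  sig <- defocus$blur_sigma_at_focus_um +
    defocus$blur_growth_per_um * abs(zoff)
  kr_y <- ceiling(truncate * max(sig) / spacing_um["dy"])
  kr_x <- ceiling(truncate * max(sig) / spacing_um["dx"])
  yy <- (-kr_y:kr_y) * spacing_um["dy"]
  xx <- (-kr_x:kr_x) * spacing_um["dx"]
  kern <- array(0, c(length(yy), length(xx), length(zoff)))
  for (k in seq_along(zoff)) {
    g <- outer(exp(-yy^2 / (2 * sig[k]^2)), exp(-xx^2 / (2 * sig[k]^2)))
    kern[, , k] <- exp(-zoff[k]^2 / (2 * axial_sigma_um^2)) * g / sum(g)
  }
  psf_model(kern, spacing_um)
}

#' Estimate an experimental PSF from a bead calibration stack
#'
#' Detects fluorescent beads as bright connected components well above the
#' background, extracts a patch around each centroid, subtracts the
#' background, averages the aligned patches, clips negatives and
#' normalizes to unit flux. The result is the image of a bead (bead
#' sphere convolved with the optical PSF), which is what Richardson-Lucy
#' deconvolution of bead-calibrated data expects.
#'
#' @param bead_stack A `channel_stack` of the bead acquisition.
#' @param bead_diameter_um Nominal bead diameter (used only for reporting).
#' @param patch_radius_um Half-size of the extracted patch, in um.
#' @param detection_nsd Detection threshold in units of background noise
#'   sd above the background level.
#' @return A `psf_model`.
#' @export
estimate_psf <- function(bead_stack, bead_diameter_um = 3,
                         patch_radius_um = 12, detection_nsd = 5) {
  stopifnot(inherits(bead_stack, "channel_stack"))
  data <- bead_stack$data
  d <- dim(data)
  sp <- bead_stack$spacing_um
  bg <- median(data)
  # robust noise scale: 90th percentile of absolute deviations (zero
  # clipping and sparse bright beads break a plain MAD)
  noise <- unname(quantile(abs(data - bg), 0.9)) / 1.2816
  # floor at a fraction of the peak so near-noiseless stacks still
  # isolate the beads rather than their faint blur tails
  thr <- max(bg + detection_nsd * max(noise, 1e-12),
             bg + 0.1 * (max(data) - bg))
  mask <- data > thr
  if (!any(mask)) stop("no beads found above the detection threshold")
  labels <- cpp_label3d(mask, dim(data), 26L)
  nlab <- max(labels)
  cent <- matrix(0, nlab, 3)  # (z, y, x) in voxels, 1-based
  for (i in seq_len(nlab)) {
    idx <- which(labels == i)
    w <- data[idx] - bg
    ai <- arrayInd(idx, d)
    cent[i, ] <- c(sum(ai[, 3] * w), sum(ai[, 1] * w), sum(ai[, 2] * w)) / sum(w)
  }
  rv <- pmax(1L, round(patch_radius_um / sp))  # (z, y, x) radii in voxels
  names(rv) <- c("z", "y", "x")
  cent_um <- sweep(cent, 2, sp, `*`)
  if (nlab >= 2 && min(stats::dist(cent_um)) < 2 * patch_radius_um)
    stop("overlapping beads within the patch radius")
  patches <- list()
  for (i in seq_len(nlab)) {
    c0 <- round(cent[i, ])
    if (c0[1] - rv[1] < 1 || c0[1] + rv[1] > d[3] ||
        c0[2] - rv[2] < 1 || c0[2] + rv[2] > d[1] ||
        c0[3] - rv[3] < 1 || c0[3] + rv[3] > d[2])
      next  # too close to the stack border for a full patch
    patches[[length(patches) + 1]] <-
      data[(c0[2] - rv[2]):(c0[2] + rv[2]),
           (c0[3] - rv[3]):(c0[3] + rv[3]),
           (c0[1] - rv[1]):(c0[1] + rv[1])]
  }
  if (length(patches) == 0L)
    stop("no beads found with a full patch inside the stack")
  avg <- Reduce(`+`, patches) / length(patches) - bg
  avg[avg < 0] <- 0
  psf_model(avg, spacing_um = sp)
}

# embed an odd-sized centered kernel into padded dims with its center at
# the DFT origin, and return its transfer function
psf_otf <- function(kernel, dp) {
  dk <- dim(kernel)
  ctr <- (dk + 1) / 2
  pk <- array(0, dp)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  # roll so the kernel center lands at index (1, 1, 1)
  roll <- function(a, shift) {
    idx <- lapply(seq_along(shift), function(i) {
      n <- dim(a)[i]
      ((seq_len(n) - 1 + shift[i]) %% n) + 1
    })
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  fft(roll(pk, ctr - 1))
}

#' Richardson-Lucy deconvolution
#'
#' The classical multiplicative maximum-likelihood update for Poisson-like
#' imaging: `e <- e * ((obs / (e %conv% psf)) %conv% psf_flipped)`,
#' initialized at the observed data. Convolutions are computed in the
#' frequency domain after reflective padding by half the PSF support, so
#' boundary voxels see mirrored context rather than wrap-around. The
#' estimate stays non-negative at every iteration, and with a unit-sum PSF
#' total flux is conserved away from the boundaries.
#'
#' @param observed A `channel_stack` or non-negative 3D array.
#' @param psf A `psf_model`; the kernel must sum to 1 (the function
#'   refuses rather than silently renormalizing).
#' @param iterations Maximum iterations (default 25).
#' @param epsilon Floor applied to the re-blurred estimate in the ratio.
#' @param tol Early stop when the mean relative change of the estimate
#'   falls below `tol`; `0` disables.
#' @return Deconvolved data of the same class as `observed`.
#' @export
richardson_lucy <- function(observed, psf, iterations = 25,
                            epsilon = 1e-12, tol = 1e-4) {
  stopifnot(iterations >= 1)
  if (abs(sum(psf$kernel) - 1) > 1e-8)
    stop("PSF kernel must sum to 1 (normalize it via psf_model())")
  is_stack <- inherits(observed, "channel_stack")
  obs <- if (is_stack) observed$data else observed
  stopifnot(length(dim(obs)) == 3L, all(obs >= 0))
  dk <- dim(psf$kernel)
  pad <- (dk - 1) / 2
  po <- pad_reflect3(obs, pad)
  dp <- dim(po)
  otf <- psf_otf(psf$kernel, dp)
  otf_c <- Conj(otf)
  np <- prod(dp)
  convf <- function(x, H) Re(fft(fft(x) * H, inverse = TRUE)) / np

  est <- po
  for (it in seq_len(iterations)) {
    den <- pmax(convf(est, otf), epsilon)
    ratio <- po / den
    corr <- convf(ratio, otf_c)
    new <- pmax(est * corr, 0)
    delta <- mean(abs(new - est)) / max(mean(est), 1e-300)
    est <- new
    if (tol > 0 && delta < tol) break
  }
  out <- est[pad[1] + seq_len(dim(obs)[1]),
             pad[2] + seq_len(dim(obs)[2]),
             pad[3] + seq_len(dim(obs)[3]), drop = FALSE]
  if (is_stack) {
    observed$data <- out
    observed
  } else out
}

#' Kullback-Leibler divergence between observed data and a re-blurred
#' estimate
#'
#' The objective Richardson-Lucy monotonically decreases:
#' `sum(r - o + o * log(o / r))` with `r = estimate %conv% psf`, terms with
#' `o = 0` contributing `r`. Useful for monitoring convergence.
#'
#' @param observed Non-negative 3D array or `channel_stack`.
#' @param estimate Current estimate (same shape).
#' @param psf A `psf_model`.
#' @return Scalar divergence.
#' @export
kl_reblur <- function(observed, estimate, psf) {
  obs <- if (inherits(observed, "channel_stack")) observed$data else observed
  est <- if (inherits(estimate, "channel_stack")) estimate$data else estimate
  r <- pmax(conv3_fft(est, psf$kernel), 1e-300)
  term <- r - obs
  pos <- obs > 0
  term[pos] <- term[pos] + obs[pos] * log(obs[pos] / r[pos])
  sum(term)
}
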