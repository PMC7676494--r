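# Internal FFT and RNG helpers shared by the phantom, deconvolution and
# stitching modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Squared frequency grid (cycles per sample) for one axis of length n.
freq_sq <- function(n) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  if (n == 1) f <- 0
  f^2
}

# Analytic optical transfer function of an isotropic-in-plane Gaussian
# blur with sd (sigma_y, sigma_x) in pixels, sampled on the DFT grid.
gauss_otf2 <- function(ny, nx, sigma_y, sigma_x) {
  fy2 <- freq_sq(ny)
  fx2 <- freq_sq(nx)
  exp(-2 * pi^2 * (outer(sigma_y^2 * fy2, sigma_x^2 * fx2, `+`)))
}

# Centered 3D convolution of a volume (ny, nx, nz) with a kernel whose
# dims are odd; linear convolution via zero padding to FFT-friendly sizes.
conv3_fft <- function(vol, kernel) {
  dv <- dim(vol)
  dk <- dim(kernel)
  stopifnot(all(dk %% 2 == 1))
  dp <- mapply(function(a, b) stats::nextn(a + b - 1, c(2, 3, 5)), dv, dk)
  pv <- array(0, dp)
  pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, dp)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  full <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(dp)
  ctr <- (dk - 1) / 2
  full[ctr[1] + seq_len(dv[1]), ctr[2] + seq_len(dv[2]),
       ctr[3] + seq_len(dv[3]), drop = FALSE]
}

# Reflective (symmetric) padding of a 3D array by `pad` voxels per side.
pad_reflect3 <- function(vol, pad) {
  idx <- function(n, p) {
    if (p == 0) return(seq_len(n))
    i <- c(rev(seq_len(min(p, n))), seq_len(n), n + 1 - seq_len(min(p, n)))
    # if pad exceeds n, recycle the reflection (rare; tiny volumes)
    while (length(i) < n + 2 * p) i <- c(i[1], i, i[length(i)])
    i
  }
  vol[idx(dim(vol)[1], pad[1]), idx(dim(vol)[2], pad[2]),
      idx(dim(vol)[3], pad[3]), drop = FALSE]
}

# Gaussian blur of a 3D array with per-axis sd in voxels, periodic
# boundaries (used inside scale-space detection where wrap-around at the
# borders is acceptable).
gauss_blur3 <- function(vol, sigma) {
  d <- dim(vol)
  otf <- array(1, d)
  g1 <- exp(-2 * pi^2 * sigma[1]^2 * freq_sq(d[1]))
  g2 <- exp(-2 * pi^2 * sigma[2]^2 * freq_sq(d[2]))
  g3 <- exp(-2 * pi^2 * sigma[3]^2 * freq_sq(d[3]))
  otf <- outer(outer(g1, g2), g3)
  Re(fft(fft(vol) * otf, inverse = TRUE)) / prod(d)
}
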