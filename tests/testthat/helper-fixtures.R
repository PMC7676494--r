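# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# smooth non-negative textured plane (registration fixtures)
textured_plane <- function(seed, n = 96, sigma = 2) {
  biopsy3d:::with_seed(seed, {
    w <- matrix(rnorm(n * n), n, n)
    otf <- biopsy3d:::gauss_otf2(n, n, sigma, sigma)
    s <- Re(stats::fft(stats::fft(w) * otf, inverse = TRUE)) / (n * n)
    s - min(s) + 0.1
  })
}

# shift a plane by an exact Fourier phase ramp (content moves by +dy, +dx)
fourier_shift_plane <- function(pl, dy, dx) {
  d <- dim(pl)
  fy <- c(0:(floor(d[1] / 2)), -(ceiling(d[1] / 2) - 1):-1) / d[1]
  fx <- c(0:(floor(d[2] / 2)), -(ceiling(d[2] / 2) - 1):-1) / d[2]
  ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(stats::fft(stats::fft(pl) * ph, inverse = TRUE)) / length(pl)
}

# small phantom + BF stack used by several suites
small_truth <- function() {
  fixture("small_truth", {
    spec <- phantom_spec(
      volume_shape = c(32, 96, 96),
      cavities = tibble::tibble(shape = "sphere", diameter_um = 45,
                                z_um = 46.5, y_um = 47, x_um = 47,
                                axis = NA_character_),
      seed = 7L)
    generate_phantom(spec)
  })
}

small_bf <- function() {
  fixture("small_bf", simulate_bf_stack(small_truth()))
}

# naive reimplementation of the local energy statistic with the same
# accumulation order as the production kernel (reflection, kernel rows
# then cols, window rows then cols) — the brute-force oracle
naive_reflect <- function(i, n) {  # 0-based
  if (n == 1) return(0)
  p <- 2 * n
  i <- ((i %% p) + p) %% p
  if (i >= n) i <- p - 1 - i
  i
}

naive_local_energy <- function(plane, radius, kernel) {
  ny <- nrow(plane); nx <- ncol(plane)
  kh <- nrow(kernel); kw <- ncol(kernel)
  cy <- kh %/% 2; cx <- kw %/% 2
  resp <- matrix(0, ny, nx)
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    acc <- 0
    for (ki in 0:(kh - 1)) {
      yy <- naive_reflect(y + ki - cy, ny)
      for (kj in 0:(kw - 1)) {
        xx <- naive_reflect(x + kj - cx, nx)
        acc <- acc + kernel[ki + 1, kj + 1] * plane[yy + 1, xx + 1]
      }
    }
    resp[y + 1, x + 1] <- acc
  }
  energy <- matrix(0, ny, nx)
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    acc <- 0
    for (wy in -radius:radius) {
      yy <- naive_reflect(y + wy, ny)
      for (wx in -radius:radius) {
        xx <- naive_reflect(x + wx, nx)
        r <- resp[yy + 1, xx + 1]
        acc <- acc + r * r
      }
    }
    energy[y + 1, x + 1] <- acc
  }
  energy
}

# exhaustive zero-normalized cross-correlation oracle over integer shifts
naive_zncc_grid <- function(ref, mov, m) {
  ny <- nrow(ref); nx <- ncol(ref)
  out <- matrix(NA_real_, 2 * m + 1, 2 * m + 1)
  for (dy in -m:m) for (dx in -m:m) {
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    a <- ref[ys, xs]
    b <- mov[ys + dy, xs + dx]
    av <- a - mean(a); bv <- b - mean(b)
    den <- sqrt(sum(av^2) * sum(bv^2))
    out[dy + m + 1, dx + m + 1] <- if (den > 0) sum(av * bv) / den else -2
  }
  out
}

# greedy one-to-one matching of truth cavity centers to enclosed
# components; returns logical vector over truth rows
match_cavities <- function(report, truth_table, tol_um = 10) {
  encl <- report[report$enclosed, , drop = FALSE]
  used <- rep(FALSE, nrow(encl))
  found <- rep(FALSE, nrow(truth_table))
  ord <- order(-truth_table$diameter_um)
  for (i in ord) {
    if (nrow(encl) == 0) break
    d <- sqrt((encl$centroid_z_um - truth_table$z_um[i])^2 +
              (encl$centroid_y_um - truth_table$y_um[i])^2 +
              (encl$centroid_x_um - truth_table$x_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_um) {
      found[i] <- TRUE
      used[j] <- TRUE
    }
  }
  found
}
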