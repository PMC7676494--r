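#' Defocus blur model
#'
#' Two-parameter model of how out-of-focus structure blurs laterally:
#' a plane at defocus distance `d` um contributes after Gaussian lateral
#' blur of sd `blur_sigma_at_focus_um + blur_growth_per_um * d`. This is
#' the physical property the tissue segmentation exploits: high spatial
#' frequencies are attenuated increasingly with distance from the focal
#' plane.
#'
#' @param blur_sigma_at_focus_um Lateral blur sd at zero defocus (um).
#' @param blur_growth_per_um Added lateral blur sd per um of defocus.
#' @return An object of class `defocus_model`.
#' @export
defocus_model <- function(blur_sigma_at_focus_um = 0.5,
                          blur_growth_per_um = 0.4) {
  stopifnot(blur_sigma_at_focus_um >= 0, blur_growth_per_um >= 0)
  structure(list(blur_sigma_at_focus_um = blur_sigma_at_focus_um,
                 blur_growth_per_um = blur_growth_per_um),
            class = "defocus_model")
}

#' Default graded-cavity layout for a phantom volume
#'
#' Five enclosed spherical cavities with equivalent diameters spanning
#' 30-100 um, placed mid-depth on a lateral grid wide enough that no two
#' spheres or sphere/wall pairs touch. This layout brackets the 50 um
#' detection claim the segmentation is validated against.
#'
#' @param volume_shape `(nz, ny, nx)` voxels.
#' @param spacing_um `(dz, dy, dx)` in um.
#' @return Tibble with columns `shape`, `diameter_um`, `z_um`, `y_um`,
#'   `x_um`, `axis`.
#' @export
default_cavities <- function(volume_shape = c(64, 256, 256),
                             spacing_um = default_spacing()) {
  ext <- (volume_shape - 1) * spacing_um  # physical extent (z, y, x)
  tibble::tibble(
    shape = "sphere",
    diameter_um = c(100, 80, 60, 45, 30),
    z_um = 0.5 * ext[1],
    y_um = c(0.305, 0.305, 0.695, 0.695, 0.5) * ext[2],
    x_um = c(0.305, 0.695, 0.305, 0.695, 0.5) * ext[3],
    axis = NA_character_
  )
}

#' Phantom specification
#'
#' Describes a synthetic optically-cleared tissue punch: a textured tissue
#' slab with internal cavities, from which modality-specific z-stacks are
#' simulated. Defaults describe the validation conditions used throughout
#' the package: a 64 x 256 x 256 voxel volume at (3, 1, 1) um spacing with
#' graded spherical cavities of 30-100 um equivalent diameter.
#'
#' @param volume_shape `(nz, ny, nx)` voxels.
#' @param spacing_um `(dz, dy, dx)` in um.
#' @param tissue_extent List with elements `z`, `y`, `x`, each a `(lo, hi)`
#'   range in um; `NULL` for default margins (12 um axially, 16 um
#'   laterally).
#' @param cavities Tibble as returned by [default_cavities()]; supported
#'   shapes are `"sphere"` and `"tube"` (a cylinder along `axis`, one of
#'   `"z"`, `"y"`, `"x"`, spanning the tissue extent).
#' @param texture_grain_um Characteristic length of the fine (cell-scale)
#'   intra-tissue intensity texture (band-limited Gaussian random field).
#' @param texture_contrast Relative modulation of tissue attenuation by
#'   the texture field.
#' @param texture_coarse_grain_um,texture_coarse_weight A second,
#'   coarser texture component (glandular/stromal density variation)
#'   mixed into the field before standardization; weight 0 disables it.
#'   The coarse component gives the volume the multi-scale blob
#'   structure real tissue has, which scale-space landmark detection
#'   relies on.
#' @param attenuation_per_um Mean tissue attenuation coefficient (per um)
#'   for bright-field image formation.
#' @param noise_sd Additive Gaussian sensor noise sd, on the scale of a
#'   unit background intensity.
#' @param seed Integer seed; all derived simulations are deterministic
#'   given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 256, 256),
                         spacing_um = default_spacing(),
                         tissue_extent = NULL,
                         cavities = default_cavities(volume_shape, spacing_um),
                         texture_grain_um = 4,
                         texture_contrast = 0.9,
                         texture_coarse_grain_um = 24,
                         texture_coarse_weight = 0.5,
                         attenuation_per_um = 0.0085,
                         noise_sd = 3e-4,
                         seed = 1L) {
  spacing_um <- check_spacing(spacing_um)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1),
            texture_grain_um > 0, noise_sd >= 0)
  if (!is.null(cavities) && nrow(cavities) > 0 &&
      any(cavities$diameter_um <= 0))
    stop("cavity diameters must be positive")
  ext <- (volume_shape - 1) * spacing_um
  if (is.null(tissue_extent)) {
    tissue_extent <- list(z = c(12, ext[1] - 12),
                          y = c(16, ext[2] - 16),
                          x = c(16, ext[3] - 16))
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_um = spacing_um, tissue_extent = tissue_extent,
                 cavities = cavities, texture_grain_um = texture_grain_um,
                 texture_contrast = texture_contrast,
                 texture_coarse_grain_um = texture_coarse_grain_um,
                 texture_coarse_weight = texture_coarse_weight,
                 attenuation_per_um = attenuation_per_um,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center coordinates (um) along each axis, 0-based convention
axis_coords <- function(spec) {
  list(z = (seq_len(spec$volume_shape[1]) - 1) * spec$spacing_um[1],
       y = (seq_len(spec$volume_shape[2]) - 1) * spec$spacing_um[2],
       x = (seq_len(spec$volume_shape[3]) - 1) * spec$spacing_um[3])
}

#' Generate a ground-truth phantom volume
#'
#' Builds the tissue mask (a textured slab), carves out the requested
#' cavities, and lays down the two fluorescence truth volumes: channel 1
#' concentrated in shells lining the cavities (emulating luminal CK8-18
#' staining), channel 2 at the tissue periphery (emulating basal/stromal
#' CK5). Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param lining_shell_um,peripheral_shell_um Shell thicknesses for the
#'   two fluorescence truths.
#' @return An object of class `phantom_truth` with elements `tissue_mask`,
#'   `cavity_labels`, `fl1_truth`, `fl2_truth`, `texture` (standardized
#'   random field), `cavity_table` (truth morphometry tibble) and `spec`.
#'   Arrays have dim `(ny, nx, nz)`.
#' @export
generate_phantom <- function(spec, lining_shell_um = 6,
                             peripheral_shell_um = 9) {
  stopifnot(inherits(spec, "phantom_spec"))
  ns <- spec$volume_shape            # (nz, ny, nx)
  d <- c(ns[2], ns[3], ns[1])        # array dim (ny, nx, nz)
  co <- axis_coords(spec)
  te <- spec$tissue_extent

  in_rng <- function(v, r) v >= r[1] & v <= r[2]
  box_y <- in_rng(co$y, te$y); box_x <- in_rng(co$x, te$x)
  box_z <- in_rng(co$z, te$z)
  tissue_box <- outer(outer(box_y, box_x, `&`), box_z, `&`)

  cavity_labels <- array(0L, d)
  cav <- spec$cavities
  if (!is.null(cav) && nrow(cav) > 0) {
    for (i in seq_len(nrow(cav))) {
      r <- cav$diameter_um[i] / 2
      if (cav$shape[i] == "sphere") {
        if (cav$z_um[i] - r < te$z[1] || cav$z_um[i] + r > te$z[2] ||
            cav$y_um[i] - r < te$y[1] || cav$y_um[i] + r > te$y[2] ||
            cav$x_um[i] - r < te$x[1] || cav$x_um[i] + r > te$x[2])
          stop("cavity ", i, " extends outside the tissue extent")
        iy <- which(abs(co$y - cav$y_um[i]) <= r)
        ix <- which(abs(co$x - cav$x_um[i]) <= r)
        iz <- which(abs(co$z - cav$z_um[i]) <= r)
        d2 <- outer(outer((co$y[iy] - cav$y_um[i])^2,
                          (co$x[ix] - cav$x_um[i])^2, `+`),
                    (co$z[iz] - cav$z_um[i])^2, `+`)
        sub <- cavity_labels[iy, ix, iz, drop = FALSE]
        sub[d2 <= r^2] <- i
        cavity_labels[iy, ix, iz] <- sub
      } else if (cav$shape[i] == "tube") {
        ax <- match.arg(cav$axis[i], c("z", "y", "x"))
        perp <- setdiff(c("z", "y", "x"), ax)
        cuv <- c(z = cav$z_um[i], y = cav$y_um[i], x = cav$x_um[i])
        for (p in perp) {
          if (cuv[p] - r < te[[p]][1] || cuv[p] + r > te[[p]][2])
            stop("cavity ", i, " extends outside the tissue extent")
        }
        r2 <- lapply(c(z = "z", y = "y", x = "x"), function(a) {
          if (a == ax) 0 * co[[a]] else (co[[a]] - cuv[a])^2
        })
        along_ok <- in_rng(co[[ax]], te[[ax]])
        r2[[ax]][!along_ok] <- Inf
        d2 <- outer(outer(r2$y, r2$x, `+`), r2$z, `+`)
        cavity_labels[d2 <= r^2] <- i
      } else stop("unknown cavity shape: ", cav$shape[i])
    }
  }

  tissue_mask <- tissue_box & cavity_labels == 0L

  # band-limited texture: low-pass filtered white noise, standardized
  # low-pass sd of grain/6 puts substantial spectral power at the grain
  # wavelength itself (1/(2*pi*sigma) ~ 1/grain), i.e. cell-scale detail
  # the high-pass energy statistic can actually see; the coarse component
  # adds gland/stroma-scale density variation (multi-scale structure)
  grain_sigma <- function(grain_um) {
    (grain_um / 6) / spec$spacing_um[c("dy", "dx", "dz")]
  }
  texture <- with_seed(derive_seed(spec$seed, "texture"), {
    w <- array(rnorm(prod(d)), d)
    g <- gauss_blur3(w, grain_sigma(spec$texture_grain_um))
    g <- (g - mean(g)) / sd(g)
    if (spec$texture_coarse_weight > 0) {
      wc <- array(rnorm(prod(d)), d)
      gc <- gauss_blur3(wc, grain_sigma(spec$texture_coarse_grain_um))
      gc <- (gc - mean(gc)) / sd(gc)
      g <- g + spec$texture_coarse_weight * gc
      g <- (g - mean(g)) / sd(g)
    }
    g
  })

  # FL1 truth: shells lining the cavities (within tissue)
  fl1 <- array(0, d)
  if (!is.null(cav) && nrow(cav) > 0) {
    for (i in seq_len(nrow(cav))) {
      r <- cav$diameter_um[i] / 2
      rs <- r + lining_shell_um
      if (cav$shape[i] == "sphere") {
        iy <- which(abs(co$y - cav$y_um[i]) <= rs)
        ix <- which(abs(co$x - cav$x_um[i]) <= rs)
        iz <- which(abs(co$z - cav$z_um[i]) <= rs)
        d2 <- outer(outer((co$y[iy] - cav$y_um[i])^2,
                          (co$x[ix] - cav$x_um[i])^2, `+`),
                    (co$z[iz] - cav$z_um[i])^2, `+`)
        sub <- fl1[iy, ix, iz, drop = FALSE]
        sub[d2 > r^2 & d2 <= rs^2] <- 1
        fl1[iy, ix, iz] <- sub
      } else {
        ax <- cav$axis[i]
        cuv <- c(z = cav$z_um[i], y = cav$y_um[i], x = cav$x_um[i])
        r2 <- lapply(c(z = "z", y = "y", x = "x"), function(a) {
          if (a == ax) 0 * co[[a]] else (co[[a]] - cuv[a])^2
        })
        along_ok <- in_rng(co[[ax]], te[[ax]])
        r2[[ax]][!along_ok] <- Inf
        d2 <- outer(outer(r2$y, r2$x, `+`), r2$z, `+`)
        fl1[d2 > r^2 & d2 <= rs^2] <- 1
      }
    }
  }
  fl1[!tissue_mask] <- 0

  # FL2 truth: tissue within a shell of the slab boundary
  bd <- function(v, r) pmin(v - r[1], r[2] - v)
  dist_box <- pmin(
    outer(outer(bd(co$y, te$y), bd(co$x, te$x), pmin), bd(co$z, te$z), pmin))
  fl2 <- array(0, d)
  fl2[dist_box <= peripheral_shell_um] <- 1
  fl2[!tissue_mask] <- 0

  vox_um3 <- prod(spec$spacing_um)
  cavity_table <- if (!is.null(cav) && nrow(cav) > 0) {
    counts <- tabulate(cavity_labels[cavity_labels > 0L], nbins = nrow(cav))
    tibble::tibble(
      cavity = seq_len(nrow(cav)),
      shape = cav$shape,
      diameter_um = cav$diameter_um,
      z_um = cav$z_um, y_um = cav$y_um, x_um = cav$x_um,
      voxels = counts,
      equivalent_diameter_um = (6 * counts * vox_um3 / pi)^(1 / 3)
    )
  } else {
    tibble::tibble(cavity = integer(), shape = character(),
                   diameter_um = numeric(), z_um = numeric(),
                   y_um = numeric(), x_um = numeric(), voxels = integer(),
                   equivalent_diameter_um = numeric())
  }

  structure(list(tissue_mask = tissue_mask, cavity_labels = cavity_labels,
                 fl1_truth = fl1, fl2_truth = fl2, texture = texture,
                 cavity_table = cavity_table, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d x %d voxels (nz, ny, nx), %d cavities, %.1f%% tissue\n",
              x$spec$volume_shape[1], x$spec$volume_shape[2],
              x$spec$volume_shape[3], nrow(x$cavity_table),
              100 * mean(x$tissue_mask)))
  invisible(x)
}

# Defocus projection: for each focal plane, sum all source planes after
# plane-distance-dependent Gaussian lateral blur (frequency domain,
# periodic laterally). planes: (ny, nx, nz) array of per-plane source
# terms; returns (ny, nx, nf).
project_defocus <- function(planes, spacing_um, defocus,
                            focal_planes = dim(planes)[3]) {
  d <- dim(planes)
  nz <- d[3]
  dz <- spacing_um[1]
  focal_idx <- if (focal_planes == nz) seq_len(nz) else
    round(seq(1, nz, length.out = focal_planes))
  Fp <- lapply(seq_len(nz), function(k) fft(planes[, , k]))
  otf <- lapply(0:(nz - 1), function(dist) {
    s <- defocus$blur_sigma_at_focus_um +
      defocus$blur_growth_per_um * dist * dz
    gauss_otf2(d[1], d[2], s / spacing_um[2], s / spacing_um[3])
  })
  out <- array(0, c(d[1], d[2], length(focal_idx)))
  for (fi in seq_along(focal_idx)) {
    f <- focal_idx[fi]
    S <- matrix(0 + 0i, d[1], d[2])
    for (k in seq_len(nz)) S <- S + Fp[[k]] * otf[[abs(k - f) + 1]]
    out[, , fi] <- Re(fft(S, inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

#' Simulate a bright-field z-stack from a phantom
#'
#' Bright-field contrast is modeled as an attenuation (transmission)
#' projection: each source plane's optical depth contributes to a focal
#' plane after defocus-dependent lateral Gaussian blur, and the recorded
#' intensity is `i0 * exp(-projected optical depth)` plus Gaussian sensor
#' noise. In-focus tissue texture therefore carries high spatial
#' frequencies that vanish with defocus distance — the signal the
#' segmentation thresholds.
#'
#' @param truth A `phantom_truth`.
#' @param defocus A [defocus_model()].
#' @param focal_planes Number of focal planes (default: one per voxel
#'   plane of the truth volume).
#' @param noise_sd Sensor noise sd (default: the spec's).
#' @param seed Integer seed (default: derived from the spec's).
#' @param i0 Background (clear-path) intensity.
#' @return A `channel_stack` with channel `"BF"`.
#' @export
simulate_bf_stack <- function(truth, defocus = defocus_model(),
                              focal_planes = NULL, noise_sd = NULL,
                              seed = NULL, i0 = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  if (is.null(focal_planes)) focal_planes <- spec$volume_shape[1]
  stopifnot(focal_planes >= 1)
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  if (is.null(seed)) seed <- derive_seed(spec$seed, "bf")
  att <- spec$attenuation_per_um *
    pmax(1 + spec$texture_contrast * truth$texture, 0.05)
  att[!truth$tissue_mask] <- 0
  od <- att * spec$spacing_um[1]
  proj <- project_defocus(od, spec$spacing_um, defocus, focal_planes)
  img <- i0 * exp(-pmax(proj, 0))
  data <- with_seed(seed, img + rnorm(length(img), sd = noise_sd))
  channel_stack(pmax(data, 0), spacing_um = spec$spacing_um, channel = "BF")
}

#' Simulate a dark-field z-stack from a phantom
#'
#' Dark-field signal is modeled as scattering proportional to the local
#' lateral gradient magnitude of the textured tissue field, summed over
#' depth with the same defocus blur rule as bright field.
#'
#' @inheritParams simulate_bf_stack
#' @param gain Scattering-to-intensity gain.
#' @return A `channel_stack` with channel `"DF"`.
#' @export
simulate_df_stack <- function(truth, defocus = defocus_model(),
                              focal_planes = NULL, noise_sd = NULL,
                              seed = NULL, gain = 0.5) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  if (is.null(focal_planes)) focal_planes <- spec$volume_shape[1]
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  if (is.null(seed)) seed <- derive_seed(spec$seed, "df")
  field <- (1 + spec$texture_contrast * truth$texture)
  field[!truth$tissue_mask] <- 0
  d <- dim(field)
  gy <- array(0, d); gx <- array(0, d)
  gy[2:(d[1] - 1), , ] <- (field[3:d[1], , ] - field[1:(d[1] - 2), , ]) /
    (2 * spec$spacing_um[2])
  gx[, 2:(d[2] - 1), ] <- (field[, 3:d[2], ] - field[, 1:(d[2] - 2), ]) /
    (2 * spec$spacing_um[3])
  s <- sqrt(gy^2 + gx^2) * spec$spacing_um[1] * gain
  proj <- project_defocus(s, spec$spacing_um, defocus, focal_planes)
  data <- with_seed(seed, proj + rnorm(length(proj), sd = noise_sd))
  channel_stack(pmax(data, 0), spacing_um = spec$spacing_um, channel = "DF")
}

#' Simulate the two fluorescence z-stacks from a phantom
#'
#' Fluorescence image formation is linear: each truth label-density
#' volume is convolved with the 3D PSF and Gaussian noise is added.
#'
#' @inheritParams simulate_bf_stack
#' @param psf A `psf_model`; default is the Gaussian defocus PSF implied
#'   by `defocus` via [defocus_psf()].
#' @param gain Label density to intensity gain.
#' @return A list with elements `FL1` and `FL2`, each a `channel_stack`.
#' @export
simulate_fl_stacks <- function(truth, defocus = defocus_model(), psf = NULL,
                               noise_sd = NULL, seed = NULL, gain = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  if (is.null(psf)) psf <- defocus_psf(defocus, spec$spacing_um)
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  if (is.null(seed)) seed <- derive_seed(spec$seed, "fl")
  one <- function(vol, chan, s) {
    blurred <- conv3_fft(vol * gain, psf$kernel)
    data <- with_seed(s, blurred + rnorm(length(blurred), sd = noise_sd))
    channel_stack(pmax(data, 0), spacing_um = spec$spacing_um,
                  channel = chan)
  }
  list(FL1 = one(truth$fl1_truth, "FL1", seed),
       FL2 = one(truth$fl2_truth, "FL2", seed + 1L))
}

#' Simulate a fluorescent bead calibration stack
#'
#' Beads are rendered as solid spheres of the given diameter, convolved
#' with the supplied PSF (the image of a bead is sphere x PSF), summed and
#' degraded with Gaussian noise. Refuses bead layouts whose spacing would
#' corrupt later PSF extraction.
#'
#' @param bead_positions_um Matrix with one row per bead, columns
#'   `(z, y, x)` in um.
#' @param psf A `psf_model` used for image formation.
#' @param volume_shape `(nz, ny, nx)` voxels of the output stack.
#' @param spacing_um `(dz, dy, dx)` um.
#' @param bead_diameter_um Physical bead diameter (3 um polystyrene beads
#'   by default).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @param amplitude Peak bead brightness before blurring.
#' @return A `channel_stack` with channel `"FL1"`.
#' @export
simulate_bead_stack <- function(bead_positions_um, psf,
                                volume_shape = c(32, 96, 96),
                                spacing_um = default_spacing(),
                                bead_diameter_um = 3, noise_sd = 0.002,
                                seed = 1L, amplitude = 1) {
  spacing_um <- check_spacing(spacing_um)
  bead_positions_um <- rbind(bead_positions_um)
  n <- nrow(bead_positions_um)
  support_um <- max((dim(psf$kernel) - 1) / 2 *
                      spacing_um[c("dy", "dx", "dz")])
  if (n >= 2) {
    dmin <- min(stats::dist(bead_positions_um))
    if (dmin < 4 * support_um)
      stop("beads too close: minimum separation ", round(dmin, 1),
           " um < 4 x PSF support radius (", round(4 * support_um, 1), " um)")
  }
  d <- c(volume_shape[2], volume_shape[3], volume_shape[1])
  co <- list(z = (seq_len(volume_shape[1]) - 1) * spacing_um[1],
             y = (seq_len(volume_shape[2]) - 1) * spacing_um[2],
             x = (seq_len(volume_shape[3]) - 1) * spacing_um[3])
  vol <- array(0, d)
  r <- bead_diameter_um / 2
  for (i in seq_len(n)) {
    p <- bead_positions_um[i, ]
    d2 <- outer(outer((co$y - p[2])^2, (co$x - p[3])^2, `+`),
                (co$z - p[1])^2, `+`)
    vol[d2 <= r^2] <- amplitude
  }
  img <- if (n > 0) conv3_fft(vol, psf$kernel) else vol
  data <- with_seed(seed, img + rnorm(length(img), sd = noise_sd))
  channel_stack(pmax(data, 0), spacing_um = spacing_um, channel = "FL1")
}
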