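#' Piecewise-linear opacity transfer functions
#'
#' A transfer function maps voxel intensity to opacity and is represented
#' as a `k x 2` matrix of `(intensity, alpha)` breakpoints sorted by
#' intensity; values outside the range clamp to the end alphas.
#' `tf_linear()` ramps opacity linearly between two intensities;
#' `tf_step()` is a near-binary step at a threshold.
#'
#' @param from,to Intensities at which opacity starts rising / reaches
#'   `max_alpha`.
#' @param max_alpha Peak opacity in `[0, 1]`.
#' @param threshold Step location.
#' @return Breakpoint matrix.
#' @export
tf_linear <- function(from = 0, to = 1, max_alpha = 0.1) {
  stopifnot(to > from, max_alpha >= 0, max_alpha <= 1)
  cbind(intensity = c(from, to), alpha = c(0, max_alpha))
}

#' @rdname tf_linear
#' @export
tf_step <- function(threshold = 0.5, max_alpha = 0.5) {
  eps <- max(1e-9, abs(threshold) * 1e-9)
  cbind(intensity = c(threshold, threshold + eps), alpha = c(0, max_alpha))
}

#' A renderable channel
#'
#' @param volume 3D array (dim `(ny, nx, nz)`), `channel_stack`, or
#'   logical mask.
#' @param color RGB triple in `[0, 1]`.
#' @param tf Opacity transfer function (see [tf_linear()]).
#' @return A list understood by [render()].
#' @export
render_channel <- function(volume, color = c(1, 1, 1),
                           tf = tf_linear(0, 1, 0.1)) {
  if (inherits(volume, "channel_stack")) volume <- volume$data
  if (is.logical(volume)) volume <- volume + 0
  stopifnot(length(dim(volume)) == 3L, length(color) == 3L,
            all(color >= 0), all(color <= 1),
            ncol(tf) == 2L, all(tf[, 2] >= 0), all(tf[, 2] <= 1))
  list(volume = volume, color = as.numeric(color), tf = tf)
}

#' Render settings
#'
#' @param azimuth,elevation Camera angles in degrees. At `(0, 0)` the
#'   camera looks along +z (head-on at the first focal plane); azimuth
#'   rotates about the image's vertical (y) axis, elevation about its
#'   horizontal (x) axis.
#' @param width,height Output image size in pixels.
#' @param step_vox Sample step along each ray, in voxels (0.5 is a
#'   standard quality/cost compromise; 1 with an axis-aligned camera
#'   samples exactly at voxel centers).
#' @param background RGB background color.
#' @param pixel_um Image pixel size in um; `NULL` fits the volume's
#'   bounding-sphere diameter into the smaller image dimension.
#' @param alpha_cutoff Early ray termination at this accumulated opacity.
#' @param spacing_um Voxel spacing `(dz, dy, dx)`; `NULL` takes it from
#'   the first `channel_stack` passed to [render()] (else 1 um isotropic).
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(azimuth = 0, elevation = 0, width = 256,
                            height = 256, step_vox = 0.5,
                            background = c(0, 0, 0), pixel_um = NULL,
                            alpha_cutoff = 0.99, spacing_um = NULL) {
  stopifnot(width >= 1, height >= 1, step_vox > 0,
            length(background) == 3L)
  structure(list(azimuth = azimuth, elevation = elevation, width = width,
                 height = height, step_vox = step_vox,
                 background = as.numeric(background), pixel_um = pixel_um,
                 alpha_cutoff = alpha_cutoff, spacing_um = spacing_um),
            class = "render_settings")
}

# orthonormal camera basis in physical (x, y, z) coordinates
camera_basis <- function(azimuth, elevation) {
  a <- azimuth * pi / 180
  e <- elevation * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(e), sin(e), 0, -sin(e), cos(e)), 3, 3)
  R <- Ry %*% Rx
  list(dir = as.numeric(R %*% c(0, 0, 1)),
       u = as.numeric(R %*% c(1, 0, 0)),
       v = as.numeric(R %*% c(0, 1, 0)))
}

render_pixel_um <- function(settings, vdim, spacing) {
  if (!is.null(settings$pixel_um)) return(settings$pixel_um)
  ext <- c(vdim[2] * spacing["dx"], vdim[1] * spacing["dy"],
           vdim[3] * spacing["dz"])
  sqrt(sum(ext^2)) / min(settings$width, settings$height)
}

#' Project a voxel to image coordinates
#'
#' The orthographic mapping [render()] uses: useful for annotating or
#' testing renders. Returns fractional 0-based `(row, col)` image
#' coordinates of a voxel's center.
#'
#' @param settings A `render_settings` (with `spacing_um` and `pixel_um`
#'   resolved or resolvable).
#' @param vdim Volume dim `(ny, nx, nz)`.
#' @param voxel `(z, y, x)` 0-based voxel coordinates.
#' @return Numeric `(row, col)`.
#' @export
project_voxel <- function(settings, vdim, voxel) {
  spacing <- check_spacing(settings$spacing_um %||% c(1, 1, 1))
  cb <- camera_basis(settings$azimuth, settings$elevation)
  px <- render_pixel_um(settings, vdim, spacing)
  p <- c(voxel[3] * spacing["dx"], voxel[2] * spacing["dy"],
         voxel[1] * spacing["dz"])
  ctr <- c((vdim[2] - 1) / 2 * spacing["dx"],
           (vdim[1] - 1) / 2 * spacing["dy"],
           (vdim[3] - 1) / 2 * spacing["dz"])
  rel <- p - ctr
  c(row = sum(rel * cb$v) / px + (settings$height - 1) / 2,
    col = sum(rel * cb$u) / px + (settings$width - 1) / 2)
}

#' Ray-cast a composite volume rendering
#'
#' Orthographic parallel rays traverse the volume front to back; at each
#' sample, every channel contributes opacity through its transfer
#' function and color, and samples are alpha-composited with early ray
#' termination. All voxels are rendered transparent, so occluded internal
#' structures (ducts, tubules) remain visible through the tissue surface.
#' Deterministic.
#'
#' @param channels List of [render_channel()]s sharing dimensions, or a
#'   single `render_channel`.
#' @param settings A [render_settings()].
#' @return RGB array `(height, width, 3)` of class `render_image`.
#' @export
render <- function(channels, settings = render_settings()) {
  if (!is.null(channels$volume)) channels <- list(channels)
  if (length(channels) == 0) stop("empty channel list")
  dims <- unique(lapply(channels, function(c) dim(c$volume)))
  if (length(dims) != 1L) stop("channel volumes differ in shape")
  vdim <- dims[[1]]
  spacing <- check_spacing(settings$spacing_um %||% c(1, 1, 1))
  cb <- camera_basis(settings$azimuth, settings$elevation)
  px <- render_pixel_um(settings, vdim, spacing)
  img <- cpp_render(lapply(channels, `[[`, "volume"), vdim,
                    as.numeric(spacing),
                    do.call(rbind, lapply(channels, `[[`, "color")),
                    lapply(channels, `[[`, "tf"),
                    cb$dir, cb$u, cb$v, px,
                    settings$height, settings$width, settings$step_vox,
                    settings$background, settings$alpha_cutoff)
  structure(img, class = c("render_image", class(img)))
}

#' Render a rotation series
#'
#' Frames at azimuths `base + 360 k / n_frames`; frame 1 is identical to
#' a single [render()] at the base azimuth.
#'
#' @inheritParams render
#' @param n_frames Number of frames.
#' @return List of `render_image`s.
#' @export
render_rotation_series <- function(channels, settings = render_settings(),
                                   n_frames = 12) {
  stopifnot(n_frames >= 1)
  lapply(seq_len(n_frames) - 1, function(k) {
    s <- settings
    s$azimuth <- settings$azimuth + 360 * k / n_frames
    render(channels, s)
  })
}

#' Save a rendered image as PNG
#' @param img A `render_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 1), path)
  invisible(path)
}

#' @export
print.render_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<render_image> %d x %d px, intensity range [%.3f, %.3f]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}
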