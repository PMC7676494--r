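#' Construct a single-channel focal-plane stack
#'
#' A `channel_stack` is the pipeline's unit of input: one imaging
#' modality's ordered focal planes with physical voxel spacing. Pixel data
#' are stored as a 3D array with dim `(ny, nx, nz)`; plane `k` is
#' `data[, , k]`. All ordered triples exposed to the user (spacing, shapes,
#' coordinates) follow the `(z, y, x)` convention, and voxel centers sit at
#' `index * spacing` with 0-based indices, z increasing away from the
#' objective.
#'
#' @param data 3D numeric array `(ny, nx, nz)`, or a list of equal-sized
#'   matrices (planes in z order).
#' @param spacing_um Physical voxel spacing `(dz, dy, dx)` in micrometres.
#' @param channel Modality tag: one of `"BF"`, `"DF"`, `"FL1"`, `"FL2"`.
#' @param wavelength_nm Optional illumination/emission wavelength.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(data, spacing_um = default_spacing(),
                          channel = "BF", wavelength_nm = NULL) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(data) == 0L) stop("stack must contain at least one plane")
    if (length(dims) != 1L)
      stop("all planes in a stack must share dimensions")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dims[[1]], length(data)))
  }
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(!is.finite(data)) || any(data < 0))
    stop("stack intensities must be finite and non-negative")
  structure(
    list(
      data = data,
      spacing_um = check_spacing(spacing_um),
      channel = check_modality(channel),
      wavelength_nm = wavelength_nm
    ),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf(
    "<channel_stack> %s: %d planes of %d x %d px, spacing (dz, dy, dx) = (%g, %g, %g) um\n",
    x$channel, d[1], d[2], d[3],
    x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Stack dimensions as (nz, ny, nx)
#' @param stack A `channel_stack`.
#' @return Integer vector `c(nz, ny, nx)`.
#' @export
stack_dim <- function(stack) {
  d <- dim(stack$data)
  c(nz = d[3], ny = d[1], nx = d[2])
}

#' Extract one focal plane as a matrix
#' @param stack A `channel_stack`.
#' @param z 1-based plane index.
#' @return Numeric matrix `(ny, nx)`.
#' @export
get_plane <- function(stack, z) {
  d <- dim(stack$data)
  if (z < 1L || z > d[3]) stop("plane index out of range")
  stack$data[, , z]
}

#' Per-plane intensity summary
#' @param stack A `channel_stack`.
#' @return A tibble with one row per plane: `z`, `mean`, `sd`, `min`, `max`.
#' @export
tidy_planes <- function(stack) {
  d <- dim(stack$data)
  tibble::tibble(
    z = seq_len(d[3]),
    mean = apply(stack$data, 3, mean),
    sd = apply(stack$data, 3, sd),
    min = apply(stack$data, 3, min),
    max = apply(stack$data, 3, max)
  )
}

#' Flat-field reference image
#'
#' A per-channel calibration image used to divide out illumination and
#' sensor-response non-uniformity. Must be strictly positive everywhere so
#' the correction is division-safe.
#'
#' @param reference 2D positive numeric matrix.
#' @param channel Modality tag.
#' @return An object of class `flat_field_ref`.
#' @export
flat_field_ref <- function(reference, channel = "BF") {
  if (!is.matrix(reference)) stop("`reference` must be a matrix")
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("flat-field reference must be strictly positive everywhere")
  structure(list(reference = reference, channel = check_modality(channel)),
            class = "flat_field_ref")
}

sidecar_path <- function(path) paste0(path, ".yml")

#' Read a multi-page TIFF into a channel stack
#'
#' Page order is taken as z order (page 1 nearest the objective). Integer
#' (8/16-bit) TIFFs are returned with their native integer values; 32-bit
#' float TIFFs are returned as stored. If a YAML sidecar `<path>.yml`
#' written by [write_stack()] is present, its spacing, channel, wavelength
#' and intensity scale are applied; explicit arguments override it.
#'
#' @param path Path to a single-channel multi-page grayscale TIFF.
#' @param channel Modality tag; `NULL` to take it from the sidecar
#'   (default `"BF"` if no sidecar).
#' @param spacing_um Spacing `(dz, dy, dx)` in um; `NULL` to take it from
#'   the sidecar (default [default_spacing()]).
#' @return A `channel_stack`.
#' @export
read_stack <- function(path, channel = NULL, spacing_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  if (is.null(channel)) channel <- meta$channel %||% "BF"
  if (is.null(spacing_um)) spacing_um <- meta$spacing_um %||% default_spacing()

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("TIFF pages differ in size: ", path)
  bps <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bps) && bps == 32L) {
    # float storage: re-read scaled, then undo the writer's scaling
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (is.array(pages)) pages <- list(pages)
    scale <- meta$intensity_scale %||% 1
    pages <- lapply(pages, function(p) p * scale)
  }
  data <- array(unlist(pages, use.names = FALSE),
                dim = c(dims[[1]], length(pages)))
  channel_stack(data, spacing_um = spacing_um, channel = channel,
                wavelength_nm = meta$wavelength_nm)
}

#' Write a channel stack as a multi-page TIFF
#'
#' Integer-valued stacks within range are stored as 8- or 16-bit unsigned
#' integer pages and round-trip bit-exactly; other stacks are stored as
#' 32-bit float scaled into `[0, 1]`, with the scale recorded in a YAML
#' sidecar `<path>.yml` together with spacing, channel and wavelength so
#' [read_stack()] restores physical values (to float32 precision).
#'
#' @param stack A non-empty `channel_stack`.
#' @param path Output path.
#' @param format `"auto"` (default), `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path,
                        format = c("auto", "uint8", "uint16", "float32")) {
  stopifnot(inherits(stack, "channel_stack"))
  format <- match.arg(format)
  data <- stack$data
  is_int <- all(data == round(data))
  if (format == "auto") {
    format <- if (is_int && max(data) <= 65535) "uint16" else "float32"
  }
  scale <- 1
  pages <- switch(format,
    uint8 = {
      if (!is_int || max(data) > 255)
        stop("data not representable as uint8")
      lapply(seq_len(dim(data)[3]), function(k) data[, , k] / 255)
    },
    uint16 = {
      if (!is_int || max(data) > 65535)
        stop("data not representable as uint16")
      lapply(seq_len(dim(data)[3]), function(k) data[, , k] / 65535)
    },
    float32 = {
      scale <- max(data, 1e-300)
      lapply(seq_len(dim(data)[3]), function(k) data[, , k] / scale)
    }
  )
  bits <- c(uint8 = 8L, uint16 = 16L, float32 = 32L)[[format]]
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  yaml::write_yaml(
    list(
      channel = stack$channel,
      spacing_um = as.numeric(stack$spacing_um),
      wavelength_nm = stack$wavelength_nm,
      intensity_scale = scale,
      format = format
    ),
    sidecar_path(path)
  )
  invisible(path)
}

#' Flat-field correction
#'
#' Divides every plane pixelwise by the reference image, then rescales by
#' the reference's spatial mean so the corrected stack keeps the sensor's
#' native global intensity scale (a uniform reference leaves the stack
#' unchanged).
#'
#' @param stack A `channel_stack`.
#' @param ref A `flat_field_ref` with the same plane dimensions.
#' @return The corrected `channel_stack`.
#' @export
flat_field_correct <- function(stack, ref) {
  stopifnot(inherits(stack, "channel_stack"), inherits(ref, "flat_field_ref"))
  d <- dim(stack$data)
  if (!identical(dim(ref$reference), d[1:2]))
    stop("flat-field reference dimensions do not match the stack")
  gain <- mean(ref$reference) / ref$reference
  out <- stack
  out$data <- stack$data * as.vector(gain)  # recycles over planes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
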