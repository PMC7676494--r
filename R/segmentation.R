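#' High-pass operator kernels
#'
#' The default operator is the 3x3 discrete Laplacian — the minimal
#' isotropic high-pass filter. `"dog"` selects a difference-of-Gaussians
#' (sd 1 and 2 px, 9x9 support) as a smoother alternative.
#'
#' @param filter_id `"laplacian"` or `"dog"`.
#' @return A small numeric matrix with zero DC response.
#' @export
highpass_kernel <- function(filter_id = c("laplacian", "dog")) {
  filter_id <- match.arg(filter_id)
  if (filter_id == "laplacian") {
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  } else {
    r <- 4
    g <- function(s) {
      k <- outer(exp(-(-r:r)^2 / (2 * s^2)), exp(-(-r:r)^2 / (2 * s^2)))
      k / sum(k)
    }
    g(1) - g(2)
  }
}

#' Local high-spatial-frequency energy of a focal-plane image
#'
#' The tissue-presence statistic: the windowed sum of the squared response
#' of a high-pass operator. In-focus tissue texture carries high spatial
#' frequencies and yields large energy; out-of-focus regions (cavities,
#' surrounding medium) are blurred by defocus and yield small energy.
#' Borders are handled by symmetric reflection. The energy is invariant to
#' adding a constant to the plane and scales quadratically with intensity
#' scaling.
#'
#' @param plane Numeric matrix `(ny, nx)`.
#' @param window_radius_px Window half-size; the window is the
#'   `(2r+1) x (2r+1)` square.
#' @param filter_id High-pass operator, see [highpass_kernel()].
#' @return Non-negative energy matrix of the same size, with attributes
#'   `window_radius_px` and `filter_id`.
#' @export
local_highfreq_energy <- function(plane, window_radius_px = 7,
                                  filter_id = c("laplacian", "dog")) {
  filter_id <- match.arg(filter_id)
  stopifnot(is.matrix(plane), window_radius_px >= 1)
  if (2 * window_radius_px + 1 > min(dim(plane)))
    stop("window larger than the plane")
  e <- cpp_local_energy(plane, as.integer(window_radius_px),
                        highpass_kernel(filter_id))
  attr(e, "window_radius_px") <- window_radius_px
  attr(e, "filter_id") <- filter_id
  e
}

#' Otsu threshold of a numeric sample
#'
#' Bimodal histogram splitting: the threshold maximizing between-class
#' variance over a fixed-width histogram of the pooled values.
#'
#' @param values Numeric vector.
#' @param n_bins Histogram resolution.
#' @return Threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("degenerate histogram: all values equal")
  h <- tabulate(pmin(n_bins, 1L + floor((values - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  lo + k * (hi - lo) / n_bins
}

#' Segment tissue from a bright-field stack
#'
#' Marks a voxel as tissue when the local high-frequency energy of its
#' focal plane exceeds a threshold; energy is computed per plane and
#' stacked into a 3D mask (no axial smoothing by default). With
#' `threshold = "auto"` one global threshold is selected over the pooled
#' 3D energy volume by Otsu splitting of the log-energy histogram
#' (energies span orders of magnitude; the split is still a single global
#' energy threshold). Optional morphological opening then closing with a
#' cubic element can clean up speckle.
#'
#' @param bf A non-empty `channel_stack` (bright field).
#' @param window_radius_px Energy window half-size in px.
#' @param threshold Numeric energy threshold, or `"auto"`.
#' @param filter_id High-pass operator, see [highpass_kernel()].
#' @param cleanup_radius Radius (voxels) of the morphological cleanup;
#'   the default of 1 removes isolated misclassified voxels, which
#'   otherwise percolate under 26-connectivity and merge distinct
#'   cavities; `0` disables it.
#' @return An object of class `tissue_segmentation`: `mask` (logical
#'   array, dim `(ny, nx, nz)`), `threshold`, `spacing_um`,
#'   `window_radius_px`, `filter_id`, and the pooled `energy` volume.
#' @export
segment_tissue <- function(bf, window_radius_px = 7, threshold = "auto",
                           filter_id = c("laplacian", "dog"),
                           cleanup_radius = 1) {
  stopifnot(inherits(bf, "channel_stack"))
  filter_id <- match.arg(filter_id)
  d <- dim(bf$data)
  energy <- array(0, d)
  for (k in seq_len(d[3])) {
    energy[, , k] <- local_highfreq_energy(bf$data[, , k],
                                           window_radius_px, filter_id)
  }
  if (identical(threshold, "auto")) {
    le <- log10(energy + 1e-12)
    if (max(le) - min(le) < 1e-9)
      stop("degenerate energy histogram: cannot auto-threshold a constant stack")
    threshold <- 10^otsu_threshold(as.vector(le)) - 1e-12
  }
  mask <- energy > threshold
  if (cleanup_radius > 0) {
    mask <- dilate3(erode3(mask, cleanup_radius), cleanup_radius)   # opening
    mask <- erode3(dilate3(mask, cleanup_radius), cleanup_radius)   # closing
  }
  structure(list(mask = mask, threshold = threshold,
                 spacing_um = bf$spacing_um,
                 window_radius_px = window_radius_px,
                 filter_id = filter_id, energy = energy),
            class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<tissue_segmentation> %d x %d x %d voxels (ny, nx, nz), %.1f%% tissue, threshold %.4g\n",
              d[1], d[2], d[3], 100 * mean(x$mask), x$threshold))
  invisible(x)
}

#' One-row summary of a tissue segmentation
#' @param x A `tissue_segmentation`.
#' @param ... Unused.
#' @return A tibble with `threshold`, `n_tissue_voxels`, `tissue_fraction`.
#' @export
glance.tissue_segmentation <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 n_tissue_voxels = sum(x$mask),
                 tissue_fraction = mean(x$mask))
}

# box erosion/dilation by repeated 1-voxel steps (6-neighborhood cross
# per step); adequate for the small cleanup radii this option targets
shift3 <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(y = seq_len(d[1]), x = seq_len(d[2]), z = seq_len(d[3]))
  dst <- src
  adj <- function(s, off, n) {
    keep <- s + off >= 1 & s + off <= n
    list(src = s[keep], dst = s[keep] + off)
  }
  ay <- adj(src$y, dy, d[1]); ax <- adj(src$x, dx, d[2])
  az <- adj(src$z, dz, d[3])
  out[ay$dst, ax$dst, az$dst] <- a[ay$src, ax$src, az$src]
  out
}

erode3 <- function(mask, radius) {
  for (i in seq_len(radius)) {
    m <- mask
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      m <- m & shift3(mask, o[1], o[2], o[3], TRUE)
    mask <- m
  }
  mask
}

dilate3 <- function(mask, radius) {
  for (i in seq_len(radius)) {
    m <- mask
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      m <- m | shift3(mask, o[1], o[2], o[3], FALSE)
    mask <- m
  }
  mask
}

#' Extract cavities from a tissue segmentation
#'
#' Connected components of the non-tissue space. Components touching the
#' stack boundary are the surrounding medium and are flagged
#' `enclosed = FALSE`; enclosed components are candidate cavities
#' (tubules, ducts). Size is measured as the equivalent spherical
#' diameter `(6 V / pi)^(1/3)` of the component's physical volume, and
#' components below `min_diameter_um` are dropped.
#'
#' @param seg A `tissue_segmentation`.
#' @param min_diameter_um Minimum equivalent diameter to report
#'   (default 50 um, the scale at which the bright-field segmentation
#'   resolves cavities reliably).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `cavity_report`: `labels` (integer array of
#'   the reported components, renumbered 1..k) and `report`, a tibble with
#'   `label`, `voxels`, `equivalent_diameter_um`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`, `enclosed`.
#' @export
extract_cavities <- function(seg, min_diameter_um = 50, connectivity = 26) {
  stopifnot(inherits(seg, "tissue_segmentation"),
            connectivity %in% c(6, 26))
  d <- dim(seg$mask)
  sp <- seg$spacing_um
  labels <- cpp_label3d(!seg$mask, d, as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0L) {
    return(structure(list(labels = labels, report = tibble::tibble(
      label = integer(), voxels = integer(),
      equivalent_diameter_um = numeric(), centroid_z_um = numeric(),
      centroid_y_um = numeric(), centroid_x_um = numeric(),
      enclosed = logical()
    ), spacing_um = sp), class = "cavity_report"))
  }
  counts <- tabulate(labels, nbins = nlab)
  vox_um3 <- prod(sp)
  eqd <- (6 * counts * vox_um3 / pi)^(1 / 3)

  # centroids (0-based voxel coords times spacing)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ai <- arrayInd(idx, d)
  cz <- unname((rowsum(ai[, 3] - 1, lab)[, 1] / counts) * sp["dz"])
  cy <- unname((rowsum(ai[, 1] - 1, lab)[, 1] / counts) * sp["dy"])
  cx <- unname((rowsum(ai[, 2] - 1, lab)[, 1] / counts) * sp["dx"])

  boundary_labels <- unique(c(
    labels[c(1, d[1]), , ], labels[, c(1, d[2]), ], labels[, , c(1, d[3])]))
  enclosed <- !(seq_len(nlab) %in% boundary_labels)

  keep <- which(eqd >= min_diameter_um)
  relabel <- integer(nlab)
  relabel[keep] <- seq_along(keep)
  new_labels <- array(0L, d)
  sel <- lab %in% keep
  new_labels[idx[sel]] <- relabel[lab[sel]]

  report <- tibble::tibble(
    label = seq_along(keep),
    voxels = counts[keep],
    equivalent_diameter_um = eqd[keep],
    centroid_z_um = cz[keep],
    centroid_y_um = cy[keep],
    centroid_x_um = cx[keep],
    enclosed = enclosed[keep]
  )
  structure(list(labels = new_labels, report = report, spacing_um = sp),
            class = "cavity_report")
}

#' @export
print.cavity_report <- function(x, ...) {
  cat(sprintf("<cavity_report> %d components (%d enclosed)\n",
              nrow(x$report), sum(x$report$enclosed)))
  if (nrow(x$report) > 0) print(x$report)
  invisible(x)
}

#' Cavity records as a tibble
#' @param x A `cavity_report`.
#' @param ... Unused.
#' @return The report tibble.
#' @export
tidy.cavity_report <- function(x, ...) x$report

#' Write a cavity report as a delimited table
#' @param x A `cavity_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cavity_report <- function(x, path) {
  utils::write.csv(as.data.frame(x$report), path, row.names = FALSE)
  invisible(path)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy <- function(x, ...) UseMethod("tidy")
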