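#' Estimate the translation between two focal planes
#'
#' Zero-normalized cross-correlation over all integer shifts in
#' `[-max_shift_px, max_shift_px]^2`, refined to subpixel precision by a
#' 1D parabolic fit around the peak in each axis. Exact ties at the
#' integer stage are broken by smallest shift magnitude, then smallest
#' `dy`, then `dx`. The returned `(dy_px, dx_px)` is the displacement of
#' `mov`'s content relative to `ref`.
#'
#' @param ref,mov Numeric matrices of equal size.
#' @param max_shift_px Maximum shift searched (default 32; sample drift in
#'   fluid is small relative to the field).
#' @param smooth_sigma_px Gaussian pre-smoothing applied to both planes
#'   before correlation (0 disables). Successive bright-field focal
#'   planes share their defocused projection content but carry
#'   uncorrelated in-focus detail; mild smoothing suppresses that
#'   structured noise and improves subpixel accuracy.
#' @return A one-row tibble: `dy_px`, `dx_px`, `peak_ncc`.
#' @export
estimate_plane_shift <- function(ref, mov, max_shift_px = 32,
                                 smooth_sigma_px = 0) {
  stopifnot(is.matrix(ref), identical(dim(ref), dim(mov)),
            max_shift_px >= 0)
  if (sd(ref) == 0 || sd(mov) == 0)
    stop("zero-variance plane: normalized cross-correlation is undefined")
  if (smooth_sigma_px > 0) {
    otf <- gauss_otf2(nrow(ref), ncol(ref), smooth_sigma_px,
                      smooth_sigma_px)
    sm <- function(m2) Re(fft(fft(m2) * otf, inverse = TRUE)) / length(m2)
    ref <- sm(ref)
    mov <- sm(mov)
  }
  m <- as.integer(max_shift_px)
  grid <- cpp_zncc_grid(ref, mov, m)
  best <- max(grid)
  cand <- which(grid == best, arr.ind = TRUE)
  dys <- cand[, 1] - m - 1L
  dxs <- cand[, 2] - m - 1L
  ord <- order(dys^2 + dxs^2, dys, dxs)
  dy <- dys[ord[1]]; dx <- dxs[ord[1]]

  # parabolic subpixel refinement per axis (only with both neighbors)
  para <- function(l, c, r) {
    den <- l - 2 * c + r
    if (den >= 0) return(0)  # not a proper peak
    off <- 0.5 * (l - r) / den
    max(-0.5, min(0.5, off))
  }
  iy <- dy + m + 1L; ix <- dx + m + 1L
  sy <- if (iy > 1 && iy < 2 * m + 1)
    para(grid[iy - 1, ix], grid[iy, ix], grid[iy + 1, ix]) else 0
  sx <- if (ix > 1 && ix < 2 * m + 1)
    para(grid[iy, ix - 1], grid[iy, ix], grid[iy, ix + 1]) else 0
  tibble::tibble(dy_px = unname(dy + sy), dx_px = unname(dx + sx),
                 peak_ncc = best)
}

#' Estimate successive-plane drift over a stack
#'
#' Applies [estimate_plane_shift()] to each pair of successive focal
#' planes; row `k` holds the shift of plane `k+1` relative to plane `k`.
#'
#' @param stack A `channel_stack` with at least 2 planes.
#' @param max_shift_px Maximum shift searched.
#' @param smooth_sigma_px Pre-smoothing for each pairwise estimate, see
#'   [estimate_plane_shift()].
#' @return A tibble with `z` (the later plane, 1-based), `dy_px`, `dx_px`,
#'   `peak_ncc`.
#' @export
estimate_stack_drift <- function(stack, max_shift_px = 32,
                                 smooth_sigma_px = 1.5) {
  stopifnot(inherits(stack, "channel_stack"))
  nz <- dim(stack$data)[3]
  if (nz < 2) {
    return(tibble::tibble(z = integer(), dy_px = numeric(),
                          dx_px = numeric(), peak_ncc = numeric()))
  }
  rows <- lapply(seq_len(nz - 1), function(k) {
    estimate_plane_shift(stack$data[, , k], stack$data[, , k + 1],
                         max_shift_px, smooth_sigma_px = smooth_sigma_px)
  })
  dplyr::bind_rows(rows, .id = NULL) |>
    dplyr::mutate(z = seq_len(nz - 1) + 1L, .before = 1)
}

#' Correct in-fluid sample drift across a stack
#'
#' Successive-plane shifts are composed cumulatively relative to plane 1,
#' and every plane is resampled by bilinear interpolation onto plane 1's
#' grid. Pixels with no source data are filled with the plane's background
#' median (avoiding spurious high-frequency edges that would fool the
#' segmentation). Shifts estimated from the bright-field channel can be
#' applied unchanged to the other channels of the same acquisition.
#'
#' @param stack A `channel_stack`.
#' @param shifts `"estimate"` (default; estimate from `stack`), or a
#'   tibble/data.frame with `dy_px`, `dx_px` and `planes - 1` rows as
#'   returned by [estimate_stack_drift()].
#' @param max_shift_px Maximum shift searched when estimating.
#' @return The drift-corrected `channel_stack`, with the successive
#'   shifts attached as attribute `"shifts"`.
#' @export
correct_stack_drift <- function(stack, shifts = "estimate",
                                max_shift_px = 32) {
  stopifnot(inherits(stack, "channel_stack"))
  nz <- dim(stack$data)[3]
  if (identical(shifts, "estimate"))
    shifts <- estimate_stack_drift(stack, max_shift_px)
  if (nrow(shifts) != nz - 1)
    stop("need one shift per successive plane pair (", nz - 1, " rows)")
  cum_dy <- cumsum(c(0, shifts$dy_px))
  cum_dx <- cumsum(c(0, shifts$dx_px))
  out <- stack
  for (k in seq_len(nz)) {
    if (cum_dy[k] == 0 && cum_dx[k] == 0) next
    plane <- stack$data[, , k]
    out$data[, , k] <- cpp_bilinear_shift(plane, cum_dy[k], cum_dx[k],
                                          median(plane))
  }
  attr(out, "shifts") <- shifts
  out
}

#' Apply externally estimated drift to another channel
#'
#' @param stack A `channel_stack` from the same acquisition.
#' @param shifts Successive-plane shift table (from
#'   [estimate_stack_drift()] on the bright-field channel).
#' @return The corrected `channel_stack`.
#' @export
apply_stack_drift <- function(stack, shifts) {
  correct_stack_drift(stack, shifts = shifts)
}

#' Drift QC plot
#'
#' @param shifts Shift table from [estimate_stack_drift()].
#' @return A ggplot of cumulative drift and peak correlation per plane.
#' @export
plot_drift <- function(shifts) {
  df <- dplyr::mutate(shifts,
                      cum_dy = cumsum(.data$dy_px),
                      cum_dx = cumsum(.data$dx_px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_dy, colour = "dy")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_dx, colour = "dx")) +
    ggplot2::labs(x = "focal plane", y = "cumulative drift (px)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
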