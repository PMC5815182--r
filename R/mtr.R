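#' Paired MR acquisitions for MTR computation
#'
#' @param s0 \code{gray_image} of the acquisition without MT saturation.
#' @param s_mt \code{gray_image} of the acquisition with MT saturation.
#' @param noise_floor intensity below which s0 is considered unreliable;
#'   pixels at or below it are flagged invalid in the MTR map.
#' @return An object of class \code{mtr_pair}.
#' @export
mtr_pair <- function(s0, s_mt, noise_floor = 0) {
  if (!identical(dim(s0$pixels), dim(s_mt$pixels)))
    stop("s0 and s_mt images have different shapes")
  if (any(s0$pixels < 0) || any(s_mt$pixels < 0))
    stop("MR intensities must be non-negative")
  structure(list(s0 = s0, s_mt = s_mt, noise_floor = noise_floor),
            class = "mtr_pair")
}

#' Robust noise floor from a background ROI
#'
#' 5 times the median absolute deviation of the s0 intensities inside a
#' user-designated background (air) region.
#'
#' @param s0 \code{gray_image} without MT saturation.
#' @param background logical/0-1 matrix of background pixels.
#' @param k multiplier on the MAD (default 5).
#' @return intensity threshold.
#' @export
estimate_noise_floor <- function(s0, background, k = 5) {
  sel <- mask_px(background) != 0L
  if (!any(sel)) stop("background region is empty")
  k * stats::mad(s0$pixels[sel])
}

#' Compute the magnetization transfer ratio map
#'
#' \code{MTR = (S0 - S_MT) / S0} per pixel, computed only where S0
#' exceeds the noise floor; elsewhere the map is NA and the validity mask
#' is 0. The ratio is dimensionless (multiply by 100 for
#' percentage-point units) and scale-invariant: multiplying both
#' acquisitions by the same factor leaves it unchanged.
#'
#' @param pair an \code{mtr_pair}.
#' @return An object of class \code{mtr_result}: \code{mtr_map}
#'   (\code{gray_image} with NA at invalid pixels) and \code{valid}
#'   (\code{binary_mask}).
#' @export
compute_mtr <- function(pair) {
  s0 <- pair$s0$pixels
  valid <- s0 > pair$noise_floor
  m <- matrix(NA_real_, nrow(s0), ncol(s0))
  m[valid] <- (s0[valid] - pair$s_mt$pixels[valid]) / s0[valid]
  res <- list(mtr_map = structure(list(pixels = m,
                                       calibration = pair$s0$calibration),
                                  class = "gray_image"),
              valid = binary_mask(valid * 1L, pair$s0$calibration))
  class(res) <- "mtr_result"
  res
}

#' Per-ROI MTR and signal statistics
#'
#' For each region: the number of valid pixels, the mean s0 signal and
#' the mean MTR over valid pixels. If control-group means are supplied,
#' normalized columns (value / control mean) are added so the control
#' group reads 1.0.
#'
#' @param result an \code{mtr_result} from \code{compute_mtr}.
#' @param pair the \code{mtr_pair} it was computed from.
#' @param rois a \code{roi_set} or a named list of ROI masks.
#' @param control_means optional list/vector with elements
#'   \code{mean_signal} and \code{mean_mtr}: the control-group means used
#'   for normalization.
#' @return data.frame with one row per ROI.
#' @export
mtr_roi_report <- function(result, pair, rois, control_means = NULL) {
  shape <- dim(pair$s0$pixels)
  masks <- if (inherits(rois, "roi_set")) roi_masks(rois, shape) else rois
  valid <- mask_px(result$valid) != 0L
  rows <- lapply(names(masks), function(nm) {
    m <- mask_px(masks[[nm]]) != 0L
    sel <- m & valid
    if (!any(sel))
      stop("ROI '", nm, "' contains no valid pixel")
    data.frame(roi_name = nm, n_valid = sum(sel),
               mean_signal = mean(pair$s0$pixels[sel]),
               mean_mtr = mean(result$mtr_map$pixels[sel]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(control_means)) {
    out$mean_signal_norm <- out$mean_signal / control_means[["mean_signal"]]
    out$mean_mtr_norm <- out$mean_mtr / control_means[["mean_mtr"]]
  }
  out
}

#' @export
print.mtr_result <- function(x, ...) {
  v <- mask_px(x$valid) != 0L
  cat(sprintf("mtr_result: %d x %d px, %d valid (mean MTR %.4f)\n",
              nrow(x$mtr_map$pixels), ncol(x$mtr_map$pixels), sum(v),
              mean(x$mtr_map$pixels[v])))
  invisible(x)
}
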