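#' Segmentation parameters
#'
#' Tunable parameters for tissue masking, adaptive soma segmentation and
#' top-hat process extraction. Radii and areas are in micrometres /
#' square micrometres and converted to pixels through the image
#' calibration. Defaults target DAB-stained microglia (Iba1) at
#' roughly 0.5 um/px; for astrocytes (GFAP) widen
#' \code{max_soma_area_um2} to ~800.
#'
#' @param tissue_threshold gray cutoff separating tissue from white
#'   background (0-255); pixels strictly darker are tissue candidates.
#' @param closing_radius_um,opening_radius_um structuring-element radii
#'   for tissue mask cleanup.
#' @param min_tissue_object_um2 smaller tissue fragments are discarded.
#' @param dark_seed_fraction fraction (0, 1) of the darkest in-tissue
#'   pixels that seeds the adaptive soma threshold.
#' @param soma_threshold_factor soma threshold = factor x seed mean gray.
#' @param min_soma_area_um2,max_soma_area_um2 soma size window.
#' @param tophat_radius_um black top-hat structuring-element radius; set
#'   just above the expected process half-width so thin dark processes
#'   respond and wide somata do not.
#' @param process_threshold_factor process binarization cutoff as a
#'   fraction of the soma darkness contrast (255 - seed mean).
#' @param min_process_object_px smaller process fragments are discarded.
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(tissue_threshold = 235,
                                closing_radius_um = 5,
                                opening_radius_um = 5,
                                min_tissue_object_um2 = 10000,
                                dark_seed_fraction = 0.002,
                                soma_threshold_factor = 3,
                                min_soma_area_um2 = 20,
                                max_soma_area_um2 = 400,
                                tophat_radius_um = 1.5,
                                process_threshold_factor = 0.15,
                                min_process_object_px = 5) {
  p <- list(tissue_threshold = tissue_threshold,
            closing_radius_um = closing_radius_um,
            opening_radius_um = opening_radius_um,
            min_tissue_object_um2 = min_tissue_object_um2,
            dark_seed_fraction = dark_seed_fraction,
            soma_threshold_factor = soma_threshold_factor,
            min_soma_area_um2 = min_soma_area_um2,
            max_soma_area_um2 = max_soma_area_um2,
            tophat_radius_um = tophat_radius_um,
            process_threshold_factor = process_threshold_factor,
            min_process_object_px = min_process_object_px)
  stopifnot(p$closing_radius_um > 0, p$opening_radius_um > 0,
            p$min_tissue_object_um2 > 0,
            p$dark_seed_fraction > 0, p$dark_seed_fraction < 1,
            p$soma_threshold_factor > 0,
            p$min_soma_area_um2 > 0, p$max_soma_area_um2 > p$min_soma_area_um2,
            p$tophat_radius_um > 0, p$process_threshold_factor > 0,
            p$min_process_object_px >= 1)
  structure(p, class = "segmentation_params")
}

disc_brush <- function(radius_um, calibration) {
  r <- max(1L, round(radius_um / calibration))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# drop labeled objects with pixel count below min_px (8-connected)
remove_small_objects <- function(bin, min_px) {
  if (!any(bin != 0L)) return(bin)
  storage.mode(bin) <- "integer"
  lab <- label8_cpp(bin)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  out <- matrix(0L, nrow(bin), ncol(bin))
  out[lab %in% keep] <- 1L
  out
}

#' Segment tissue from white background
#'
#' Thresholding (pixels darker than \code{tissue_threshold}), then
#' morphological closing, hole filling (border-connected background flood
#' fill), opening, and removal of objects smaller than
#' \code{min_tissue_object_um2} — in exactly that order.
#'
#' @param gray a \code{gray_image} in [0, 255] (chromogen gray or overall
#'   brightness).
#' @param params \code{segmentation_params}.
#' @return A \code{binary_mask} of valid tissue (possibly empty).
#' @export
segment_tissue <- function(gray, params = segmentation_params()) {
  cal <- gray$calibration
  bin <- (gray$pixels < params$tissue_threshold) * 1L
  if (any(bin != 0L)) {
    bin <- EBImage::closing(bin, disc_brush(params$closing_radius_um, cal))
    bin <- EBImage::fillHull(bin)
    bin <- EBImage::opening(bin, disc_brush(params$opening_radius_um, cal))
    bin <- remove_small_objects(round(bin),
                                ceiling(params$min_tissue_object_um2 / cal^2))
  }
  binary_mask(bin, cal)
}

#' Adaptive soma threshold
#'
#' The seed mean is the average gray of the darkest
#' \code{dark_seed_fraction} of in-tissue pixels (the "sufficiently dark"
#' regions indicative of soma); the binarization threshold is
#' \code{soma_threshold_factor} times that mean, clamped to [0, 255]. The
#' seed mean is returned alongside for reuse in process binarization.
#'
#' @param gray chromogen \code{gray_image}.
#' @param tissue tissue \code{binary_mask}.
#' @param params \code{segmentation_params}.
#' @return list with \code{threshold} and \code{seed_mean}.
#' @export
adaptive_soma_threshold <- function(gray, tissue,
                                    params = segmentation_params()) {
  g <- gray$pixels[mask_px(tissue) != 0L]
  if (length(g) == 0L) stop("tissue mask is empty")
  k <- max(1L, round(params$dark_seed_fraction * length(g)))
  seed_mean <- mean(sort(g, partial = k)[seq_len(k)])
  thr <- min(255, max(0, params$soma_threshold_factor * seed_mean))
  list(threshold = thr, seed_mean = seed_mean)
}

#' Segment soma objects
#'
#' Binarizes in-tissue pixels at the adaptive threshold (gray <=
#' threshold), labels 8-connected objects, removes objects outside the
#' soma area window, and renumbers labels consecutively.
#'
#' @param gray chromogen \code{gray_image}.
#' @param tissue tissue \code{binary_mask}.
#' @param threshold gray cutoff from \code{adaptive_soma_threshold}.
#' @param params \code{segmentation_params}.
#' @return A \code{label_map} of soma objects (possibly empty).
#' @export
segment_soma <- function(gray, tissue, threshold,
                         params = segmentation_params()) {
  cal <- gray$calibration
  bin <- (gray$pixels <= threshold & mask_px(tissue) != 0L) * 1L
  lab <- label8_cpp(bin)
  k <- attr(lab, "object_count")
  if (k > 0L) {
    px_area <- tabulate(lab[lab > 0L], nbins = k) * cal^2
    keep <- which(px_area >= params$min_soma_area_um2 &
                  px_area <= params$max_soma_area_um2)
    relab <- integer(k)
    relab[keep] <- seq_along(keep)
    out <- matrix(0L, nrow(bin), ncol(bin))
    nz <- lab > 0L
    out[nz] <- relab[lab[nz]]
    lab <- out
  }
  label_map(lab, cal)
}

#' Segment thin processes by black top-hat
#'
#' Black top-hat (morphological closing minus image) with a disc of
#' radius \code{tophat_radius_um} responds strongly to dark structures
#' thinner than the disc and suppresses wide soma-scale objects. The
#' response is binarized at \code{process_threshold_factor x (255 -
#' seed_mean)} — i.e. a fixed fraction of the soma darkness contrast —
#' restricted to tissue, size-filtered, and finally all soma pixels are
#' set to 0 to leave the mask of true processes.
#'
#' @param gray chromogen \code{gray_image}.
#' @param tissue tissue \code{binary_mask}.
#' @param soma soma \code{label_map}.
#' @param seed_mean seed mean gray from \code{adaptive_soma_threshold}.
#' @param params \code{segmentation_params}.
#' @return A soma-free \code{binary_mask} of processes.
#' @export
segment_processes <- function(gray, tissue, soma, seed_mean,
                              params = segmentation_params()) {
  cal <- gray$calibration
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  th <- 255 * EBImage::blackTopHat(gray$pixels / 255,
                                   disc_brush(params$tophat_radius_um, cal))
  cutoff <- params$process_threshold_factor * (255 - seed_mean)
  bin <- (th > cutoff & mask_px(tissue) != 0L) * 1L
  bin <- remove_small_objects(bin, params$min_process_object_px)
  bin[mask_px(soma) > 0L] <- 0L
  binary_mask(bin, cal)
}

#' Ultimate thinning of the process mask
#'
#' Homotopic thinning to one-pixel-wide lines: simple border pixels are
#' deleted sequentially (cycling over the four cardinal directions) until
#' stability, preserving both the 8-connectivity of every component and
#' line endpoints, so skeleton path lengths reflect process lengths.
#'
#' @param processes process \code{binary_mask}.
#' @return A \code{binary_mask} skeleton, subset of the input.
#' @export
skeletonize_processes <- function(processes) {
  px <- mask_px(processes)
  storage.mode(px) <- "integer"
  binary_mask(thin_cpp(px), processes$calibration)
}

#' Overall brightness of an RGB section
#'
#' Mean of the three channels; the natural input for tissue-vs-white
#' background masking (the chromogen gray is bright wherever only the
#' counterstain is present, so it cannot separate tissue from slide).
#'
#' @param section a \code{stained_section}.
#' @return A \code{gray_image} in [0, 255].
#' @export
brightness_gray <- function(section) {
  gray_image((section$pixels[, , 1L] + section$pixels[, , 2L] +
              section$pixels[, , 3L]) / 3, section$calibration)
}

#' Run the full segmentation sequence
#'
#' Tissue mask, adaptive soma threshold, soma labeling, top-hat process
#' extraction with soma subtraction, and skeletonization, in that fixed
#' order.
#'
#' @param gray chromogen \code{gray_image} (from \code{chromogen_gray}).
#' @param params \code{segmentation_params}.
#' @param tissue_gray \code{gray_image} used for the tissue mask
#'   (typically \code{brightness_gray} of the section); defaults to
#'   \code{gray}.
#' @return An object of class \code{glia_segmentation}: list with
#'   \code{tissue}, \code{soma}, \code{soma_gray_mean} (seed mean),
#'   \code{threshold}, \code{processes}, \code{skeleton}.
#' @export
segment_glia <- function(gray, params = segmentation_params(),
                         tissue_gray = gray) {
  tissue <- segment_tissue(tissue_gray, params)
  if (!any(mask_px(tissue) != 0L)) {
    empty <- binary_mask(matrix(0L, nrow(gray$pixels), ncol(gray$pixels)),
                         gray$calibration)
    return(structure(list(tissue = tissue,
                          soma = label_map(empty$pixels, gray$calibration),
                          soma_gray_mean = NA_real_, threshold = NA_real_,
                          processes = empty, skeleton = empty),
                     class = "glia_segmentation"))
  }
  ad <- adaptive_soma_threshold(gray, tissue, params)
  soma <- segment_soma(gray, tissue, ad$threshold, params)
  processes <- segment_processes(gray, tissue, soma, ad$seed_mean, params)
  skeleton <- skeletonize_processes(processes)
  structure(list(tissue = tissue, soma = soma,
                 soma_gray_mean = ad$seed_mean, threshold = ad$threshold,
                 processes = processes, skeleton = skeleton),
            class = "glia_segmentation")
}

#' @export
print.glia_segmentation <- function(x, ...) {
  cat(sprintf(paste0("glia_segmentation: %d soma objects, %d process px, ",
                     "%d skeleton px (threshold %.1f)\n"),
              x$soma$object_count, sum(mask_px(x$processes)),
              sum(mask_px(x$skeleton)), x$threshold))
  invisible(x)
}
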