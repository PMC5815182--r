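#' Mean optical density of an object set against local background
#'
#' Chromogen densitometry: \code{OD = log10(mean_gray(background) /
#' mean_gray(objects))}, where the background is the in-tissue area not
#' covered by any visible cell (the exclusion mask). Equal object and
#' background brightness gives OD 0; a 10x darker object gives OD 1.
#'
#' @param gray chromogen \code{gray_image}.
#' @param objects \code{binary_mask} (or matrix) of the measured pixels.
#' @param tissue tissue \code{binary_mask}.
#' @param exclusion \code{binary_mask} of all visible-cell pixels to
#'   exclude from the background (defaults to \code{objects}).
#' @return mean OD (a single number).
#' @export
optical_density <- function(gray, objects, tissue, exclusion = objects) {
  obj <- mask_px(objects) != 0L
  if (!any(obj)) stop("object mask is empty")
  bg <- mask_px(tissue) != 0L & mask_px(exclusion) == 0L
  if (!any(bg)) stop("background region is empty")
  log10(mean(gray$pixels[bg]) / mean(gray$pixels[obj]))
}

# corner-corrected boundary-walk perimeter (Vossepoel-Smeulders weights):
# 0.980 per axial step, 1.406 per diagonal step, -0.091 per corner.
# Converges to the true perimeter of smooth shapes, where the naive
# 1/sqrt(2) walk overestimates by ~5% from staircase zigzag.
perimeter_walk <- function(bin) {
  if (sum(bin) == 1L) return(4)  # single pixel: unit-square boundary
  oc <- EBImage::ocontour(bin)[[1L]]
  n <- nrow(oc)
  if (n < 2L) return(4)
  d <- rbind(diff(oc), oc[1L, , drop = FALSE] - oc[n, , drop = FALSE])
  diag <- rowSums(abs(d)) == 2L
  dir <- d[, 1L] * 3L + d[, 2L]
  corners <- sum(dir != c(dir[-1L], dir[1L]))
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * corners
}

skeleton_length_px <- function(skel_bin) {
  storage.mode(skel_bin) <- "integer"
  skeleton_length_cpp(skel_bin)
}

#' Length of a skeleton in micrometres
#'
#' Chain length of a one-pixel-wide skeleton: each 4-adjacent pixel pair
#' is one pixel step, each diagonal pair counts sqrt(2) (unless the two
#' pixels already share an orthogonal skeleton neighbour, which would
#' double-count the corner), multiplied by the calibration. A straight
#' horizontal run of 100 pixels has 99 steps.
#'
#' @param skeleton a \code{binary_mask} skeleton.
#' @return total length in micrometres.
#' @export
skeleton_length_um <- function(skeleton) {
  skeleton_length_px(mask_px(skeleton)) * skeleton$calibration
}

#' Per-cell morphometric features
#'
#' Computes, for every cell of an arbor decomposition: soma area
#' (pixel count x calibration^2), soma perimeter (corner-corrected
#' boundary walk), form factor (4 pi area / perimeter^2; 1 for a circle),
#' proximal/distal areas, proximal/distal process lengths measured on the
#' skeleton restricted to each compartment (orthogonal step 1 px,
#' diagonal step sqrt(2) px, x calibration), and soma / visible-cell
#' optical densities against the local non-cell background.
#'
#' @param decomp an \code{arbor_decomposition}.
#' @param seg the \code{glia_segmentation} it came from.
#' @param gray the chromogen \code{gray_image} (for optical densities);
#'   omit to skip the OD columns.
#' @return data.frame with one row per cell.
#' @export
morphometric_features <- function(decomp, seg, gray = NULL) {
  cal <- decomp$calibration
  nr <- decomp$shape[1L]; nc <- decomp$shape[2L]
  skel <- mask_px(seg$skeleton)
  visible_all <- mask_px(decomp$visible)
  k <- length(decomp$cells)
  rows <- vector("list", k)
  for (s in seq_len(k)) {
    cl <- decomp$cells[[s]]
    soma_bin <- matrix(0L, nr, nc)
    soma_bin[cl$soma] <- 1L
    area <- length(cl$soma) * cal^2
    per <- perimeter_walk(soma_bin) * cal
    # quantization can push tiny objects above 1; cap at 1 (ImageJ
    # circularity convention)
    ff <- if (per > 0) min(1, 4 * pi * area / per^2) else NA_real_
    comp_len <- function(idx) {
      if (!length(idx)) return(0)
      m <- matrix(0L, nr, nc)
      m[idx] <- skel[idx]
      skeleton_length_px(m) * cal
    }
    soma_od <- visible_od <- NA_real_
    if (!is.null(gray)) {
      vis_bin <- matrix(0L, nr, nc)
      vis_bin[cl$visible] <- 1L
      soma_od <- optical_density(gray, soma_bin, seg$tissue, visible_all)
      visible_od <- optical_density(gray, vis_bin, seg$tissue, visible_all)
    }
    rows[[s]] <- data.frame(
      soma_id = s,
      centroid_row = cl$centroid[1L], centroid_col = cl$centroid[2L],
      soma_area_um2 = area, soma_perimeter_um = per, soma_form_factor = ff,
      proximal_area_um2 = length(cl$proximal) * cal^2,
      distal_area_um2 = length(cl$distal) * cal^2,
      proximal_length_um = comp_len(cl$proximal),
      distal_length_um = comp_len(cl$distal),
      soma_od = soma_od, visible_od = visible_od)
  }
  if (k == 0L) {
    return(data.frame(soma_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), soma_area_um2 = numeric(0),
                      soma_perimeter_um = numeric(0),
                      soma_form_factor = numeric(0),
                      proximal_area_um2 = numeric(0),
                      distal_area_um2 = numeric(0),
                      proximal_length_um = numeric(0),
                      distal_length_um = numeric(0),
                      soma_od = numeric(0), visible_od = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Microglia activation index
#'
#' Soma plus proximal-process area normalized to distal-process area:
#' \code{(sum soma_area + sum proximal_area) / sum distal_area} over the
#' given cells. Activated (ameboid) cells retract their distal arbor, so
#' the index rises with activation. Returns \code{NA} (undefined) when
#' the distal sum is 0 rather than infinity.
#'
#' @param cells per-cell feature rows (from \code{morphometric_features}),
#'   already restricted to the ROI of interest.
#' @return dimensionless ratio, or NA if undefined.
#' @export
activation_index <- function(cells) {
  if (nrow(cells) == 0L) return(NA_real_)
  dist_sum <- sum(cells$distal_area_um2)
  if (dist_sum <= 0) return(NA_real_)
  (sum(cells$soma_area_um2) + sum(cells$proximal_area_um2)) / dist_sum
}

#' Microglia size index
#'
#' Soma plus proximal-process area normalized to the number of cells
#' (square micrometres per cell). Undefined (NA) when there are no cells.
#'
#' @param cells per-cell feature rows restricted to the ROI.
#' @return square micrometres per cell, or NA if undefined.
#' @export
size_index <- function(cells) {
  if (nrow(cells) == 0L) return(NA_real_)
  (sum(cells$soma_area_um2) + sum(cells$proximal_area_um2)) / nrow(cells)
}

#' Stained area fraction and integrated density in a ROI
#'
#' Bulk-stain quantification (e.g. MBP/MOG myelin stains):
#' \code{fraction} is the share of in-ROI tissue pixels at or below the
#' gray threshold (i.e. stained); \code{integrated_density} sums
#' (255 - gray) x calibration^2 over those stained pixels, an
#' ImageJ-style IntDen in intensity x square micrometres.
#'
#' @param gray chromogen \code{gray_image}.
#' @param tissue tissue \code{binary_mask}.
#' @param roi logical/0-1 matrix of the ROI.
#' @param threshold gray cutoff; pixels with gray <= threshold count as
#'   stained.
#' @return list with \code{fraction} and \code{integrated_density}.
#' @export
stained_area_fraction <- function(gray, tissue, roi, threshold) {
  cal <- gray$calibration
  sel <- mask_px(tissue) != 0L & mask_px(roi) != 0L
  if (!any(sel)) stop("ROI does not intersect tissue")
  g <- gray$pixels[sel]
  stained <- g <= threshold
  list(fraction = mean(stained),
       integrated_density = sum((255 - g[stained])) * cal^2)
}

#' Normalize measurements to the control group
#'
#' Divides every value by the mean of the control-group values, so the
#' control mean maps to exactly 1.0 and other groups read as fold of
#' control.
#'
#' @param values numeric vector of per-sample measurements.
#' @param groups group label per sample.
#' @param control_group label of the control group.
#' @return numeric vector of normalized values, same order as input.
#' @export
normalize_to_control <- function(values, groups, control_group) {
  sel <- groups == control_group
  if (!any(sel)) stop("control group '", control_group, "' is empty")
  m <- mean(values[sel])
  if (m == 0) stop("control group mean is zero; cannot normalize")
  values / m
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' dCt = target Ct - reference-gene Ct per sample; ddCt = dCt - mean dCt
#' of the calibrator group; fold change = 2^-ddCt (so the calibrator
#' group averages a fold change of 1 on the log scale).
#'
#' @param table data.frame with columns \code{sample}, \code{group},
#'   \code{target_ct}, \code{reference_ct}.
#' @param calibrator_group label of the calibrator (control) group.
#' @return the input with added \code{delta_ct}, \code{ddct},
#'   \code{fold_change} columns.
#' @export
ddct_fold_change <- function(table, calibrator_group) {
  need <- c("sample", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$target_ct)) || any(!is.finite(table$reference_ct)))
    stop("Ct values must be finite")
  sel <- table$group == calibrator_group
  if (!any(sel)) stop("calibrator group '", calibrator_group, "' is empty")
  table$delta_ct <- table$target_ct - table$reference_ct
  table$ddct <- table$delta_ct - mean(table$delta_ct[sel])
  table$fold_change <- 2^(-table$ddct)
  table
}

#' Per-ROI quantification
#'
#' Aggregates per-cell features over each ROI (a cell belongs to the ROI
#' whose mask contains its soma centroid) and adds bulk-stain readouts:
#' soma count, soma density per square millimetre of in-ROI tissue,
#' activation and size indices, stained area fraction and integrated
#' density.
#'
#' @param cells per-cell feature table from \code{morphometric_features}.
#' @param seg the \code{glia_segmentation}.
#' @param gray chromogen \code{gray_image}.
#' @param rois named list of ROI masks (see \code{roi_masks}), or NULL to
#'   use the whole tissue as a single ROI named "all".
#' @param stain_threshold gray cutoff for the stained-area readouts
#'   (defaults to the segmentation soma threshold).
#' @return data.frame with one row per ROI.
#' @export
roi_features <- function(cells, seg, gray, rois = NULL,
                         stain_threshold = NULL) {
  cal <- gray$calibration
  tissue <- mask_px(seg$tissue)
  if (is.null(rois))
    rois <- list(all = tissue != 0L)
  if (is.null(stain_threshold)) stain_threshold <- seg$threshold
  rows <- lapply(names(rois), function(nm) {
    m <- mask_px(rois[[nm]]) != 0L
    inroi <- if (nrow(cells)) {
      ri <- round(cells$centroid_row) + 1L
      ci <- round(cells$centroid_col) + 1L
      m[cbind(pmin(pmax(ri, 1L), nrow(m)), pmin(pmax(ci, 1L), ncol(m)))]
    } else logical(0)
    sub <- cells[inroi, , drop = FALSE]
    tissue_area_um2 <- sum(tissue != 0L & m) * cal^2
    saf <- if (tissue_area_um2 > 0 && is.finite(stain_threshold))
      stained_area_fraction(gray, seg$tissue, m, stain_threshold)
    else list(fraction = NA_real_, integrated_density = NA_real_)
    data.frame(roi_name = nm,
               soma_count = nrow(sub),
               soma_count_per_mm2 = if (tissue_area_um2 > 0)
                 nrow(sub) / (tissue_area_um2 / 1e6) else NA_real_,
               activation_index = activation_index(sub),
               size_index = size_index(sub),
               stained_area_fraction = saf$fraction,
               integrated_density = saf$integrated_density)
  })
  do.call(rbind, rows)
}
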