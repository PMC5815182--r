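# run code under a private RNG stream, restoring global state afterwards
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

#' Default cell geometry per morphotype
#'
#' Ramified (resting) cells: small soma, 4-6 long thin processes.
#' Ameboid (activated) cells: enlarged soma, 2-3 short thick processes.
#' Radii and lengths in micrometres; thickness in pixels at the default
#' 0.5 um/px calibration; stain amplitude is the peak chromogen optical
#' density.
#'
#' @param morphotype "ramified" or "ameboid".
#' @return list of sampling ranges for \code{generate_histology}.
#' @export
cell_spec_defaults <- function(morphotype = c("ramified", "ameboid")) {
  morphotype <- match.arg(morphotype)
  if (morphotype == "ramified")
    list(soma_radius_um = c(2.8, 3.8), n_primary = 4:6,
         process_length_um = c(mean = 40, sd = 10), min_length_um = 10,
         branch_probability = 0.04, thickness_px = 1:2,
         soma_amplitude = c(1.0, 1.3), process_amplitude = c(0.40, 0.50),
         turn_sd = 0.15)
  else
    list(soma_radius_um = c(4.0, 5.5), n_primary = 2:3,
         process_length_um = c(mean = 10, sd = 3), min_length_um = 4,
         branch_probability = 0.02, thickness_px = 2:3,
         soma_amplitude = c(1.1, 1.4), process_amplitude = c(0.45, 0.55),
         turn_sd = 0.25)
}

# random walk from (r0, c0) at angle theta0, unit steps in px, wrapped
# normal turns; may branch recursively. Returns list of polylines
# (continuous (r, c) coordinates) clipped to the field.
draw_process <- function(r0, c0, theta0, n_steps, turn_sd, branch_prob,
                         nr, nc, depth = 0L) {
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- c(r0, c0)
  theta <- theta0
  branches <- list()
  i <- 1L
  while (i <= n_steps) {
    theta <- theta + stats::rnorm(1L, 0, turn_sd)
    r1 <- pts[i, 1L] + sin(theta)
    c1 <- pts[i, 2L] + cos(theta)
    if (r1 < 1 || r1 > nr - 2 || c1 < 1 || c1 > nc - 2) break
    pts[i + 1L, ] <- c(r1, c1)
    i <- i + 1L
    if (depth < 2L && i < n_steps && stats::runif(1L) < branch_prob) {
      side <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.6, 1.2)
      branches <- c(branches,
                    draw_process(r1, c1, theta + side, n_steps - i,
                                 turn_sd, branch_prob, nr, nc, depth + 1L))
    }
  }
  c(list(pts[seq_len(i), , drop = FALSE]), branches)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# length of a polyline inside/outside a circle (by segment midpoints)
split_length <- function(pts, center, radius) {
  if (nrow(pts) < 2L) return(c(inside = 0, outside = 0))
  seg <- sqrt(rowSums(diff(pts)^2))
  mid <- (pts[-1L, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
  d <- sqrt((mid[, 1L] - center[1L])^2 + (mid[, 2L] - center[2L])^2)
  c(inside = sum(seg[d <= radius]), outside = sum(seg[d > radius]))
}

# pixel indices covered by a polyline stamped at the given thickness
stamp_polyline <- function(pts, thickness, nr, nc) {
  off <- seq_len(thickness) - 1L - (thickness - 1L) %/% 2L
  r <- round(pts[, 1L]) + 1L
  c <- round(pts[, 2L]) + 1L
  idx <- integer(0)
  for (dr in off) for (dc in off) {
    rr <- pmin(pmax(r + dr, 1L), nr)
    cc <- pmin(pmax(c + dc, 1L), nc)
    idx <- c(idx, rr + (cc - 1L) * nr)
  }
  unique(idx)
}

#' Generate a ground-truthed synthetic histology field
#'
#' Renders brown (DAB) ramified/ameboid glial cells on a
#' hematoxylin-textured tissue background via the Beer-Lambert model with
#' the package's default stain vectors, plus Gaussian pixel noise. Somata
#' are ellipses placed by rejection sampling with a minimum edge-to-edge
#' separation of 15 um; processes are random walks that may branch.
#' Identical seeds give bitwise-identical images and ground truth.
#'
#' @param n_cells number of cells (>= 0).
#' @param field_size_um side of the square field in micrometres.
#' @param morphotype_mix named proportions, e.g.
#'   \code{c(ramified = 1)} or \code{c(ramified = 0.5, ameboid = 0.5)}.
#' @param calibration micrometres per pixel.
#' @param seed integer seed; the generator uses a private RNG stream.
#' @param noise_sd Gaussian pixel-noise standard deviation in intensity
#'   units (0-255 scale).
#' @param influence_radius_um radius used to split ground-truth process
#'   lengths into proximal/distal (matches \code{arbor_params}).
#' @param background_od mean hematoxylin optical density of the tissue.
#' @param amplitude_scale multiplier on the sampled chromogen amplitudes
#'   (1 = the morphotype defaults); useful for staining-intensity series.
#' @param stains \code{stain_matrix} used for rendering.
#' @return list with \code{section} (a \code{stained_section}) and
#'   \code{truth} (per-cell specs, soma masks, polylines and lengths;
#'   image-level cell count and stained-area fraction).
#' @export
generate_histology <- function(n_cells = 30, field_size_um = 500,
                               morphotype_mix = c(ramified = 1),
                               calibration = 0.5, seed = 1,
                               noise_sd = 4, influence_radius_um = 12,
                               background_od = 0.12, amplitude_scale = 1,
                               stains = default_stain_matrix()) {
  stopifnot(n_cells >= 0, field_size_um > 0, calibration > 0)
  n <- round(field_size_um / calibration)
  with_seed(seed, {
    # morphotype assignment: fixed counts from the mix proportions
    mix <- morphotype_mix / sum(morphotype_mix)
    counts <- round(mix * n_cells)
    while (sum(counts) > n_cells) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    while (sum(counts) < n_cells) counts[which.max(mix)] <- counts[which.max(mix)] + 1L
    types <- rep(names(counts), counts)

    margin_um <- min(25, field_size_um / 5)
    margin <- margin_um / calibration
    centers <- matrix(NA_real_, n_cells, 2L)
    radii <- matrix(NA_real_, n_cells, 2L)
    sep_um <- 15
    for (i in seq_len(n_cells)) {
      def <- cell_spec_defaults(types[i])
      rad <- stats::runif(2L, def$soma_radius_um[1L], def$soma_radius_um[2L])
      ok <- FALSE
      for (try in seq_len(2000L)) {
        cand <- stats::runif(2L, margin, n - 1 - margin)
        if (i == 1L) { ok <- TRUE; break }
        prev <- seq_len(i - 1L)
        d_um <- sqrt(rowSums((centers[prev, , drop = FALSE] -
                              matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) *
          calibration
        gap <- d_um - max(rad) - apply(radii[prev, , drop = FALSE], 1L, max)
        if (all(gap >= sep_um)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place ", n_cells,
             " non-overlapping cells; try fewer cells or a larger field")
      centers[i, ] <- cand
      radii[i, ] <- rad
    }

    od_dab <- matrix(0, n, n)
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      def <- cell_spec_defaults(types[i])
      cen <- centers[i, ]
      rad_px <- radii[i, ] / calibration
      # soma ellipse rendered inside its bounding window only
      w_r <- max(1L, floor(cen[1L] - rad_px[1L])):min(n, ceiling(cen[1L] + rad_px[1L]) + 2L)
      w_c <- max(1L, floor(cen[2L] - rad_px[2L])):min(n, ceiling(cen[2L] + rad_px[2L]) + 2L)
      inside <- outer(((w_r - 1L) - cen[1L])^2 / rad_px[1L]^2,
                      ((w_c - 1L) - cen[2L])^2 / rad_px[2L]^2, "+") <= 1
      soma_idx <- as.integer(outer(w_r, (w_c - 1L) * n, "+"))[inside]
      soma_amp <- amplitude_scale * stats::runif(1L, def$soma_amplitude[1L],
                                                 def$soma_amplitude[2L])
      proc_amp <- amplitude_scale * stats::runif(1L, def$process_amplitude[1L],
                                                 def$process_amplitude[2L])
      n_proc <- sample(def$n_primary, 1L)
      thick <- sample(def$thickness_px, 1L)
      angles <- stats::runif(1L) * 2 * pi + 2 * pi * seq_len(n_proc) / n_proc
      polylines <- list()
      proc_idx <- integer(0)
      for (a in angles) {
        len_um <- max(def$min_length_um,
                      stats::rnorm(1L, def$process_length_um["mean"],
                                   def$process_length_um["sd"]))
        n_steps <- round(len_um / calibration)
        start <- cen + c(sin(a), cos(a)) * (rad_px + 0.5)
        pls <- draw_process(start[1L], start[2L], a, n_steps, def$turn_sd,
                            def$branch_probability, n, n)
        polylines <- c(polylines, pls)
        for (pl in pls)
          proc_idx <- c(proc_idx, stamp_polyline(pl, thick, n, n))
      }
      proc_idx <- setdiff(unique(proc_idx), soma_idx)
      od_dab[soma_idx] <- soma_amp
      od_dab[proc_idx] <- pmax(od_dab[proc_idx], proc_amp)
      lens <- vapply(polylines, polyline_length, numeric(1)) * calibration
      splits <- vapply(polylines, split_length, c(inside = 0, outside = 0),
                       center = cen, radius = influence_radius_um / calibration)
      cells[[i]] <- list(
        morphotype = types[i], centroid = cen,
        soma_radii_um = radii[i, ], n_primary_processes = n_proc,
        thickness_px = thick, soma_amplitude = soma_amp,
        process_amplitude = proc_amp,
        soma_idx = soma_idx, process_idx = proc_idx,
        polylines = polylines,
        skeleton_length_um = sum(lens),
        proximal_length_um = sum(splits["inside", ]) * calibration,
        distal_length_um = sum(splits["outside", ]) * calibration)
    }

    # hematoxylin background with smooth texture
    tex <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = 8)
    tex <- tex / max(stats::sd(tex), 1e-12) * 0.02
    od_he <- pmax(background_od + tex, 0)

    V <- unclass(stains)
    px <- array(0L, c(n, n, 3L))
    for (ch in 1:3) {
      od_ch <- od_dab * V[ch, 1L] + od_he * V[ch, 2L]
      ival <- 256 * 10^(-od_ch) - 1
      if (noise_sd > 0) ival <- ival + stats::rnorm(n * n, 0, noise_sd)
      px[, , ch] <- pmin(pmax(round(ival), 0L), 255L)
    }
    stained <- od_dab > 0
    truth <- list(cells = cells, cell_count = n_cells,
                  stained_mask = which(stained),
                  stained_area_fraction = mean(stained),
                  field_px = n, calibration = calibration,
                  influence_radius_um = influence_radius_um, seed = seed)
    list(section = stained_section(px, calibration,
                                   label = sprintf("synthetic-seed%d", seed)),
         truth = truth)
  })
}

#' Generate a synthetic MR acquisition pair with known MTR
#'
#' \code{s0 = s0_level + N(0, noise_sd)} and
#' \code{s_mt = s0_level (1 - MTR_region) + N(0, noise_sd)} with
#' independent noise, so \code{compute_mtr} recovers the regional MTR
#' exactly when \code{noise_sd = 0}. Intensities are clipped at 0.
#'
#' @param shape c(rows, cols) of the images.
#' @param rois named list of logical/0-1 region masks (regions may not
#'   overlap); pixels outside every region have MTR 0.
#' @param mtr_by_region named numeric vector in [0, 1), one entry per ROI.
#' @param s0_level signal level of the unsaturated acquisition (> 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed (private RNG stream).
#' @return list with \code{pair} (an \code{mtr_pair}), \code{truth}
#'   (noiseless MTR field matrix) and \code{rois}.
#' @export
generate_mr_pair <- function(shape = c(128, 128), rois, mtr_by_region,
                             s0_level = 200, noise_sd = 0, seed = 1) {
  stopifnot(s0_level > 0, all(mtr_by_region >= 0), all(mtr_by_region < 1))
  truth <- matrix(0, shape[1L], shape[2L])
  for (nm in names(rois)) {
    m <- mask_px(rois[[nm]]) != 0L
    if (any(truth[m] != 0))
      stop("ROI regions overlap at '", nm, "'")
    truth[m] <- mtr_by_region[[nm]]
  }
  with_seed(seed, {
    s0 <- s0_level + stats::rnorm(length(truth), 0, noise_sd)
    smt <- s0_level * (1 - truth) + stats::rnorm(length(truth), 0, noise_sd)
    s0 <- matrix(pmax(s0, 0), shape[1L], shape[2L])
    smt <- matrix(pmax(smt, 0), shape[1L], shape[2L])
    list(pair = mtr_pair(gray_image(s0, 1), gray_image(smt, 1),
                         noise_floor = 0),
         truth = truth, rois = rois)
  })
}
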