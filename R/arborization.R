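#' Arbor decomposition parameters
#'
#' @param soma_dilations number of 3x3 dilation iterations applied to each
#'   soma to form the proximal marker region (>= 1).
#' @param influence_radius_um radius (micrometres) of the circular
#'   influence zone around the soma centroid separating proximal from
#'   distal processes.
#' @return An object of class \code{arbor_params}.
#' @export
arbor_params <- function(soma_dilations = 2, influence_radius_um = 12) {
  stopifnot(soma_dilations >= 1, influence_radius_um > 0)
  structure(list(soma_dilations = as.integer(soma_dilations),
                 influence_radius_um = influence_radius_um),
            class = "arbor_params")
}

#' Morphological reconstruction from markers
#'
#' Binary geodesic reconstruction: returns the union of all 8-connected
#' components of \code{mask} that intersect \code{markers} (markers are
#' intersected with the mask first, so they need not be a subset).
#'
#' @param mask a \code{binary_mask} (or 0/1 matrix).
#' @param markers a \code{binary_mask} (or 0/1 matrix), same shape.
#' @return A \code{binary_mask}.
#' @export
reconstruct_from_markers <- function(mask, markers) {
  cal <- if (inherits(mask, "binary_mask")) mask$calibration else 1
  m <- mask_px(mask)
  storage.mode(m) <- "integer"
  mk <- mask_px(markers) != 0L & m != 0L
  out <- matrix(0L, nrow(m), ncol(m))
  if (any(mk)) {
    lab <- label8_cpp(m)
    hit <- unique(lab[mk])
    out[lab %in% hit] <- 1L
  }
  binary_mask(out, cal)
}

dilate_n <- function(bin, n) {
  k <- matrix(1L, 3L, 3L)
  for (i in seq_len(n)) bin <- EBImage::dilate(bin, k)
  round(bin)
}

#' Decompose each cell's arbor into proximal and distal processes
#'
#' For each soma object with centroid c: the soma dilated
#' \code{soma_dilations} times is the marker; skeleton pixels inside the
#' circular influence zone disk(c, r) that are reachable from the marker
#' form the proximal thinned processes; reconstructing the full process
#' mask from those and clipping to the disk gives the final proximal
#' processes; soma plus proximal processes is the "visible" cell; the
#' reconstructed processes outside the disk are the distal processes.
#' Process components touching no marker (out-of-focus arbors or debris)
#' belong to no cell. A pixel claimable by two cells is assigned to the
#' cell with the nearer soma centroid (ties to the lower label), so cell
#' masks partition the claimed process pixels.
#'
#' @param seg a \code{glia_segmentation}.
#' @param params an \code{arbor_params}.
#' @return An object of class \code{arbor_decomposition}: per-cell pixel
#'   index sets (\code{cells}: soma_id, centroid, soma/proximal/distal/
#'   visible indices) plus image-level union masks \code{proximal},
#'   \code{distal}, \code{visible} and the image \code{shape}.
#' @export
decompose_arbors <- function(seg, params = arbor_params()) {
  if (is.null(seg$skeleton)) stop("segmentation lacks a skeleton")
  cal <- seg$soma$calibration
  soma <- seg$soma$pixels
  proc <- mask_px(seg$processes)
  skel <- mask_px(seg$skeleton)
  nr <- nrow(soma); nc <- ncol(soma)
  k <- seg$soma$object_count
  r_px <- params$influence_radius_um / cal

  lab_proc <- label8_cpp(proc)
  n_comp <- attr(lab_proc, "object_count")
  comp_idx <- if (n_comp > 0L)
    split(which(lab_proc > 0L), lab_proc[lab_proc > 0L]) else list()

  centroids <- matrix(NA_real_, k, 2L)
  for (s in seq_len(k)) {
    idx <- which(soma == s)
    centroids[s, ] <- c(mean((idx - 1L) %% nr), mean((idx - 1L) %/% nr))
  }

  # ownership of claimed process pixels: nearest centroid, tie lower label
  owner <- matrix(0L, nr, nc)
  owner_d <- matrix(Inf, nr, nc)
  cells <- vector("list", k)

  for (s in seq_len(k)) {
    cen <- centroids[s, ]
    soma_s <- (soma == s) * 1L
    # bounding window: soma bbox + dilations + influence radius margin
    idx <- which(soma == s)
    rr <- (idx - 1L) %% nr; cc <- (idx - 1L) %/% nr
    pad <- ceiling(r_px) + params$soma_dilations + 2L
    w_r <- max(1L, min(rr) + 1L - pad):min(nr, max(rr) + 1L + pad)
    w_c <- max(1L, min(cc) + 1L - pad):min(nc, max(cc) + 1L + pad)
    marker_w <- dilate_n(soma_s[w_r, w_c, drop = FALSE],
                         params$soma_dilations)
    # disk of the influence zone (0-based coordinates, Euclidean, in px)
    dr <- (w_r - 1L) - cen[1L]
    dc <- (w_c - 1L) - cen[2L]
    disk_w <- outer(dr^2, dc^2, "+") <= r_px^2
    skel_w <- skel[w_r, w_c, drop = FALSE]
    cand <- (skel_w != 0L & disk_w) * 1L
    prox_thin_w <- mask_px(reconstruct_from_markers(cand, marker_w))
    if (!any(prox_thin_w != 0L)) {
      cells[[s]] <- list(soma_id = s, centroid = cen, soma = idx,
                         proximal = integer(0), distal = integer(0),
                         visible = idx)
      next
    }
    # full-image indices of proximal thinned pixels
    pt_idx <- which(prox_thin_w != 0L)
    pt_r <- w_r[(pt_idx - 1L) %% length(w_r) + 1L]
    pt_c <- w_c[(pt_idx - 1L) %/% length(w_r) + 1L]
    pt_full <- pt_r + (pt_c - 1L) * nr
    hit <- unique(lab_proc[pt_full])
    hit <- hit[hit > 0L]
    recon_idx <- unlist(comp_idx[hit], use.names = FALSE)
    # split reconstructed processes at the influence circle
    rr2 <- (recon_idx - 1L) %% nr
    cc2 <- (recon_idx - 1L) %/% nr
    in_disk <- (rr2 - cen[1L])^2 + (cc2 - cen[2L])^2 <= r_px^2
    prox_idx <- recon_idx[in_disk]
    dist_idx <- recon_idx[!in_disk]
    # contested-pixel resolution against previously claimed pixels
    d2 <- (((recon_idx - 1L) %% nr) - cen[1L])^2 +
          (((recon_idx - 1L) %/% nr) - cen[2L])^2
    better <- d2 < owner_d[recon_idx]   # strict: ties keep the lower label
    win <- recon_idx[better]
    owner_d[win] <- d2[better]
    owner[win] <- s
    cells[[s]] <- list(soma_id = s, centroid = cen, soma = idx,
                       proximal = prox_idx, distal = dist_idx,
                       visible = integer(0))
  }

  # rebuild per-cell sets from the resolved ownership
  for (s in seq_len(k)) {
    cl <- cells[[s]]
    claimed <- c(cl$proximal, cl$distal)
    mine <- claimed[owner[claimed] == s]
    cl$proximal <- intersect(cl$proximal, mine)
    cl$distal <- intersect(cl$distal, mine)
    cl$visible <- sort(unique(c(cl$soma, cl$proximal)))
    cells[[s]] <- cl
  }

  mk_mask <- function(field) {
    m <- matrix(0L, nr, nc)
    m[unlist(lapply(cells, `[[`, field), use.names = FALSE)] <- 1L
    binary_mask(m, cal)
  }
  structure(list(cells = cells,
                 proximal = mk_mask("proximal"),
                 distal = mk_mask("distal"),
                 visible = mk_mask("visible"),
                 shape = c(nr, nc), calibration = cal,
                 params = params),
            class = "arbor_decomposition")
}

#' @export
print.arbor_decomposition <- function(x, ...) {
  cat(sprintf(paste0("arbor_decomposition: %d cells, proximal %d px, ",
                     "distal %d px\n"), length(x$cells),
              sum(mask_px(x$proximal)), sum(mask_px(x$distal))))
  invisible(x)
}
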