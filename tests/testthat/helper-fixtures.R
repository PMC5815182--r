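# shared fixture builders; everything is generated in code at test time

# rasterized disk as a 0/1 matrix, center at the matrix midpoint
make_disk <- function(radius_px, pad = 5L) {
  n <- 2L * radius_px + 2L * pad + 1L
  cen <- (n + 1) / 2
  yy <- row(matrix(0, n, n)) - cen
  xx <- col(matrix(0, n, n)) - cen
  (yy^2 + xx^2 <= radius_px^2) * 1L
}

# brute-force point-in-polygon oracle (even-odd crossing count, written
# independently of rasterize_polygon): loops over every pixel center
brute_polygon_mask <- function(polygon, shape) {
  out <- matrix(FALSE, shape[1L], shape[2L])
  np <- nrow(polygon)
  for (r in 0:(shape[1L] - 1L)) {
    for (c in 0:(shape[2L] - 1L)) {
      crossings <- 0L
      j <- np
      for (i in seq_len(np)) {
        ri <- polygon[i, 1L]; rj <- polygon[j, 1L]
        ci <- polygon[i, 2L]; cj <- polygon[j, 2L]
        if ((ri > r) != (rj > r)) {
          xint <- (cj - ci) * (r - ri) / (rj - ri) + ci
          if (c < xint) crossings <- crossings + 1L
        }
        j <- i
      }
      out[r + 1L, c + 1L] <- crossings %% 2L == 1L
    }
  }
  out
}

# hand-built segmentation: one circular soma with one straight horizontal
# process, on an all-tissue field; calibration 1 um/px
single_cell_seg <- function(n = 100L, soma_center = c(50L, 30L),
                            soma_radius = 5L, process_len = 40L) {
  tissue <- matrix(1L, n, n)
  yy <- row(tissue) - soma_center[1L]
  xx <- col(tissue) - soma_center[2L]
  soma <- (yy^2 + xx^2 <= soma_radius^2) * 1L
  proc <- matrix(0L, n, n)
  c0 <- soma_center[2L] + soma_radius + 1L
  proc[soma_center[1L], c0:(c0 + process_len - 1L)] <- 1L
  structure(list(tissue = binary_mask(tissue, 1),
                 soma = label_map(soma, 1),
                 soma_gray_mean = 30, threshold = 48,
                 processes = binary_mask(proc, 1),
                 skeleton = binary_mask(proc, 1)),
            class = "glia_segmentation")
}

# small ramified field used by several tests (cached per session)
small_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_histology(n_cells = 10, field_size_um = 250,
                                   seed = 11)
    cache
  }
})

run_small_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- small_field()
      gray <- chromogen_gray(unmix_stains(rgb_to_od(g$section),
                                          calibration = 0.5), "dab")
      seg <- segment_glia(gray, tissue_gray = brightness_gray(g$section))
      decomp <- decompose_arbors(seg)
      cells <- morphometric_features(decomp, seg, gray)
      cache <<- list(truth = g$truth, section = g$section, gray = gray,
                     seg = seg, decomp = decomp, cells = cells)
    }
    cache
  }
})
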