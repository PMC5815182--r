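#' Stain absorption matrix
#'
#' Optical-density absorption vectors (one unit-length non-negative
#' 3-vector per stain, RGB order). Two-stain matrices are completed with
#' the normalized cross product of the two vectors so the per-pixel solve
#' is exact; the residual channel is discarded after unmixing.
#'
#' @param vectors list of numeric 3-vectors, or a 3 x k matrix (k = 2 or 3)
#'   with one stain per column.
#' @param names stain names (defaults to "stain1", "stain2", ...).
#' @return An object of class \code{stain_matrix}: 3 x 3 matrix with stain
#'   names on the first \code{n_stains} columns.
#' @export
stain_matrix <- function(vectors, names = NULL) {
  if (is.list(vectors)) vectors <- do.call(cbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L || !ncol(vectors) %in% 2:3)
    stop("need 2 or 3 absorption 3-vectors")
  if (any(vectors < 0)) stop("absorption vectors must be non-negative")
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length stain vector")
  vectors <- sweep(vectors, 2L, nrm, "/")
  k <- ncol(vectors)
  if (is.null(names)) names <- paste0("stain", seq_len(k))
  if (k == 2L) {
    v <- c(vectors[2, 1] * vectors[3, 2] - vectors[3, 1] * vectors[2, 2],
           vectors[3, 1] * vectors[1, 2] - vectors[1, 1] * vectors[3, 2],
           vectors[1, 1] * vectors[2, 2] - vectors[2, 1] * vectors[1, 2])
    if (sqrt(sum(v^2)) < 1e-12)
      stop("stain vectors are linearly dependent")
    vectors <- cbind(vectors, abs(v) / sqrt(sum(v^2)))
    names <- c(names, ".residual")
  }
  if (abs(det(vectors)) < 1e-12) stop("stain matrix is singular")
  structure(vectors, dimnames = list(c("R", "G", "B"), names),
            n_stains = k, class = "stain_matrix")
}

#' Default DAB + hematoxylin stain matrix
#'
#' Ruifrok-Johnston absorption vectors for hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), normalized to
#' unit length. Override per experiment when the chromogen batch differs.
#'
#' @return A \code{stain_matrix} with columns \code{dab}, \code{hematoxylin}.
#' @export
default_stain_matrix <- function() {
  stain_matrix(list(dab = c(0.269, 0.568, 0.778),
                    hematoxylin = c(0.650, 0.704, 0.286)),
               names = c("dab", "hematoxylin"))
}

#' RGB to optical density
#'
#' Beer-Lambert transform per channel: \code{od = -log10((I + 1)/256)}.
#' White (255) maps to 0 absorbance; black (0) to log10(256) ~ 2.408. The
#' +1 offset keeps the transform finite and exactly invertible for 8-bit
#' data.
#'
#' @param section a \code{stained_section} (or rows x cols x 3 array of
#'   0-255 intensities).
#' @return rows x cols x 3 numeric array of optical densities (>= 0).
#' @export
rgb_to_od <- function(section) {
  px <- if (inherits(section, "stained_section")) section$pixels
        else as_rgb_array(section)
  -log10((px + 1) / 256)
}

#' Unmix stains from an optical-density image
#'
#' Per-pixel solve of \code{od = M c} for the stain concentrations c
#' (exact least squares, since M is completed to an invertible 3 x 3
#' basis). Negative concentrations — pixels slightly outside the stain
#' simplex — are clipped to 0.
#'
#' @param od rows x cols x 3 optical-density array from \code{rgb_to_od}.
#' @param matrix a \code{stain_matrix} (default DAB + hematoxylin).
#' @param calibration micrometres per pixel for the output channels.
#' @return A list of class \code{stain_channels}: one \code{gray_image}
#'   concentration map per stain (residual channel dropped), plus
#'   \code{stain_names}.
#' @export
unmix_stains <- function(od, matrix = default_stain_matrix(),
                         calibration = 1) {
  if (!inherits(matrix, "stain_matrix")) matrix <- stain_matrix(matrix)
  d <- dim(od)
  Minv <- solve(unclass(matrix))
  flat <- base::matrix(od, d[1L] * d[2L], 3L)
  conc <- flat %*% t(Minv)
  conc[conc < 0] <- 0
  k <- attr(matrix, "n_stains")
  nms <- colnames(matrix)[seq_len(k)]
  maps <- lapply(seq_len(k), function(i)
    gray_image(base::matrix(conc[, i], d[1L], d[2L]), calibration))
  names(maps) <- nms
  structure(list(concentrations = maps, stain_names = nms),
            class = "stain_channels")
}

#' Gray rendering of the chromogen channel
#'
#' Renders a deconvolved concentration map back to an 8-bit-range gray
#' image in which stained structures are dark:
#' \code{g = 255 * 10^(-c)}, clipped to [0, 255]. Strictly decreasing in
#' concentration, so darker means more chromogen. Soma/process
#' segmentation operates on this image.
#'
#' @param channels a \code{stain_channels} (or a single concentration
#'   \code{gray_image}).
#' @param chromogen name of the chromogen channel (default first stain).
#' @return A \code{gray_image} with values in [0, 255].
#' @export
chromogen_gray <- function(channels, chromogen = NULL) {
  conc <- if (inherits(channels, "gray_image")) channels
  else {
    if (is.null(chromogen)) chromogen <- channels$stain_names[1L]
    if (!chromogen %in% names(channels$concentrations))
      stop("no such stain channel: ", chromogen)
    channels$concentrations[[chromogen]]
  }
  g <- 255 * 10^(-conc$pixels)
  g[g > 255] <- 255
  g[g < 0] <- 0
  gray_image(g, conc$calibration)
}
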