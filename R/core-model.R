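#' @useDynLib gliamorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Calibrated RGB histology section
#'
#' Container for a brightfield RGB image with mandatory pixel-size
#' calibration. All downstream areas and lengths are reported in
#' micrometres, so the calibration (micrometres per pixel edge) is
#' required metadata with no default.
#'
#' @param pixels integer array of dimension rows x cols x 3, values 0-255.
#' @param calibration pixel edge length in micrometres per pixel (> 0).
#' @param label free-text section identifier.
#' @param stain_pair character vector of length 2 naming the chromogen and
#'   the counterstain, e.g. \code{c("dab", "hematoxylin")}.
#' @return An object of class \code{stained_section}.
#' @export
stained_section <- function(pixels, calibration, label = "",
                            stain_pair = c("dab", "hematoxylin")) {
  pixels <- as_rgb_array(pixels)
  stopifnot(is.numeric(calibration), length(calibration) == 1L,
            is.finite(calibration), calibration > 0)
  if (any(pixels < 0 | pixels > 255))
    stop("RGB intensities must lie in [0, 255]")
  if (length(stain_pair) != 2L)
    stop("stain_pair must name exactly two stains")
  structure(list(pixels = pixels, calibration = calibration,
                 label = as.character(label)[1L],
                 stain_pair = as.character(stain_pair)),
            class = "stained_section")
}

as_rgb_array <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("pixels must be a rows x cols x 3 array")
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("image grid must be non-empty")
  storage.mode(pixels) <- "integer"
  pixels
}

#' Single-channel calibrated image
#'
#' @param pixels numeric matrix (rows x cols), row 1 at the top.
#' @param calibration micrometres per pixel (> 0).
#' @return An object of class \code{gray_image}.
#' @export
gray_image <- function(pixels, calibration) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("gray_image pixels must be finite")
  stopifnot(is.numeric(calibration), calibration > 0)
  structure(list(pixels = pixels, calibration = calibration),
            class = "gray_image")
}

#' Binary mask
#'
#' @param pixels matrix of 0/1 (or logical).
#' @param calibration micrometres per pixel (> 0).
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(pixels, calibration) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels <- pixels * 1L
  storage.mode(pixels) <- "integer"
  if (any(pixels != 0L & pixels != 1L))
    stop("binary mask values must be strictly in {0, 1}")
  stopifnot(is.numeric(calibration), calibration > 0)
  structure(list(pixels = pixels, calibration = calibration),
            class = "binary_mask")
}

#' Label map of individualized objects
#'
#' Background is 0; objects carry consecutive labels 1..object_count and
#' are connected under 8-connectivity.
#'
#' @param pixels integer matrix of non-negative labels.
#' @param calibration micrometres per pixel (> 0).
#' @return An object of class \code{label_map}.
#' @export
label_map <- function(pixels, calibration) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("labels must be non-negative")
  k <- if (any(pixels > 0L)) max(pixels) else 0L
  present <- sort(unique(pixels[pixels > 0L]))
  if (length(present) && !identical(present, seq_len(k)))
    stop("labels must be consecutive 1..object_count")
  structure(list(pixels = pixels, calibration = calibration,
                 object_count = as.integer(k)),
            class = "label_map")
}

mask_px <- function(x) {
  if (inherits(x, "binary_mask") || inherits(x, "gray_image") ||
      inherits(x, "label_map")) x$pixels else x
}

#' Named regions of interest
#'
#' Regions are polygons in 0-based (row, col) pixel coordinates or
#' precomputed masks; names must be unique.
#'
#' @param regions a list; each element a list with \code{name} and either
#'   \code{polygon} (n x 2 matrix of (row, col)) or \code{mask} (matrix).
#' @return An object of class \code{roi_set}.
#' @export
roi_set <- function(regions) {
  nm <- vapply(regions, function(r) as.character(r$name)[1L], character(1))
  if (anyDuplicated(nm)) stop("duplicate ROI name: ", nm[duplicated(nm)][1L])
  for (r in regions) {
    if (is.null(r$polygon) && is.null(r$mask))
      stop("each ROI needs a polygon or a mask")
    if (!is.null(r$polygon)) {
      p <- as.matrix(r$polygon)
      if (ncol(p) != 2L || nrow(p) < 3L)
        stop("polygon must be an n x 2 matrix with n >= 3")
    }
  }
  structure(list(regions = regions), class = "roi_set")
}

#' Read a ROI set from JSON
#'
#' The JSON dialect is
#' \code{{"regions": [{"name": "cc", "polygon": [[r, c], ...]}]}} with
#' 0-based (row, col) vertices. Every region must intersect the image.
#'
#' @param path JSON file path.
#' @param image_shape integer c(rows, cols) of the target image.
#' @return A \code{roi_set}.
#' @export
read_roiset <- function(path, image_shape) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$regions)) stop("ROI JSON must contain a 'regions' list")
  regions <- lapply(js$regions, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, function(v) as.numeric(v)))
    list(name = r$name, polygon = poly)
  })
  rs <- roi_set(regions)
  for (r in rs$regions) {
    m <- rasterize_polygon(r$polygon, image_shape)
    if (!any(m)) stop("ROI '", r$name, "' lies fully outside the image")
  }
  rs
}

#' Write a ROI set to JSON
#' @param rois a \code{roi_set} whose regions are polygons.
#' @param path output file path.
#' @export
write_roiset <- function(rois, path) {
  regions <- lapply(rois$regions, function(r) {
    list(name = r$name,
         polygon = lapply(seq_len(nrow(r$polygon)),
                          function(i) as.numeric(r$polygon[i, ])))
  })
  jsonlite::write_json(list(regions = regions), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon to a logical mask
#'
#' Pixel-center containment with the half-open even-odd rule: a pixel
#' (r, c) is inside if its center (the integer point) is inside the
#' polygon, with points on the lower/left boundary in and on the
#' upper/right boundary out. An axis-aligned square (0,0)-(k,k) therefore
#' covers exactly k^2 pixels.
#'
#' @param polygon n x 2 matrix of (row, col) vertices, 0-based.
#' @param shape integer c(rows, cols).
#' @return logical matrix of dimension \code{shape}.
#' @export
rasterize_polygon <- function(polygon, shape) {
  polygon <- as.matrix(polygon)
  out <- matrix(FALSE, shape[1L], shape[2L])
  r0 <- max(0L, floor(min(polygon[, 1L])))
  r1 <- min(shape[1L] - 1L, ceiling(max(polygon[, 1L])))
  c0 <- max(0L, floor(min(polygon[, 2L])))
  c1 <- min(shape[2L] - 1L, ceiling(max(polygon[, 2L])))
  if (r1 < r0 || c1 < c0) return(out)
  rows <- r0:r1; cols <- c0:c1
  pr <- polygon[, 1L]; pc <- polygon[, 2L]
  n <- length(pr)
  jj <- c(n, seq_len(n - 1L))
  grid_r <- matrix(rows, length(rows), length(cols))
  grid_c <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(FALSE, length(rows), length(cols))
  for (i in seq_len(n)) {
    j <- jj[i]
    ri <- pr[i]; rj <- pr[j]; ci <- pc[i]; cj <- pc[j]
    if (ri == rj) next
    crosses <- (ri > grid_r) != (rj > grid_r)
    xint <- (cj - ci) * (grid_r - ri) / (rj - ri) + ci
    inside <- xor(inside, crosses & (grid_c < xint))
  }
  out[rows + 1L, cols + 1L] <- inside
  out
}

#' Rasterize all ROIs of a set
#' @param rois a \code{roi_set}.
#' @param shape integer c(rows, cols).
#' @return named list of logical matrices.
#' @export
roi_masks <- function(rois, shape) {
  out <- lapply(rois$regions, function(r) {
    if (!is.null(r$mask)) {
      m <- as.matrix(r$mask) != 0
      if (!identical(dim(m), as.integer(shape)))
        stop("ROI mask shape does not match image shape")
      m
    } else rasterize_polygon(r$polygon, shape)
  })
  names(out) <- vapply(rois$regions, function(r) r$name, character(1))
  out
}

#' Read a stained section from a PNG/TIFF file
#'
#' Reads an 8-bit RGB raster losslessly (intensities 0-255 pass through
#' unchanged) and attaches the mandatory calibration.
#'
#' @param path image file (PNG or TIFF, 8-bit RGB).
#' @param calibration micrometres per pixel.
#' @param stain_pair chromogen/counterstain identifiers.
#' @return A \code{stained_section}.
#' @export
read_section <- function(path, calibration,
                         stain_pair = c("dab", "hematoxylin")) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode raster '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) < 3L || d[3L] < 3L)
    stop("not an RGB raster: ", path)
  px <- array(0L, c(d[2L], d[1L], 3L))
  for (ch in 1:3) px[, , ch] <- t(round(img[, , ch] * 255))
  stained_section(px, calibration, label = basename(path),
                  stain_pair = stain_pair)
}

#' Write a stained section as PNG
#' @param section a \code{stained_section}.
#' @param path output path (.png).
#' @export
write_section <- function(section, path) {
  d <- dim(section$pixels)
  img <- array(0, c(d[2L], d[1L], 3L))
  for (ch in 1:3) img[, , ch] <- t(section$pixels[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(img, colormode = "Color"), path)
  invisible(path)
}

#' Read a grayscale MR image (16-bit TIFF/PNG)
#' @param path image file.
#' @param calibration millimetres or micrometres per pixel (any unit; MTR
#'   is dimensionless so only relative geometry matters).
#' @param scale maximum digital number of the encoding (65535 for 16-bit).
#' @return A \code{gray_image} in digital numbers.
#' @export
read_gray <- function(path, calibration = 1, scale = 65535) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2L) img <- img[, , 1L]
  gray_image(t(img * scale), calibration)
}

#' Write a single-channel image as PNG/TIFF
#' @param gray a \code{gray_image} or \code{binary_mask}.
#' @param path output path.
#' @param scale maximum value of the encoding (255 for 8-bit output; use 1
#'   for masks).
#' @export
write_gray <- function(gray, path, scale = 255) {
  px <- mask_px(gray)
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(px / scale, 0), 1))), path)
  invisible(path)
}

#' @export
print.stained_section <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("stained_section '%s': %d x %d px, %.4g um/px, stains %s + %s\n",
              x$label, d[1L], d[2L], x$calibration,
              x$stain_pair[1L], x$stain_pair[2L]))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d objects\n",
              nrow(x$pixels), ncol(x$pixels), x$object_count))
  invisible(x)
}

#' 8-connected component labeling
#'
#' Labels the foreground of a binary mask with consecutive integers under
#' 8-connectivity (the convention used throughout the pipeline).
#'
#' @param mask a \code{binary_mask} or a 0/1 matrix.
#' @param calibration micrometres per pixel (taken from the mask if absent).
#' @return A \code{label_map}.
#' @export
label_components <- function(mask, calibration = NULL) {
  if (inherits(mask, "binary_mask") && is.null(calibration))
    calibration <- mask$calibration
  if (is.null(calibration)) calibration <- 1
  px <- mask_px(mask)
  storage.mode(px) <- "integer"
  lab <- label8_cpp(px)
  label_map(lab, calibration)
}
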