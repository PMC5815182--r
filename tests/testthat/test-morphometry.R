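test_that("optical density follows log10(background/object)", {
  g <- matrix(250, 20, 20)
  g[5:8, 5:8] <- 25
  obj <- matrix(0L, 20, 20); obj[5:8, 5:8] <- 1L
  tis <- binary_mask(matrix(1L, 20, 20), 1)
  expect_equal(optical_density(gray_image(g, 1), binary_mask(obj, 1), tis), 1)
  # object mean equal to background mean gives OD 0
  gu <- gray_image(matrix(100, 20, 20), 1)
  expect_equal(optical_density(gu, binary_mask(obj, 1), tis), 0)
  # random masks match direct arithmetic on pixel lists
  set.seed(4)
  gr <- matrix(runif(400, 20, 250), 20, 20)
  o <- (matrix(runif(400), 20, 20) < 0.2) * 1L
  if (sum(o) == 0) o[1, 1] <- 1L
  excl <- o
  od <- optical_density(gray_image(gr, 1), binary_mask(o, 1), tis,
                        binary_mask(excl, 1))
  expect_equal(od, log10(mean(gr[o == 0]) / mean(gr[o == 1])))
  # empty background is a validation error
  expect_error(optical_density(gu, tis, tis, tis), "background")
})

test_that("skeleton lengths follow the orthogonal/diagonal step rule", {
  # horizontal 100 px at 0.5 um/px -> 99 steps -> 49.5 um
  h <- matrix(0L, 20, 120); h[10, 11:110] <- 1L
  expect_equal(skeleton_length_um(binary_mask(h, 0.5)), 49.5)
  # 45-degree diagonal of 100 px -> 99 sqrt(2) steps
  d <- matrix(0L, 120, 120)
  d[cbind(11:110, 11:110)] <- 1L
  expect_equal(skeleton_length_um(binary_mask(d, 0.5)), 99 * sqrt(2) * 0.5)
  # an L-corner does not double-count the diagonal shortcut
  l <- matrix(0L, 5, 5); l[2, 2] <- 1L; l[2, 3] <- 1L; l[3, 3] <- 1L
  expect_equal(skeleton_length_um(binary_mask(l, 1)), 2)
})

test_that("form factor of rasterized disks approaches 1 with radius", {
  ffs <- sapply(c(20, 40, 80), function(r) {
    dk <- make_disk(r)
    n <- nrow(dk)
    seg <- structure(list(tissue = binary_mask(matrix(1L, n, n), 1),
                          soma = label_map(dk, 1), soma_gray_mean = 30,
                          threshold = 48,
                          processes = binary_mask(matrix(0L, n, n), 1),
                          skeleton = binary_mask(matrix(0L, n, n), 1)),
                     class = "glia_segmentation")
    dec <- decompose_arbors(seg)
    morphometric_features(dec, seg)$soma_form_factor
  })
  expect_true(all(ffs >= 0.92 & ffs <= 1.05))
  expect_true(ffs[3] >= 0.95)
})

test_that("per-cell features have consistent areas, lengths and ODs", {
  rf <- run_small_field()
  cells <- rf$cells
  expect_equal(nrow(cells), length(rf$decomp$cells))
  expect_true(all(cells$soma_area_um2 > 0))
  expect_true(all(cells$soma_form_factor > 0 & cells$soma_form_factor <= 1.1))
  expect_true(all(cells$proximal_length_um >= 0))
  expect_true(all(cells$distal_length_um >= 0))
  # areas agree with the pixel sets (0.25 um2 per pixel at 0.5 um/px)
  expect_equal(cells$proximal_area_um2,
               sapply(rf$decomp$cells, function(cl) length(cl$proximal)) * 0.25)
  # stained cells are darker than background: positive OD
  expect_true(all(cells$soma_od > 0))
  expect_true(all(cells$visible_od > 0))
  expect_true(all(cells$soma_od >= cells$visible_od))
})

test_that("activation and size indices follow their defining ratios", {
  cells <- data.frame(soma_area_um2 = c(60, 40),
                      proximal_area_um2 = c(30, 20),
                      distal_area_um2 = c(50, 25))
  expect_equal(activation_index(cells), (100 + 50) / 75)
  expect_equal(size_index(cells), 75)
  # undefined cases flagged as NA, not infinity
  cells0 <- cells; cells0$distal_area_um2 <- 0
  expect_true(is.na(activation_index(cells0)))
  expect_true(is.na(activation_index(cells[0, ])))
  expect_true(is.na(size_index(cells[0, ])))
})

test_that("indices are invariant to 90-degree rotation of the field", {
  rf <- run_small_field()
  sec <- rf$section
  rot <- sec
  rot$pixels <- array(0L, dim(sec$pixels)[c(2, 1, 3)])
  for (ch in 1:3)
    rot$pixels[, , ch] <- t(sec$pixels[, , ch])[, nrow(sec$pixels):1]
  gray <- chromogen_gray(unmix_stains(rgb_to_od(rot), calibration = 0.5), "dab")
  seg <- segment_glia(gray, tissue_gray = brightness_gray(rot))
  cells <- morphometric_features(decompose_arbors(seg), seg, gray)
  a0 <- activation_index(rf$cells); a1 <- activation_index(cells)
  s0 <- size_index(rf$cells); s1 <- size_index(cells)
  expect_equal(seg$soma$object_count, rf$seg$soma$object_count)
  expect_lt(abs(a1 - a0) / a0, 0.02)
  expect_lt(abs(s1 - s0) / s0, 0.02)
})

test_that("stained area fraction and IntDen match brute-force pixel loops", {
  g <- matrix(200, 30, 30)
  g[1:15, ] <- 50
  tis <- binary_mask(matrix(1L, 30, 30), 0.5)
  roi <- matrix(1L, 30, 30)
  out <- stained_area_fraction(gray_image(g, 0.5), tis, roi, threshold = 100)
  expect_equal(out$fraction, 0.5)
  expect_equal(out$integrated_density, sum(255 - g[1:15, ]) * 0.25)
  # unstained ROI -> 0/0
  out0 <- stained_area_fraction(gray_image(matrix(200, 10, 10), 0.5),
                                binary_mask(matrix(1L, 10, 10), 0.5),
                                matrix(1L, 10, 10), threshold = 100)
  expect_equal(out0$fraction, 0)
  expect_equal(out0$integrated_density, 0)
  # random image, random ROI: brute-force oracle
  set.seed(12)
  gr <- matrix(runif(900, 0, 255), 30, 30)
  roi2 <- (matrix(runif(900), 30, 30) < 0.5) * 1L
  t2 <- (matrix(runif(900), 30, 30) < 0.9) * 1L
  res <- stained_area_fraction(gray_image(gr, 1), binary_mask(t2, 1), roi2, 120)
  sel <- t2 == 1L & roi2 == 1L
  expect_equal(res$fraction, sum(gr[sel] <= 120) / sum(sel))
  expect_equal(res$integrated_density, sum((255 - gr[sel & gr <= 120])))
  expect_error(stained_area_fraction(gray_image(gr, 1),
                                     binary_mask(matrix(0L, 30, 30), 1),
                                     roi2, 120), "intersect")
})

test_that("control normalization maps the control mean to exactly 1", {
  v <- c(2, 4, 6, 10)
  grp <- c("ctrl", "ctrl", "cpz", "cpz")
  out <- normalize_to_control(v, grp, "ctrl")
  expect_equal(out, c(2/3, 4/3, 2, 10/3))
  expect_equal(mean(out[grp == "ctrl"]), 1)
  # order invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(normalize_to_control(v[perm], grp[perm], "ctrl"), out[perm])
  expect_error(normalize_to_control(v, grp, "nope"), "empty")
  expect_error(normalize_to_control(c(0, 0, 1), c("c", "c", "t"), "c"), "zero")
})

test_that("ddCt fold changes follow 2^-ddCt against the calibrator", {
  tab <- data.frame(sample = paste0("s", 1:4),
                    group = c("ctrl", "ctrl", "trt", "trt"),
                    target_ct = c(25, 25, 26, 23),
                    reference_ct = c(20, 20, 20, 20))
  out <- ddct_fold_change(tab, "ctrl")
  expect_equal(out$fold_change[1:2], c(1, 1))   # ddCt 0 -> fold 1
  expect_equal(out$fold_change[3], 0.5)          # ddCt 1 -> fold 0.5
  expect_equal(out$fold_change[4], 4)            # ddCt -2 -> fold 4
  expect_error(ddct_fold_change(tab, "none"), "calibrator")
  tab$target_ct[1] <- NA
  expect_error(ddct_fold_change(tab, "ctrl"), "finite")
})

test_that("ROI aggregation assigns cells by soma centroid", {
  rf <- run_small_field()
  n <- nrow(rf$seg$tissue$pixels)
  left <- matrix(0L, n, n); left[, 1:(n %/% 2)] <- 1L
  right <- 1L - left
  tab <- roi_features(rf$cells, rf$seg, rf$gray,
                      list(left = left, right = right))
  expect_equal(sum(tab$soma_count), nrow(rf$cells))
  expect_equal(tab$roi_name, c("left", "right"))
  expect_true(all(tab$stained_area_fraction >= 0 &
                  tab$stained_area_fraction <= 1))
  expect_true(all(tab$soma_count_per_mm2 >= 0))
})
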