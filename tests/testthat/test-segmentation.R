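test_that("tissue segmentation: threshold, hole filling, size filter", {
  # uniform white image -> empty mask
  white <- gray_image(matrix(255, 120, 120), 0.5)
  expect_equal(sum(segment_tissue(white)$pixels), 0)
  # a gray block on white is recovered exactly at threshold 240
  g <- matrix(255, 200, 200)
  g[51:150, 51:150] <- 180
  p <- segmentation_params(tissue_threshold = 240, closing_radius_um = 1,
                           opening_radius_um = 1, min_tissue_object_um2 = 10)
  m <- segment_tissue(gray_image(g, 1), p)
  expect_equal(sum(m$pixels), 100 * 100)
  # an interior white hole is filled: area equals the full block
  g[100:102, 100:102] <- 255
  m2 <- segment_tissue(gray_image(g, 1), p)
  expect_equal(sum(m2$pixels), 100 * 100)
  # objects below the size filter disappear
  g3 <- matrix(255, 200, 200)
  g3[10:12, 10:12] <- 100
  p_big <- segmentation_params(tissue_threshold = 240, closing_radius_um = 1,
                               opening_radius_um = 1,
                               min_tissue_object_um2 = 500)
  expect_equal(sum(segment_tissue(gray_image(g3, 1), p_big)$pixels), 0)
})

test_that("adaptive threshold equals factor x mean of darkest fraction", {
  # forced arithmetic: 10 px at 40, 90 px at 200, fraction 0.1, factor 1.5
  g <- matrix(200, 10, 10)
  g[1, 1:10] <- 40
  p <- segmentation_params(dark_seed_fraction = 0.10,
                           soma_threshold_factor = 1.5)
  out <- adaptive_soma_threshold(gray_image(g, 1),
                                 binary_mask(matrix(1L, 10, 10), 1), p)
  expect_equal(out$seed_mean, 40)
  expect_equal(out$threshold, 60)
  # uniform tissue: seed mean equals the constant regardless of fraction
  gu <- gray_image(matrix(123, 20, 20), 1)
  tis <- binary_mask(matrix(1L, 20, 20), 1)
  for (f in c(0.01, 0.2, 0.9))
    expect_equal(adaptive_soma_threshold(gu, tis,
                   segmentation_params(dark_seed_fraction = f))$seed_mean, 123)
  # random image: matches the full-sort oracle
  set.seed(5)
  gr <- matrix(runif(400, 0, 255), 20, 20)
  p2 <- segmentation_params(dark_seed_fraction = 0.05,
                            soma_threshold_factor = 1.3)
  out2 <- adaptive_soma_threshold(gray_image(gr, 1), tis, p2)
  k <- round(0.05 * 400)
  expect_equal(out2$threshold, 1.3 * mean(sort(as.vector(gr))[1:k]))
  # empty tissue is a validation error
  expect_error(adaptive_soma_threshold(gu, binary_mask(matrix(0L, 20, 20), 1)),
               "empty")
})

test_that("soma segmentation counts, filters by area and renumbers labels", {
  g <- matrix(200, 60, 60)
  g[10:15, 10:14] <- 30   # 30 px blob
  g[40:45, 40:44] <- 30   # 30 px blob
  g[30, 30] <- 30         # 1 px speck, below min area
  tis <- binary_mask(matrix(1L, 60, 60), 0.5)
  p <- segmentation_params(min_soma_area_um2 = 5, max_soma_area_um2 = 1000)
  lab <- segment_soma(gray_image(g, 0.5), tis, threshold = 60, p)
  expect_equal(lab$object_count, 2)
  expect_setequal(unique(as.vector(lab$pixels)), c(0L, 1L, 2L))
  # nothing at or below threshold -> empty map
  expect_equal(segment_soma(gray_image(matrix(200, 10, 10), 0.5),
                            binary_mask(matrix(1L, 10, 10), 0.5), 60,
                            p)$object_count, 0)
  # oversized objects are removed too (66x66 px = 1089 um2 > 1000)
  g2 <- matrix(200, 80, 80); g2[10:75, 10:75] <- 30
  expect_equal(segment_soma(gray_image(g2, 0.5),
                            binary_mask(matrix(1L, 80, 80), 0.5), 60,
                            p)$object_count, 0)
})

test_that("top-hat process segmentation picks thin lines, not wide disks", {
  n <- 100
  g <- matrix(255, n, n)
  g[50, 21:70] <- 40              # 1-px line, length 50
  tis <- binary_mask(matrix(1L, n, n), 1)
  empty_soma <- label_map(matrix(0L, n, n), 1)
  p <- segmentation_params(tophat_radius_um = 2, min_process_object_px = 5)
  m <- segment_processes(gray_image(g, 1), tis, empty_soma, seed_mean = 40, p)
  on_line <- sum(m$pixels[50, 21:70])
  expect_gte(on_line, 45)
  # no captured pixel farther than 2 px from the line
  hit <- which(m$pixels != 0, arr.ind = TRUE)
  expect_true(all(abs(hit[, 1] - 50) <= 2 &
                  hit[, 2] >= 19 & hit[, 2] <= 72))
  # a soma-scale disk (radius 10) is suppressed in the interior, and the
  # labeled soma removes any rim response
  dk <- make_disk(10, pad = 20)
  g2 <- matrix(255, nrow(dk), ncol(dk)); g2[dk == 1] <- 40
  tis2 <- binary_mask(matrix(1L, nrow(dk), ncol(dk)), 1)
  soma2 <- label_map(dk, 1)
  m2 <- segment_processes(gray_image(g2, 1), tis2, soma2, seed_mean = 40, p)
  expect_equal(sum(m2$pixels[dk == 1]), 0)       # soma subtracted
  interior <- EBImage::erode(dk, EBImage::makeBrush(7, "disc"))
  expect_equal(sum(m2$pixels[interior == 1]), 0) # wide object not captured
  # blank image -> empty mask
  expect_equal(sum(segment_processes(gray_image(matrix(255, 50, 50), 1),
                                     binary_mask(matrix(1L, 50, 50), 1),
                                     label_map(matrix(0L, 50, 50), 1),
                                     40, p)$pixels), 0)
})

test_that("thinning yields one-pixel skeletons preserving connectivity", {
  # empty in, empty out
  e <- binary_mask(matrix(0L, 20, 20), 1)
  expect_equal(sum(skeletonize_processes(e)$pixels), 0)
  # 3-px-wide bar thins to a single 8-connected path of one component
  bar <- matrix(0L, 40, 80)
  bar[19:21, 10:69] <- 1L
  sk <- skeletonize_processes(binary_mask(bar, 1))
  expect_true(all(sk$pixels <= bar))
  expect_equal(label_components(sk)$object_count, 1)
  # length close to the bar length
  expect_gt(skeleton_length_um(sk), 50)
  # thinness: no 2x2 all-foreground block
  s <- sk$pixels
  blocks <- s[-nrow(s), -ncol(s)] + s[-1, -ncol(s)] +
            s[-nrow(s), -1] + s[-1, -1]
  expect_true(all(blocks < 4))
})

test_that("skeleton component count matches process component count", {
  set.seed(9)
  for (i in 1:3) {
    bin <- matrix(0L, 60, 60)
    # several random thick strokes
    for (j in 1:4) {
      r <- sample(5:55, 1); c0 <- sample(5:25, 1); len <- sample(10:30, 1)
      bin[r + (-1:1), c0:min(60, c0 + len)] <- 1L
    }
    m <- binary_mask(bin, 1)
    sk <- skeletonize_processes(m)
    expect_equal(label_components(sk)$object_count,
                 label_components(m)$object_count)
    expect_true(all(sk$pixels <= bin))
  }
})

test_that("full segmentation keeps soma and processes disjoint", {
  rf <- run_small_field()
  seg <- rf$seg
  expect_equal(sum(seg$processes$pixels[seg$soma$pixels > 0]), 0)
  expect_true(all(seg$skeleton$pixels <= seg$processes$pixels))
  expect_true(all((seg$soma$pixels > 0) <= seg$tissue$pixels))
  # detected count within 10% of the generated count
  expect_true(abs(seg$soma$object_count - rf$truth$cell_count) <=
                ceiling(0.1 * rf$truth$cell_count))
})
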