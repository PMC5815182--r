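test_that("reconstruction returns exactly the marked components", {
  m <- matrix(0L, 30, 30)
  m[5, 3:25] <- 1L       # line 1
  m[20, 3:25] <- 1L      # line 2
  mk <- matrix(0L, 30, 30); mk[5, 10] <- 1L
  rec <- reconstruct_from_markers(binary_mask(m, 1), binary_mask(mk, 1))
  expect_equal(sum(rec$pixels[5, ]), 23)
  expect_equal(sum(rec$pixels[20, ]), 0)
  # empty markers -> empty result
  expect_equal(sum(reconstruct_from_markers(binary_mask(m, 1),
                                            binary_mask(matrix(0L, 30, 30), 1))$pixels), 0)
  # random blobs: equals the union of components hit by markers (oracle
  # via independent component labeling)
  set.seed(3)
  for (i in 1:5) {
    bin <- (matrix(runif(900), 30, 30) < 0.25) * 1L
    mrk <- (matrix(runif(900), 30, 30) < 0.05) * 1L
    rec2 <- reconstruct_from_markers(binary_mask(bin, 1), binary_mask(mrk, 1))
    lab <- label_components(binary_mask(bin, 1))$pixels
    hit <- setdiff(unique(lab[mrk == 1L & bin == 1L]), 0L)
    oracle <- (matrix(lab %in% hit, 30, 30)) * 1L
    expect_identical(rec2$pixels, oracle)
  }
})

test_that("single soma with a straight process splits at the influence circle", {
  seg <- single_cell_seg()   # soma center (50,30) r=5, process cols 36..75
  p <- arbor_params(soma_dilations = 2, influence_radius_um = 10)
  dec <- decompose_arbors(seg, p)
  cl <- dec$cells[[1]]
  expect_gt(length(cl$proximal), 0)
  expect_gt(length(cl$distal), 0)
  expect_length(intersect(cl$proximal, cl$distal), 0)
  # proximal pixels are the process pixels inside the circle (cols <= 40)
  pc <- ((cl$proximal - 1L) %/% 100L) + 1L   # 1-based column
  dc <- ((cl$distal - 1L) %/% 100L) + 1L
  expect_true(all(pc <= 41))
  expect_true(all(dc >= 41))
  expect_equal(length(cl$proximal) + length(cl$distal), 40)
  # visible = soma + proximal
  expect_setequal(cl$visible, union(cl$soma, cl$proximal))
})

test_that("orphan processes belong to neither compartment", {
  seg <- single_cell_seg()
  seg$processes$pixels[10, 10:30] <- 1L   # line far from the soma
  seg$skeleton$pixels[10, 10:30] <- 1L
  dec <- decompose_arbors(seg, arbor_params(influence_radius_um = 10))
  expect_equal(sum(dec$proximal$pixels[10, 10:30]), 0)
  expect_equal(sum(dec$distal$pixels[10, 10:30]), 0)
})

test_that("soma without processes: visible equals soma, distal empty", {
  seg <- single_cell_seg()
  seg$processes <- binary_mask(matrix(0L, 100, 100), 1)
  seg$skeleton <- binary_mask(matrix(0L, 100, 100), 1)
  dec <- decompose_arbors(seg)
  cl <- dec$cells[[1]]
  expect_setequal(cl$visible, cl$soma)
  expect_length(cl$distal, 0)
  expect_length(cl$proximal, 0)
})

test_that("decomposition invariants hold on random segmentations", {
  set.seed(17)
  for (i in 1:5) {
    n <- 80
    soma <- matrix(0L, n, n)
    for (s in 1:3) {
      cen <- sample(15:65, 2)
      yy <- row(soma) - cen[1]; xx <- col(soma) - cen[2]
      soma[yy^2 + xx^2 <= 16 & soma == 0L] <- s
    }
    # renumber in case a disk got fully overwritten
    lab <- label_components(binary_mask((soma > 0) * 1L, 1))
    proc <- (matrix(runif(n * n), n, n) < 0.15) * 1L
    proc[lab$pixels > 0] <- 0L
    sk <- skeletonize_processes(binary_mask(proc, 1))
    seg <- structure(list(tissue = binary_mask(matrix(1L, n, n), 1),
                          soma = lab, soma_gray_mean = 30, threshold = 48,
                          processes = binary_mask(proc, 1), skeleton = sk),
                     class = "glia_segmentation")
    dec <- decompose_arbors(seg, arbor_params(influence_radius_um = 12))
    expect_equal(sum(dec$proximal$pixels * dec$distal$pixels), 0)
    expect_true(all(dec$proximal$pixels <= proc))
    expect_true(all(dec$distal$pixels <= proc))
    expect_true(all(dec$visible$pixels[lab$pixels > 0] == 1L))
    # partition: no process pixel claimed by two cells
    claimed <- unlist(lapply(dec$cells, function(cl) c(cl$proximal, cl$distal)))
    expect_false(any(duplicated(claimed)))
  }
})

test_that("shrinking the influence radius shifts area from proximal to distal", {
  rf <- run_small_field()
  radii <- c(6, 12, 18)
  prox <- dist <- numeric(3)
  for (i in seq_along(radii)) {
    d <- decompose_arbors(rf$seg, arbor_params(influence_radius_um = radii[i]))
    prox[i] <- sum(d$proximal$pixels)
    dist[i] <- sum(d$distal$pixels)
  }
  expect_true(all(diff(prox) >= 0))   # larger radius -> more proximal
  expect_true(all(diff(dist) <= 0))   # and weakly less distal
  expect_gt(prox[3], prox[1])
})
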