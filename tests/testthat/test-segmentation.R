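# Instance segmentation: preprocessing, nuclei, membranes, fusion,
# quantification.

test_that("preprocessing normalizes to [0, 1] and subtracts the low quantile", {
  ramp <- matrix(rep(0:255, 4), 32, 32)
  pp <- preprocess_channel(ramp)
  expect_equal(min(pp$norm), 0)
  expect_equal(max(pp$norm), 1)
  x <- matrix(c(rep(0, 110), runif(9890, 10, 200)), 100, 100)
  expect_equal(preprocess_channel(x)$offset,
               quantile(x, 1e-4, names = FALSE))
  expect_error(preprocess_channel(matrix(5, 10, 10)), "dynamic range")
})

test_that("preprocessing an already-normalized raster only shifts by the low quantile", {
  set.seed(1)
  x <- matrix(runif(1e4), 100, 100)
  x[1] <- 0; x[2] <- 1
  pp <- preprocess_channel(x)
  off <- quantile(x, 1e-4, names = FALSE)
  expect_equal(pp$norm, pmax(x - off, 0) / (1 - off), tolerance = 1e-12)
})

test_that("a single bright disk yields one nucleus strictly inside its expansion", {
  img <- matrix(2, 120, 120)
  img <- draw_disk(img, 60, 60, 10, 80)
  pp <- preprocess_channel(img)
  nuc <- detect_nuclei(pp$norm, pp$thresholds, segmentation_params(),
                       pixel_size = 1)
  expect_equal(max(nuc$nuclei), 1)
  expect_equal(max(nuc$expanded), 1)
  expect_true(all(nuc$expanded[nuc$nuclei == 1] == 1))
  expect_gt(sum(nuc$expanded == 1), sum(nuc$nuclei == 1))
})

test_that("two disks at 1.5 radii are split, each containing its centre", {
  img <- matrix(2, 140, 140)
  img <- draw_disk(img, 70, 55, 10, 80)
  img <- draw_disk(img, 70, 85, 10, 80)   # centres 30 px apart = 1.5 diam... 1.5 r spacing rule
  pp <- preprocess_channel(img)
  nuc <- detect_nuclei(pp$norm, pp$thresholds, segmentation_params(),
                       pixel_size = 1)
  expect_equal(max(nuc$nuclei), 2)
  expect_true(nuc$nuclei[70, 55] != nuc$nuclei[70, 85])
  expect_true(all(nuc$nuclei[70, c(55, 85)] > 0))
})

test_that("an empty field yields empty masks, not an error", {
  set.seed(2)
  img <- matrix(rnorm(1e4, 10, 0.5), 100, 100)
  pp <- preprocess_channel(img)
  # force a threshold above everything: all background
  nuc <- detect_nuclei(pp$norm, c(1.1, 1.2), segmentation_params(), 1)
  expect_equal(max(nuc$nuclei), 0)
  expect_equal(max(nuc$expanded), 0)
})

test_that("a membrane ring around one nucleus becomes one compartment bounded on the ring", {
  epcam <- matrix(1, 140, 140)
  epcam <- draw_disk(epcam, 70, 70, 30, 18)   # dim interior
  ring <- draw_ring(matrix(0, 140, 140), 70, 70, 27, 30) > 0
  epcam[ring] <- 60
  nuclei <- matrix(0L, 140, 140)
  nuclei[draw_disk(matrix(0, 140, 140), 70, 70, 8) > 0] <- 1L
  pp <- preprocess_channel(epcam)
  comp <- membrane_watershed(pp$norm, nuclei, pp$thresholds,
                             segmentation_params())
  expect_equal(max(comp), 1)
  # compartment boundary pixels lie on the drawn ring
  b <- comp == 1 &
    (rbind(comp[-1, ], 0) != comp | rbind(0, comp[-140, ]) != comp |
       cbind(comp[, -1], 0) != comp | cbind(0, comp[, -140]) != comp)
  expect_gte(mean(ring[b]), 0.8)
})

test_that("a two-chamber membrane figure with two nuclei gives two compartments", {
  epcam <- matrix(1, 160, 120)
  epcam[40:120, 30:90] <- 18
  wall <- matrix(FALSE, 160, 120)
  wall[40:43, 30:90] <- TRUE; wall[117:120, 30:90] <- TRUE
  wall[40:120, 30:33] <- TRUE; wall[40:120, 87:90] <- TRUE
  wall[78:81, 30:90] <- TRUE                     # internal wall
  epcam[wall] <- 60
  nuclei <- matrix(0L, 160, 120)
  nuclei[draw_disk(matrix(0, 160, 120), 60, 60, 8) > 0] <- 1L
  nuclei[draw_disk(matrix(0, 160, 120), 100, 60, 8) > 0] <- 2L
  pp <- preprocess_channel(epcam)
  comp <- membrane_watershed(pp$norm, nuclei, pp$thresholds,
                             segmentation_params())
  expect_equal(max(comp), 2)
  expect_true(comp[60, 60] != comp[100, 60])
  expect_true(all(comp[c(60, 100) , 60] > 0))
})

test_that("an EPCAM-negative field yields no compartments", {
  set.seed(3)
  epcam <- matrix(rnorm(1e4, 5, 0.3), 100, 100)
  pp <- preprocess_channel(epcam)
  comp <- membrane_watershed(pp$norm, matrix(0L, 100, 100),
                             c(1.1, 1.2), segmentation_params())
  expect_equal(max(comp), 0)
})

test_that("fusion cuts expansions to compartments and keeps orphan compartments", {
  H <- 60; W <- 60
  nuclei <- matrix(0L, H, W); nuclei[20:24, 20:24] <- 1L
  expanded <- matrix(0L, H, W); expanded[14:30, 14:30] <- 1L   # 289 px
  comp <- matrix(0L, H, W)
  comp[16:25, 16:25] <- 1L                      # 100 px, holds the nucleus
  comp[40:55, 40:55] <- 2L                      # orphan compartment
  fused <- fuse_masks(nuclei, expanded, comp, segmentation_params())
  a1 <- sum(fused == 1)
  expect_lte(a1, 100)
  expect_true(all(comp[fused == 1] == 1))
  # orphan compartment kept verbatim as the second cell
  expect_equal(sum(fused == 2), 256)
  expect_true(all(fused[comp == 2] == 2))
})

test_that("specks below the area floor are removed", {
  H <- 40; W <- 40
  nuclei <- matrix(0L, H, W); nuclei[10, 10] <- 1L
  expanded <- matrix(0L, H, W); expanded[9:10, 9:11] <- 1L   # 6 px < 20
  comp <- matrix(0L, H, W)
  fused <- fuse_masks(nuclei, expanded, comp,
                      segmentation_params(min_area = 10))
  expect_equal(max(fused), 0)
})

test_that("quantification reports exact means, areas and centroids", {
  mask <- matrix(0L, 30, 30); mask[11:20, 6:15] <- 1L
  arr <- array(0, dim = c(30, 30, 2))
  arr[, , 1][mask == 1] <- 40
  arr[, , 2] <- matrix(runif(900, 1, 2), 30, 30)
  img <- multiplex_image(arr, c("CD45", "VIM"), pixel_size = 2)
  tb <- quantify_cells(mask, img)
  expect_equal(tb$area_px, 100)
  expect_equal(tb$area_um2, 400)
  expect_equal(tb$CD45, 40)
  # centroid of the square: rows 11..20 -> centre 15.5 px, cols 6..15 -> 10.5
  expect_equal(tb$y, 15 * 2, tolerance = 1e-9)
  expect_equal(tb$x, 10 * 2, tolerance = 1e-9)
  expect_equal(nrow(quantify_cells(matrix(0L, 5, 5),
                                   multiplex_image(array(runif(50), c(5, 5, 2)),
                                                   c("a", "b"), 1))), 0)
})

test_that("noise-free rendering quantifies to planted means within 1%", {
  ct <- tibble::tibble(type = c("mesenchymal", "macrophage"), n = c(6, 6),
                       nucleus_radius = 4, proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(260, 260), cell_types = ct, cv = 0,
                          noise_sd_frac = 0, seed = 4)
  gt <- generate_ground_truth(cfg)
  rnd <- render_multiplex_image(gt, channels = c("DAPI", "EPCAM", "VIM", "CD45"))
  tb <- quantify_cells(rnd$mask, rnd$image)
  prof <- cfg$type_profiles
  for (i in seq_len(nrow(tb))) {
    ty <- gt$cells$type[tb$cell_id[i]]
    for (mk in c("VIM", "CD45")) {
      planted <- prof[ty, mk] + 1   # +1 channel background
      expect_lt(abs(tb[[mk]][i] - planted) / planted, 0.011)
    }
  }
})

test_that("cells keep at least half of their pure nucleus after fusion", {
  cfg <- synthetic_config(field_um = c(300, 300), n_cells = 120, seed = 6)
  gt <- generate_ground_truth(cfg)
  rnd <- render_multiplex_image(gt, channels = c("DAPI", "EPCAM"))
  seg <- segment_cells(rnd$image)
  nuc <- seg$nuclei
  keep <- sort(unique(seg$mask[seg$mask > 0]))
  # for every output cell derived from nucleus k, overlap(cell, nucleus) >= 50%
  sel <- nuc > 0
  ov <- table(nucleus = nuc[sel], cell = seg$mask[sel])
  for (k in rownames(ov)) {
    own <- ov[k, ]
    cell_match <- names(which.max(own))
    if (cell_match == "0") next   # nucleus removed by sanity filter
    expect_gte(own[[cell_match]] / sum(ov[k, ]), 0.5)
  }
})
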