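# Artery-proximity analyses: composition profiles, controls, differential
# markers, semantic masks.

test_that("composition profiles bin neighbours by distance and type", {
  tb <- tibble::tibble(cell_id = 1:5,
                       x = c(0, 10, -10, 40, -40), y = 0,
                       cell_type = c("focal", "A", "A", "B", "B"))
  prof <- neighborhood_composition_profile(tb, focal_ids = 1, radius = 50,
                                           bin_width = 5)
  b10 <- prof[prof$bin_lo == 5, ]
  expect_equal(b10$cell_type, "A")
  expect_equal(b10$pct, 100)
  b40 <- prof[prof$bin_lo == 35, ]
  expect_equal(b40$cell_type, "B")
  expect_equal(b40$pct, 100)
  expect_error(neighborhood_composition_profile(tb, integer(0)), "empty")
})

test_that("profile neighbour sets equal the brute-force pairwise oracle", {
  tt <- small_tissue()
  tb <- tt$raw
  tb$cell_type <- tt$gt$cells$type
  focal <- tb$cell_id[seq(1, 400, by = 7)]
  prof <- neighborhood_composition_profile(tb, focal, radius = 50)
  # oracle: all pairwise distances from focal cells
  fx <- tb[match(focal, tb$cell_id), ]
  d <- sqrt(outer(fx$x, tb$x, "-")^2 + outer(fx$y, tb$y, "-")^2)
  d[cbind(seq_along(focal), match(focal, tb$cell_id))] <- Inf
  expect_equal(sum(prof$n), sum(d <= 50))
})

test_that("control sampling is seeded, disjoint from focals, and bounded", {
  tb <- tibble::tibble(cell_id = 1:20, is_immune = rep(c(TRUE, FALSE), 10))
  focal <- c(1, 3)
  ctrl <- sample_controls(tb, 5, pool = "immune", seed = 1, exclude = focal)
  expect_length(ctrl, 5)
  expect_length(intersect(ctrl, focal), 0)
  expect_true(all(tb$is_immune[match(ctrl, tb$cell_id)]))
  expect_identical(ctrl, sample_controls(tb, 5, "immune", 1, focal))
  all8 <- sample_controls(tb, 8, "immune", 3, focal)
  expect_setequal(all8, setdiff(tb$cell_id[tb$is_immune], focal))
  expect_error(sample_controls(tb, 9, "immune", 1, focal), "too small")
})

test_that("the rank-sum statistic matches enumeration and the reference test", {
  w <- spatmux:::wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:15, 8, replace = TRUE)   # ties included
    b <- sample(1:15, 10, replace = TRUE)
    mine <- spatmux:::wilcoxon_rank_sum(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("identical groups yield no significant markers", {
  tb <- tibble::tibble(cell_id = 1:40, m1 = rep(1:20, 2), m2 = rep(5, 40))
  res <- differential_markers(tb, 1:20, 21:40, c("m1", "m2"))
  expect_true(all(res$p >= 0.9))
  expect_false(any(res$significant))
  expect_error(differential_markers(tb, 1:20, 15:40, "m1"), "disjoint")
  expect_error(differential_markers(tb, 1:2, 21:40, "m1"), "at least 3")
})

test_that("planted artery-close marker shifts are detected with correct signs", {
  cfg <- synthetic_vessel_config(n_cells = 900, n_vessels = 2, seed = 21)
  gt <- generate_ground_truth(cfg)
  tb <- emit_cell_table(gt)
  focal <- gt$cells$id[gt$cells$tag == "artery-close"]
  tb$is_immune <- gt$cells$type %in% c("macrophage", "ILC_T")
  ctrl <- sample_controls(tb, length(focal), pool = "immune", seed = 2,
                          exclude = focal)
  res <- differential_markers(tb, focal, ctrl, panel_markers())
  sig <- res[res$significant, ]
  expect_setequal(sig$marker, c("CD90", "HLA-DR", "CD163", "MRC1"))
  expect_true(all(sig$log2fc[sig$marker %in% c("CD90", "HLA-DR")] > 1))
  expect_true(all(sig$log2fc[sig$marker %in% c("CD163", "MRC1")] < -1))
})

test_that("the binary maximum filter equals brute-force disk dilation", {
  set.seed(5)
  m <- matrix(runif(120 * 90) < 0.01, 120, 90)
  r <- 7
  out <- max_filter_binary(m, r)
  # oracle: explicit disk structuring element
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  oracle <- matrix(FALSE, 120, 90)
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    ii <- idx[, 1] + offs$di[k]; jj <- idx[, 2] + offs$dj[k]
    ok <- ii >= 1 & ii <= 120 & jj >= 1 & jj <= 90
    oracle[cbind(ii[ok], jj[ok])] <- TRUE
  }
  expect_identical(out, oracle)
})

test_that("rolling-ball subtraction removes a smooth background, keeps peaks", {
  x <- matrix(20, 150, 150)
  x[70:72, 70:72] <- 70
  out <- rolling_ball_subtract(x, 20)
  interior <- out[40:110, 40:110]
  peak <- matrix(FALSE, 71, 71); peak[31:33, 31:33] <- TRUE
  expect_lt(max(interior[!peak]), 1e-9)   # flat background fully removed
  expect_gt(out[71, 71], 40)              # compact peak survives
  expect_true(all(out >= 0))
})

test_that("component size filter and 1-px overlap rule behave as specified", {
  m <- matrix(FALSE, 100, 200)
  m[10:48, 10:48] <- TRUE          # 39x39 = 1521 px, below 2000
  m[10:59, 100:139] <- TRUE        # 50x40 = 2000 px, retained
  out <- spatmux:::drop_small_components(m, 2000)
  expect_false(any(out[10:48, 10:48]))
  expect_true(all(out[10:59, 100:139]))
})

test_that("semantic masks satisfy their algebra and recover planted contrasts", {
  cfg <- synthetic_vessel_config(n_cells = 500, n_vessels = 1, seed = 31)
  gt <- generate_ground_truth(cfg)
  rnd <- render_multiplex_image(
    gt, channels = c("ACTA2", "CD144", "CD45", "CD90", "HLA-DR", "CD163",
                     "MRC1", "DAPI"))
  masks <- semantic_artery_masks(rnd$image)
  # mask algebra
  expect_true(all((masks$immune_close | masks$immune_distant) == masks$cd45))
  expect_false(any(masks$immune_close & masks$immune_distant))
  expect_true(all(masks$zone[masks$expansion]))
  expect_gte(sum(masks$core), 2000)
  # the zone is the disk dilation of the expansion
  expect_identical(masks$zone,
                   max_filter_binary(masks$expansion,
                                     masks$params$max_filter_radius))
  contrast <- mask_intensity_contrast(masks, rnd$image)
  expect_setequal(head(contrast$channel, 2), c("CD90", "HLA-DR"))
  expect_setequal(tail(contrast$channel, 2), c("CD163", "MRC1"))
  # ordering is invariant to adding a constant to every channel
  img2 <- rnd$image
  img2$data <- img2$data + 10
  contrast2 <- mask_intensity_contrast(masks, img2)
  expect_equal(contrast2$channel, contrast$channel)
  expect_equal(contrast2$difference, contrast$difference, tolerance = 1e-9)
})

test_that("missing channels are rejected by name", {
  img <- multiplex_image(array(runif(100), c(5, 10, 2)), c("ACTA2", "CD144"), 1)
  expect_error(semantic_artery_masks(img), "CD45")
})
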