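# Ground-truth generator: counts, determinism, geometry tags, emission,
# rendering.

test_that("exact per-type counts are honoured with no structures", {
  ct <- tibble::tibble(type = "mesenchymal", n = 100, nucleus_radius = 4,
                       proliferation_rate = 0.3)
  cfg <- synthetic_config(field_um = c(500, 500), cell_types = ct, seed = 2)
  gt <- generate_ground_truth(cfg)
  expect_equal(nrow(gt$cells), 100)
  expect_true(all(gt$cells$type == "mesenchymal"))
  expect_false(anyDuplicated(gt$cells$id) > 0)
})

test_that("a fully occupied vessel ring yields the configured counts", {
  ct <- tibble::tibble(type = "mesenchymal", n = 0, nucleus_radius = 4,
                       proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(400, 400), cell_types = ct,
                          vessels = synthetic_vessels(200, 200, 30,
                                                      n_endo = 20, n_vsm = 25,
                                                      n_slots = 12,
                                                      occupancy = 1),
                          seed = 4)
  gt <- generate_ground_truth(cfg)
  expect_equal(sum(gt$cells$tag == "vessel-endothelial"), 20)
  expect_equal(sum(gt$cells$tag == "artery-close"), 12)
})

test_that("proliferating counts stay within 4 binomial sd of the configured rate", {
  ct <- tibble::tibble(type = "mesenchymal", n = 2000, nucleus_radius = 4,
                       proliferation_rate = 0.3)
  cfg <- synthetic_config(field_um = c(1100, 1100), cell_types = ct, seed = 7)
  gt <- generate_ground_truth(cfg)
  k <- sum(gt$cells$proliferating)
  sdev <- sqrt(2000 * 0.3 * 0.7)
  expect_gte(k, 600 - 4 * sdev)
  expect_lte(k, 600 + 4 * sdev)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(field_um = c(400, 400), n_cells = 300, seed = 5)
  expect_identical(generate_ground_truth(cfg), generate_ground_truth(cfg))
  gt2 <- generate_ground_truth(cfg, seed = 6)
  expect_false(identical(generate_ground_truth(cfg)$cells$x, gt2$cells$x))
})

test_that("realized composition converges to configured fractions", {
  cfg <- synthetic_config(field_um = c(1900, 1900), n_cells = 10000, seed = 8)
  gt <- generate_ground_truth(cfg)
  ct <- cfg$cell_types
  realized <- table(factor(gt$cells$type, levels = ct$type)) / nrow(gt$cells)
  for (i in seq_len(nrow(ct))) {
    p <- ct$frac[i]
    tol <- 4 * sqrt(p * (1 - p) / 10000)
    expect_lt(abs(realized[[ct$type[i]]] - p), tol + 1e-9)
  }
})

test_that("artery-close tags are reproducible from the structure registry", {
  cfg <- synthetic_vessel_config(n_cells = 500, n_vessels = 2, seed = 3)
  gt <- generate_ground_truth(cfg)
  close_cells <- gt$cells[gt$cells$tag == "artery-close", ]
  vs <- gt$structures[gt$structures$kind == "vessel", ]
  # independent distance computation: distance to the nearest vessel wall
  d_wall <- vapply(seq_len(nrow(close_cells)), function(i) {
    min(abs(sqrt((close_cells$x[i] - vs$cx)^2 + (close_cells$y[i] - vs$cy)^2) -
              vs$r_outer))
  }, numeric(1))
  expect_true(all(d_wall <= cfg$artery_close_um))
  # and no distant cell carries the tag
  far <- gt$cells[gt$cells$tag == "free", ]
  d_far <- vapply(seq_len(nrow(far)), function(i) {
    min(sqrt((far$x[i] - vs$cx)^2 + (far$y[i] - vs$cy)^2)) - max(vs$r_outer)
  }, numeric(1))
  expect_true(all(d_far > 0))
})

test_that("infeasible packing raises an error naming the culprit", {
  ct <- tibble::tibble(type = "mesenchymal", n = 5000, nucleus_radius = 4,
                       proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(200, 200), cell_types = ct, seed = 1)
  expect_error(generate_ground_truth(cfg), "infeasible packing")
  expect_error(
    generate_ground_truth(
      synthetic_config(field_um = c(400, 400),
                       cell_types = tibble::tibble(type = "mesenchymal", n = 0,
                                                   nucleus_radius = 4,
                                                   proliferation_rate = 0),
                       vessels = synthetic_vessels(200, 200, 20, n_endo = 60),
                       seed = 1)),
    "vessel")
})

test_that("emitted tables reproduce configured means exactly at zero dispersion", {
  ct <- tibble::tibble(type = c("mesenchymal", "endothelial"), n = c(2, 1),
                       nucleus_radius = 4, proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(300, 300), cell_types = ct, cv = 0,
                          background = setNames(rep(0, 22), spatmux:::default_marker_panel()),
                          seed = 10)
  gt <- generate_ground_truth(cfg)
  tb <- emit_cell_table(gt)
  prof <- cfg$type_profiles
  for (i in seq_len(nrow(tb))) {
    ty <- gt$cells$type[i]
    expect_equal(unlist(tb[i, colnames(prof)]), prof[ty, ],
                 ignore_attr = TRUE)
  }
})

test_that("emission is seed-deterministic and recovers the mesenchymal share", {
  cfg <- synthetic_config(field_um = c(1900, 1900), n_cells = 10000, seed = 12)
  gt <- generate_ground_truth(cfg)
  expect_identical(emit_cell_table(gt, seed = 3), emit_cell_table(gt, seed = 3))
  share <- mean(gt$cells$type == "mesenchymal")
  expect_lt(abs(share - 0.34), 0.02)
})

test_that("rendering puts DAPI inside nuclei and is bit-identical across runs", {
  ct <- tibble::tibble(type = "mesenchymal", n = 1, nucleus_radius = 4,
                       proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(60, 60), cell_types = ct, cv = 0.35,
                          noise_sd_frac = 0, seed = 2)
  gt <- generate_ground_truth(cfg)
  rnd <- render_multiplex_image(gt, channels = c("DAPI", "VIM"))
  dapi <- get_channel(rnd$image, "DAPI")
  yy <- (seq_len(nrow(dapi)) - 0.5) * 0.51
  xx <- (seq_len(ncol(dapi)) - 0.5) * 0.51
  nuc <- outer((yy - gt$cells$y)^2, (xx - gt$cells$x)^2, "+") <= 16
  expect_gt(mean(dapi[nuc]), mean(dapi[!nuc]))
  rnd2 <- render_multiplex_image(gt, channels = c("DAPI", "VIM"))
  expect_identical(rnd$image$data, rnd2$image$data)
  expect_identical(rnd$mask, rnd2$mask)
})

test_that("rendered CD90 is elevated on artery-close immune pixels", {
  cfg <- synthetic_vessel_config(n_cells = 400, n_vessels = 1, seed = 6)
  gt <- generate_ground_truth(cfg)
  rnd <- render_multiplex_image(gt, channels = c("CD90", "CD45"))
  cd90 <- get_channel(rnd$image, "CD90")
  close_ids <- gt$cells$id[gt$cells$tag == "artery-close"]
  far_imm <- gt$cells$id[gt$cells$tag == "free" &
                           gt$cells$type %in% c("macrophage", "ILC_T")]
  expect_gt(length(close_ids), 5)
  m_close <- mean(cd90[rnd$mask %in% close_ids])
  m_far <- mean(cd90[rnd$mask %in% far_imm])
  expect_gte(m_close, 1.5 * m_far)
})

test_that("too-coarse pixel size is rejected", {
  ct <- tibble::tibble(type = "mesenchymal", n = 5, nucleus_radius = 4,
                       proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(100, 100), cell_types = ct,
                          pixel_size = 3, seed = 1)
  gt <- generate_ground_truth(cfg)
  expect_error(render_multiplex_image(gt), "too coarse")
})
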