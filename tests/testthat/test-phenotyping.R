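# Clustering, annotation, subclustering, gating, composition.

test_that("two disjoint marker supports give two pure clusters", {
  set.seed(1)
  n <- 500
  tb <- tibble::tibble(
    cell_id = 1:(2 * n),
    m1 = c(rlnorm(n, log(50), 0.3), rlnorm(n, log(1), 0.3)),
    m2 = c(rlnorm(n, log(1), 0.3), rlnorm(n, log(50), 0.3)))
  tb <- arcsinh_normalize(tb, c("m1", "m2"), 5)
  # modularity at resolution 1 subdivides large homogeneous blobs; a low
  # resolution recovers the two planted populations exactly
  res <- cluster_cells(tb, c("m1", "m2"), resolution = 0.02, seed = 1)
  expect_equal(nrow(res$means), 2)
  purity <- max(table(res$labels[1:n])) / n
  expect_gte(purity, 0.99)
})

test_that("vanishing resolution collapses a connected population to one cluster", {
  set.seed(2)
  tb <- tibble::tibble(cell_id = 1:300, m1 = rnorm(300), m2 = rnorm(300))
  res <- cluster_cells(tb, c("m1", "m2"), resolution = 1e-4, seed = 1)
  expect_equal(nrow(res$means), 1)
  res1 <- cluster_cells(tb, c("m1", "m2"), resolution = 1, seed = 1)
  expect_gte(nrow(res1$means), nrow(res$means))
})

test_that("clustering is deterministic given the seed", {
  tb <- small_tissue()$norm
  r1 <- cluster_cells(tb, panel_markers(), seed = 3)
  r2 <- cluster_cells(tb, panel_markers(), seed = 3)
  expect_identical(r1$labels, r2$labels)
})

test_that("fewer cells than k is an error", {
  tb <- tibble::tibble(cell_id = 1:5, m = rnorm(5))
  expect_error(cluster_cells(tb, "m", k_neighbors = 10), "k_neighbors")
})

test_that("annotation recovers planted types on the synthetic tissue", {
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  ann <- add_annotation(tt$norm, res)
  acc <- mean(ann$cell_type == type_to_label[tt$gt$cells$type])
  expect_gte(acc, 0.95)
})

test_that("an EPCAM/SOX9 cluster is annotated as SOX9-high epithelial", {
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  ann <- annotate_clusters(res)
  sox9 <- ann[ann$cell_type == "SOX9-high epithelial", ]
  expect_gt(nrow(sox9), 0)
  expect_true(any(grepl("SOX9", sox9$evidence) & grepl("EPCAM", sox9$evidence)))
})

test_that("an empty rulebook leaves every cluster unassigned", {
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  ann <- annotate_clusters(res, annotation_rulebook(rules = list()))
  expect_true(all(ann$cell_type == "unassigned"))
})

test_that("annotation is invariant to cluster relabelling", {
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  k <- nrow(res$means)
  perm <- sample(k)
  res2 <- res
  res2$labels <- match(res$labels, perm)
  res2$means <- res$means[perm, , drop = FALSE]
  rownames(res2$means) <- seq_len(k)
  a1 <- add_annotation(tt$norm, res)$cell_type
  a2 <- add_annotation(tt$norm, res2)$cell_type
  expect_equal(a1, a2)
})

test_that("subclustering separates types hidden under a coarse parent label", {
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  tb <- add_annotation(tt$norm, res)
  # collapse the two epithelial annotations into one coarse parent
  tb$cell_type[tb$cell_type %in% c("SOX2-high epithelial",
                                   "SOX9-high epithelial")] <- "epithelial"
  sub <- subcluster(tb, "epithelial", c("EPCAM", "SOX2", "SOX9"),
                    resolution = 0.5, seed = 1)
  sel <- !is.na(sub)
  expect_true(all(startsWith(sub[sel], "epithelial.")))
  truth <- tt$gt$cells$type[sel]
  tab <- table(sub[sel], truth)
  # the two planted epithelial types land in different subclusters
  best <- apply(tab, 2, which.max)
  expect_true(best[["SOX2_epithelial"]] != best[["SOX9_epithelial"]])
  # lower resolution cannot create more subclusters
  sub_lo <- subcluster(tb, "epithelial", c("EPCAM", "SOX2", "SOX9"),
                       resolution = 0.05, seed = 1)
  expect_lte(length(unique(na.omit(sub_lo))), length(unique(na.omit(sub))))
  expect_error(subcluster(tb, "no such type", "EPCAM"), "too small")
})

test_that("gates recover planted B cells and respect their thresholds", {
  # dedicated gating fixture: 20% B cells among a mixed immune/stromal field,
  # percentiles set against those planted shares
  ct <- tibble::tibble(type = c("B_cell", "macrophage", "mesenchymal"),
                       n = c(200, 300, 500), nucleus_radius = 4,
                       proliferation_rate = 0)
  cfg <- synthetic_config(field_um = c(700, 700), cell_types = ct, seed = 11)
  gt <- generate_ground_truth(cfg)
  tb <- arcsinh_normalize(emit_cell_table(gt), panel_markers(), 5)
  g <- gate_cells(tb, list(gate("B cell", c("CD19", "CD45"),
                                percentile = c(CD19 = 79, CD45 = 45))))
  truth <- gt$cells$type == "B_cell"
  called <- !is.na(g)
  # the CD19 conjunct at p45 admits only the B high mode; CD45 admits immune
  expect_gte(sum(truth & called) / sum(called), 0.9)   # precision
  expect_gte(sum(truth & called) / sum(truth), 0.9)    # recall
  above_max <- list(gate("x", "CD19", absolute = c(CD19 = max(tb$CD19) + 1)))
  expect_true(all(is.na(gate_cells(tb, above_max))))
  expect_error(gate_cells(tb, list(gate("x", "NOPE"))), "NOPE")
  # disjoint gates yield disjoint label sets
  g2 <- gate_cells(tb, list(gate("hi", "CD19", percentile = 99),
                            gate("lo", "CD19", absolute = c(CD19 = -1))))
  expect_true(all(table(g2) > 0))
  expect_false(any(g2[!is.na(g2)] == "hi" & g2[!is.na(g2)] == "lo"))
})

test_that("composition percentages sum to 100 and match planted shares", {
  tb <- tibble::tibble(week = 6, cell_type = rep(c("A", "B"), each = 50))
  comp <- composition(tb)
  expect_equal(comp$pct, c(50, 50))
  tt <- small_tissue()
  res <- cluster_cells(tt$norm, panel_markers(), seed = 1)
  ann <- add_annotation(tt$norm, res)
  comp2 <- composition(ann)
  expect_equal(sum(comp2$pct), 100, tolerance = 1e-9)
  planted <- table(type_to_label[tt$gt$cells$type]) / nrow(tt$gt$cells)
  for (ty in names(planted)) {
    got <- comp2$pct[comp2$cell_type == ty]
    if (length(got) == 1)
      expect_lt(abs(got / 100 - planted[[ty]]), 0.03)
  }
  expect_error(composition(tibble::tibble(week = 6,
                                          cell_type = NA_character_)),
               "no annotated cells")
})

test_that("marker correlation is symmetric with unit diagonal; duplicates correlate fully", {
  tt <- small_tissue()
  tb <- tt$norm
  tb$VIM2 <- tb$VIM
  cc <- marker_correlation(tb, c("VIM", "VIM2", "CD45"))
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc["VIM", "VIM2"], 1)
})
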