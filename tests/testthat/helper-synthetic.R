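# Shared fixtures and small oracles used across test files.

# mapping from generator type names to rulebook annotation labels
type_to_label <- c(
  mesenchymal = "mesenchymal", endothelial = "endothelial",
  SOX2_epithelial = "SOX2-high epithelial",
  SOX9_epithelial = "SOX9-high epithelial",
  airway_smooth_muscle = "airway smooth muscle",
  vascular_smooth_muscle = "vascular smooth muscle",
  pericyte = "pericyte", macrophage = "macrophage", ILC_T = "ILC & T",
  B_cell = "B cell", NK_cell = "NK cell",
  lymphatic_endothelial = "lymphatic endothelial")

panel_markers <- function() colnames(spatmux:::default_type_profiles())

# small phenotyping fixture: well-separated types, emitted table + truth
small_tissue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(field_um = c(700, 700), n_cells = 1500, seed = 42)
      gt <- generate_ground_truth(cfg)
      tb <- emit_cell_table(gt)
      norm <- arcsinh_normalize(tb, panel_markers(), 5)
      cache <<- list(cfg = cfg, gt = gt, raw = tb, norm = norm)
    }
    cache
  }
})

# matched-instance recall/precision at an IoU threshold
iou_match <- function(truth, pred, thr = 0.5) {
  sel <- truth > 0 & pred > 0
  df <- data.frame(t = truth[sel], p = pred[sel])
  ov <- dplyr::count(df, t, p)
  at <- tabulate(truth[truth > 0])
  ap <- tabulate(pred[pred > 0])
  ov$iou <- ov$n / (at[ov$t] + ap[ov$p] - ov$n)
  good <- ov[ov$iou >= thr, ]
  list(recall = length(unique(good$t)) / sum(at > 0),
       precision = length(unique(good$p)) / sum(ap > 0))
}

# draw a filled disk into a matrix
draw_disk <- function(m, cy, cx, r, value = 1) {
  H <- nrow(m); W <- ncol(m)
  ii <- pmax(1, floor(cy - r)):pmin(H, ceiling(cy + r))
  jj <- pmax(1, floor(cx - r)):pmin(W, ceiling(cx + r))
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  sub <- m[ii, jj]
  sub[d2 <= r^2] <- value
  m[ii, jj] <- sub
  m
}

# draw an annulus (ring) into a matrix
draw_ring <- function(m, cy, cx, r0, r1, value = 1) {
  H <- nrow(m); W <- ncol(m)
  ii <- pmax(1, floor(cy - r1)):pmin(H, ceiling(cy + r1))
  jj <- pmax(1, floor(cx - r1)):pmin(W, ceiling(cx + r1))
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  sub <- m[ii, jj]
  sub[d2 >= r0^2 & d2 <= r1^2] <- value
  m[ii, jj] <- sub
  m
}

# exact two-sided Fisher oracle by direct enumeration with lchoose
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  pobs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(p[p <= pobs * (1 + 1e-7)])
}
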