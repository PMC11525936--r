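# Artery-proximity analyses: instance-based neighbourhood composition and
# differential markers, plus the semantic-mask workflow.

#' Composition-vs-distance profile around focal cells
#'
#' For each distance bin (default 5-µm bins out to 50 µm), the percentage of
#' neighbours of each cell type, pooled over all focal cells. A focal cell is
#' excluded from its own neighbourhood but may appear in another focal
#' cell's.
#'
#' @param table annotated cell tibble (`cell_id`, `x`, `y`, `cell_type`).
#' @param focal_ids cell ids of the focal set.
#' @param radius profile radius in µm.
#' @param bin_width distance bin width in µm.
#' @return tibble with `bin_lo`, `bin_hi`, `cell_type`, `n`, `pct` (per bin).
#' @export
neighborhood_composition_profile <- function(table, focal_ids, radius = 50,
                                             bin_width = 5) {
  assert_that(length(focal_ids) > 0, "focal set is empty")
  assert_that(all(focal_ids %in% table$cell_id), "focal ids not all in table")
  assert_that("cell_type" %in% names(table), "need cell_type annotations")
  g <- build_neighbor_graph(table, radius)
  e <- g$edges
  dir_src <- c(e$from, e$to); dir_dst <- c(e$to, e$from); dd <- c(e$dist, e$dist)
  sel <- dir_src %in% focal_ids
  nb <- tibble::tibble(dist = dd[sel],
                       cell_type = table$cell_type[match(dir_dst[sel], table$cell_id)])
  breaks <- seq(0, radius, by = bin_width)
  nb$bin <- cut(nb$dist, breaks, include.lowest = TRUE, right = TRUE)
  nb |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::count(.data$bin, .data$cell_type) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = breaks[as.integer(.data$bin)],
                  bin_hi = breaks[as.integer(.data$bin) + 1]) |>
    dplyr::select("bin_lo", "bin_hi", "cell_type", "n", "pct")
}

#' Sample control cells
#'
#' Uniform sample without replacement from the immune pool (excluding the
#' focal set) or from all non-focal cells.
#'
#' @param table cell tibble with `cell_id`.
#' @param n number of controls.
#' @param pool `"immune"` (requires logical column `immune_col`) or `"any"`.
#' @param seed integer seed.
#' @param exclude cell ids excluded from the pool (the focal set).
#' @param immune_col name of the logical immune-indicator column.
#' @return vector of sampled cell ids.
#' @export
sample_controls <- function(table, n, pool = c("immune", "any"), seed = 0L,
                            exclude = NULL, immune_col = "is_immune") {
  pool <- match.arg(pool)
  cand <- table$cell_id
  if (pool == "immune") {
    assert_that(immune_col %in% names(table),
                paste0("pool = 'immune' needs column ", immune_col))
    cand <- cand[table[[immune_col]]]
  }
  cand <- setdiff(cand, exclude)
  assert_that(length(cand) >= n,
              paste0("control pool too small: ", length(cand), " < ", n))
  set.seed(seed)
  sample(cand, n)
}

# Wilcoxon rank-sum with normal approximation and tie correction (no
# continuity correction), matching the large-sample two-sided test.
wilcoxon_rank_sum <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Differential marker expression between two cell groups
#'
#' Per marker: two-sided Wilcoxon rank-sum (normal approximation with tie
#' correction), Benjamini-Hochberg adjustment across markers, and
#' `log2FC = log2((mean_A + eps) / (mean_B + eps))`. A marker is significant
#' iff adjusted p < `alpha` and |log2FC| > `lfc`.
#'
#' @param table cell tibble.
#' @param ids_a,ids_b disjoint cell-id groups (each >= 3 cells).
#' @param markers marker columns to test.
#' @param alpha adjusted-p cut (0.05).
#' @param lfc absolute log2 fold-change cut (1).
#' @param eps mean guard (1e-9).
#' @return tibble with `marker`, `mean_a`, `mean_b`, `log2fc`, `p`, `padj`,
#'   `significant`, ordered by `log2fc` descending.
#' @export
differential_markers <- function(table, ids_a, ids_b, markers,
                                 alpha = 0.05, lfc = 1, eps = 1e-9) {
  assert_that(length(ids_a) >= 3 && length(ids_b) >= 3,
              "each group needs at least 3 cells")
  assert_that(length(intersect(ids_a, ids_b)) == 0, "groups must be disjoint")
  ia <- match(ids_a, table$cell_id); ib <- match(ids_b, table$cell_id)
  assert_that(!anyNA(ia) && !anyNA(ib), "ids not all present in table")
  res <- purrr::map_dfr(markers, function(m) {
    va <- table[[m]][ia]; vb <- table[[m]][ib]
    w <- wilcoxon_rank_sum(va, vb)
    tibble::tibble(marker = m, mean_a = mean(va), mean_b = mean(vb),
                   log2fc = log2((mean(va) + eps) / (mean(vb) + eps)),
                   p = w$p)
  })
  res$padj <- p.adjust(res$p, method = "BH")
  res$significant <- res$padj < alpha & abs(res$log2fc) > lfc
  dplyr::arrange(res, dplyr::desc(.data$log2fc))
}

#' Parameters of the semantic artery-mask workflow
#'
#' @param rolling_ball_radius background-subtraction radius (px) for CD45.
#' @param blur_sigma named Gaussian blur sigmas (px) per channel.
#' @param min_artery_px minimum artery-core component size (px).
#' @param overlap_px minimum overlap (px) for the ACTA2 expansion.
#' @param max_filter_radius proximity-zone radius (px).
#' @param nbins histogram bins for the triangle threshold.
#' @return list of class `macro_params`.
#' @export
macro_params <- function(rolling_ball_radius = 50,
                         blur_sigma = c(ACTA2 = 4, CD144 = 4, CD45 = 2),
                         min_artery_px = 2000, overlap_px = 1,
                         max_filter_radius = 80, nbins = 256) {
  assert_that(rolling_ball_radius > 0 && max_filter_radius > 0 &&
              all(blur_sigma > 0), "all radii must be > 0")
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 blur_sigma = blur_sigma, min_artery_px = min_artery_px,
                 overlap_px = overlap_px,
                 max_filter_radius = max_filter_radius, nbins = nbins),
            class = "macro_params")
}

#' Rolling-ball background subtraction
#'
#' Morphological background estimation: grayscale opening with a disk of the
#' given radius, subtracted from the input (clamped at 0).
#'
#' @param x numeric matrix.
#' @param radius structuring-element radius (px).
#' @return background-subtracted matrix.
#' @export
rolling_ball_subtract <- function(x, radius) {
  br <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  # grayscale morphology operates on [0, 1]; rescale around it
  hi <- max(x, 1)
  bg <- EBImage::opening(x / hi, br) * hi
  pmax(x - matrix(as.numeric(bg), nrow(x), ncol(x)), 0)
}

#' Maximum filter of a binary mask with a Euclidean disk
#'
#' For binary input the maximum filter equals morphological dilation with
#' the same structuring element; it is computed exactly via the Euclidean
#' distance transform: a pixel is in the output iff some foreground pixel
#' lies within `radius`.
#'
#' @param mask logical matrix.
#' @param radius disk radius (px, Euclidean, measured centre-to-centre).
#' @return logical matrix.
#' @export
max_filter_binary <- function(mask, radius) {
  if (!any(mask)) return(mask)
  d <- EBImage::distmap(!mask)
  mask | (matrix(as.numeric(d), nrow(mask), ncol(mask)) <= radius)
}

#' Semantic artery masks (threshold-based workflow)
#'
#' Pipeline, in order: CD45 rolling-ball background subtraction; per-channel
#' Gaussian blur; per-channel triangle threshold into binary masks; artery
#' core = ACTA2 AND CD144 with components below the size filter removed;
#' optional correction (add/remove masks replacing interactive validation);
#' ACTA2 expansion = union of ACTA2 components overlapping the corrected
#' core by at least `overlap_px`; proximity zone = maximum filter (disk) of
#' the expansion; artery-close immune = CD45 mask AND zone; artery-distant
#' immune = CD45 mask AND NOT zone.
#'
#' @param image a [multiplex_image()] with ACTA2, CD144 and CD45 channels.
#' @param params a [macro_params()].
#' @param correction optional list with logical `add` / `remove` masks
#'   applied to the artery core.
#' @return list of class `semantic_masks` with logical matrices `core`,
#'   `acta2`, `cd144`, `cd45`, `expansion`, `zone`, `immune_close`,
#'   `immune_distant`, and `params`.
#' @export
semantic_artery_masks <- function(image, params = macro_params(),
                                  correction = NULL) {
  for (ch in c("ACTA2", "CD144", "CD45"))
    assert_that(ch %in% image$channels, paste0("missing channel: ", ch))
  acta2 <- get_channel(image, "ACTA2")
  cd144 <- get_channel(image, "CD144")
  cd45 <- rolling_ball_subtract(get_channel(image, "CD45"),
                                params$rolling_ball_radius)
  bl <- function(x, ch) gaussian_smooth(x, params$blur_sigma[[ch]])
  acta2_b <- bl(acta2, "ACTA2"); cd144_b <- bl(cd144, "CD144"); cd45_b <- bl(cd45, "CD45")
  th <- function(x) x > triangle_threshold(x, params$nbins)
  m_acta2 <- th(acta2_b); m_cd144 <- th(cd144_b); m_cd45 <- th(cd45_b)
  core <- m_acta2 & m_cd144
  core <- drop_small_components(core, params$min_artery_px)
  if (!is.null(correction)) {
    if (!is.null(correction$add)) core <- core | correction$add
    if (!is.null(correction$remove)) core <- core & !correction$remove
  }
  # expansion within the ACTA2 mask: keep ACTA2 components overlapping core
  lab <- EBImage::bwlabel(m_acta2)
  lab <- matrix(as.integer(lab), nrow(core), ncol(core))
  if (max(lab) > 0) {
    ov <- tabulate(lab[core & lab > 0], nbins = max(lab))
    keep <- which(ov >= params$overlap_px)
    expansion <- matrix(lab %in% keep, nrow(core), ncol(core)) & m_acta2
  } else expansion <- core
  expansion <- expansion | core
  zone <- max_filter_binary(expansion, params$max_filter_radius)
  structure(list(core = core, acta2 = m_acta2, cd144 = m_cd144, cd45 = m_cd45,
                 expansion = expansion, zone = zone,
                 immune_close = m_cd45 & zone,
                 immune_distant = m_cd45 & !zone,
                 params = params),
            class = "semantic_masks")
}

drop_small_components <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Intensity contrast between artery-close and -distant immune regions
#'
#' Mean and median of every channel inside the artery-close vs artery-distant
#' immune masks, with the per-channel difference `mean_close - mean_distant`,
#' ordered by difference.
#'
#' @param masks a [semantic_artery_masks()] result.
#' @param image the [multiplex_image()] the masks were derived from (all
#'   channels are measured).
#' @return tibble with `channel`, `mean_close`, `mean_distant`,
#'   `median_close`, `median_distant`, `difference`, sorted by `difference`
#'   descending.
#' @export
mask_intensity_contrast <- function(masks, image) {
  assert_that(all(dim(masks$immune_close) == dim(image$data)[1:2]),
              "masks and image geometry differ")
  assert_that(any(masks$immune_close), "artery-close immune region is empty")
  assert_that(any(masks$immune_distant), "artery-distant immune region is empty")
  purrr::map_dfr(image$channels, function(ch) {
    m <- get_channel(image, ch)
    tibble::tibble(channel = ch,
                   mean_close = mean(m[masks$immune_close]),
                   mean_distant = mean(m[masks$immune_distant]),
                   median_close = median(m[masks$immune_close]),
                   median_distant = median(m[masks$immune_distant]))
  }) |>
    dplyr::mutate(difference = .data$mean_close - .data$mean_distant) |>
    dplyr::arrange(dplyr::desc(.data$difference))
}
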