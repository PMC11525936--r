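# Image rendering and table emission from ground truth.

immune_types <- c("macrophage", "ILC_T", "B_cell", "NK_cell")
epithelial_types <- c("SOX2_epithelial", "SOX9_epithelial")

# log-normal per-cell, per-marker intensity draws shared by the image
# renderer and the table emitter. cv = 0 collapses to the exact means.
draw_cell_intensities <- function(gt, config = gt$config) {
  cells <- gt$cells
  prof <- config$type_profiles
  mk <- colnames(prof)
  mu <- prof[cells$type, , drop = FALSE]
  if ("Ki67" %in% mk)
    mu[cells$proliferating, "Ki67"] <- mu[cells$proliferating, "Ki67"] * config$ki67_shift
  shift <- config$vessel_immune_shift
  close_imm <- cells$tag == "artery-close"
  if (any(close_imm) && length(shift) > 0) {
    for (m in intersect(names(shift), mk))
      mu[close_imm, m] <- mu[close_imm, m] * shift[[m]]
  }
  if (config$cv <= 0) return(mu)
  sdlog <- sqrt(log(1 + config$cv^2))
  draws <- rlnorm(length(mu), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  matrix(draws, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Emit a per-cell table directly from ground truth
#'
#' Bypasses imaging and segmentation: one row per planted cell with marker
#' intensities drawn from the configured log-normal model plus the per-channel
#' constant background. Ki67 means of proliferating cells are elevated by the
#' configured shift, and artery-close immune cells carry the configured
#' marker-mean multipliers.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param config a [synthetic_config()] (defaults to the one inside `gt`).
#' @param seed integer seed for the intensity draws.
#' @return tibble with `cell_id`, `x`, `y` (µm), `area_px`, `area_um2`,
#'   `week` and one column per marker.
#' @export
emit_cell_table <- function(gt, config = gt$config, seed = gt$seed + 1L) {
  assert_that(nrow(gt$cells) > 0, "ground truth contains no cells")
  set.seed(seed)
  intens <- draw_cell_intensities(gt, config)
  bg <- config$background[colnames(intens)]
  bg[is.na(bg)] <- 0
  intens <- sweep(intens, 2, bg, "+")
  r_foot <- gt$cells$nucleus_radius + config$cell_rim
  area_um2 <- pi * r_foot^2
  out <- tibble::tibble(cell_id = gt$cells$id, x = gt$cells$x, y = gt$cells$y,
                        area_px = round(area_um2 / config$pixel_size^2),
                        area_um2 = area_um2, week = config$week)
  dplyr::bind_cols(out, tibble::as_tibble(intens))
}

#' Render a multichannel image and true label mask from ground truth
#'
#' Draws, per cell: DAPI and Ki67 over the nucleus disk; EPCAM as a membrane
#' outline (cell-boundary ring) with a dim interior on epithelial cells; every
#' other marker over the whole cell footprint. Footprints are nucleus disks
#' grown by the configured cytoplasm rim, with contested pixels assigned to
#' the nearest cell centre, so the returned mask is a valid instance
#' segmentation ground truth. Vessel structures additionally paint a solid
#' ACTA2 annulus (media) and a CD144 annulus (endothelial lining) so that
#' semantic artery masks have contiguous support. Signal is synthesized
#' noise-free, then optional Poisson resampling and Gaussian noise (sd =
#' `noise_sd_frac` of the nominal high-signal level, 60) are applied and the
#' result is clamped at 0 and rounded to integer counts.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param config a [synthetic_config()] (defaults to the one inside `gt`).
#' @param channels channels to render (default: the full configured panel).
#' @param seed integer seed for intensity draws and noise.
#' @return list with `image` (a [multiplex_image()]) and `mask` (integer
#'   matrix, the true instance labels).
#' @export
render_multiplex_image <- function(gt, config = gt$config,
                                   channels = colnames(config$type_profiles),
                                   seed = gt$seed + 2L) {
  cells <- gt$cells
  ps <- config$pixel_size
  assert_that(min(cells$nucleus_radius) / ps >= 2,
              "pixel size too coarse: smallest nucleus under 2 px radius")
  set.seed(seed)
  H <- as.integer(ceiling(config$field_um[2] / ps))
  W <- as.integer(ceiling(config$field_um[1] / ps))
  n <- nrow(cells)
  intens <- draw_cell_intensities(gt, config)

  # footprint rasterization with nearest-centre resolution of contested pixels
  mask <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  r_foot <- (cells$nucleus_radius + config$cell_rim) / ps
  cx <- cells$x / ps; cy <- cells$y / ps   # pixel units, 0-based geometry
  px_info <- vector("list", n)
  for (i in seq_len(n)) {
    j0 <- max(1L, floor(cx[i] - r_foot[i])); j1 <- min(W, ceiling(cx[i] + r_foot[i]) + 1L)
    i0 <- max(1L, floor(cy[i] - r_foot[i])); i1 <- min(H, ceiling(cy[i] + r_foot[i]) + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    dx <- (jj - 0.5) - cx[i]; dy <- (ii - 0.5) - cy[i]
    d2 <- outer(dy^2, dx^2, "+")
    sel <- d2 <= r_foot[i]^2
    if (!any(sel)) next
    lin <- as.vector(outer(ii, (jj - 1L) * H, "+"))[as.vector(sel)]
    dv <- sqrt(d2[sel])
    win <- dv < bestd[lin]
    mask[lin[win]] <- i
    bestd[lin[win]] <- dv[win]
    px_info[[i]] <- list(lin = lin, d = dv)
  }
  # keep only owned pixels per cell
  for (i in seq_len(n)) {
    pi_ <- px_info[[i]]
    if (is.null(pi_)) next
    own <- mask[pi_$lin] == i
    px_info[[i]] <- list(lin = pi_$lin[own], d = pi_$d[own])
  }
  # cell-boundary pixels (any 4-neighbour with a different label)
  boundary <- matrix(FALSE, H, W)
  boundary[-1, ] <- boundary[-1, ] | (mask[-1, ] != mask[-H, ])
  boundary[-H, ] <- boundary[-H, ] | (mask[-H, ] != mask[-1, ])
  boundary[, -1] <- boundary[, -1] | (mask[, -1] != mask[, -W])
  boundary[, -W] <- boundary[, -W] | (mask[, -W] != mask[, -1])
  boundary <- boundary & mask > 0

  r_nuc <- cells$nucleus_radius / ps
  is_epi <- cells$type %in% epithelial_types
  high_level <- 60
  arr <- array(0, dim = c(H, W, length(channels)))
  for (k in seq_along(channels)) {
    ch <- channels[k]
    assert_that(ch %in% colnames(intens), paste0("unknown channel: ", ch))
    canvas <- matrix(config$background[[ch]] %||% 0, H, W)
    for (i in seq_len(n)) {
      pi_ <- px_info[[i]]
      if (is.null(pi_) || length(pi_$lin) == 0) next
      v <- intens[i, ch]
      if (ch %in% c("DAPI", "Ki67")) {
        nuc <- pi_$d <= r_nuc[i]
        canvas[pi_$lin[nuc]] <- canvas[pi_$lin[nuc]] + v
      } else if (ch == "EPCAM" && is_epi[i]) {
        # membrane ring about 1.5 µm thick, plus contested borders
        ring <- pi_$d >= r_foot[i] - 1.5 / ps | boundary[pi_$lin]
        canvas[pi_$lin[ring]] <- canvas[pi_$lin[ring]] + v
        canvas[pi_$lin[!ring]] <- canvas[pi_$lin[!ring]] + 0.3 * v
      } else if (ch == "EPCAM") {
        # non-epithelial: no membrane signal
      } else {
        canvas[pi_$lin] <- canvas[pi_$lin] + v
      }
    }
    if (!is.null(config$vessels) && ch %in% c("ACTA2", "CD144")) {
      for (vi in seq_len(nrow(config$vessels))) {
        v <- config$vessels[vi, ]
        ann <- if (ch == "ACTA2") c(v$r - 2, v$r + 10) else c(v$r - 2, v$r + 2)
        lev <- if (ch == "ACTA2") 60 else 55
        canvas <- paint_annulus(canvas, v$cx / ps, v$cy / ps,
                                ann[1] / ps, ann[2] / ps, lev)
      }
    }
    if (config$poisson_noise) canvas[] <- rpois(length(canvas), pmax(canvas, 0))
    if (config$noise_sd_frac > 0)
      canvas <- canvas + rnorm(length(canvas), 0, config$noise_sd_frac * high_level)
    arr[, , k] <- round(pmax(canvas, 0))
  }
  list(image = multiplex_image(arr, channels, ps), mask = mask)
}

paint_annulus <- function(canvas, cx, cy, r0, r1, value) {
  H <- nrow(canvas); W <- ncol(canvas)
  j0 <- max(1L, floor(cx - r1)); j1 <- min(W, ceiling(cx + r1) + 1L)
  i0 <- max(1L, floor(cy - r1)); i1 <- min(H, ceiling(cy + r1) + 1L)
  jj <- j0:j1; ii <- i0:i1
  d2 <- outer(((ii - 0.5) - cy)^2, ((jj - 0.5) - cx)^2, "+")
  sel <- d2 >= r0^2 & d2 <= r1^2
  sub <- canvas[ii, jj]
  sub[sel] <- sub[sel] + value
  canvas[ii, jj] <- sub
  canvas
}

#' Write all synthetic-tissue artifacts to a directory
#'
#' Emits the ground-truth CSV, the structure registry (GeoJSON-like circles
#' polygonized to 64-gons), the rendered multichannel TIFF and the true-label
#' mask TIFF.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param dir output directory (created if missing).
#' @param channels channels to render.
#' @return the directory path, invisibly.
#' @export
write_synthetic_bundle <- function(gt, dir, channels = c("DAPI", "EPCAM")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(gt$cells, file.path(dir, "ground_truth_cells.csv"), row.names = FALSE)
  if (nrow(gt$structures) > 0) {
    polys <- lapply(seq_len(nrow(gt$structures)), function(i) {
      s <- gt$structures[i, ]
      th <- seq(0, 2 * pi, length.out = 65)[-65]
      cbind(s$cx + s$r_outer * cos(th), s$cy + s$r_outer * sin(th))
    })
    rs <- region_set(gt$structures$structure_id,
                     rep("include", nrow(gt$structures)), polys)
    write_regions(rs, file.path(dir, "structures.geojson"))
  }
  rnd <- render_multiplex_image(gt, channels = channels)
  write_multichannel_image(rnd$image, file.path(dir, "image.tiff"))
  write_label_mask(rnd$mask, file.path(dir, "true_mask.tiff"))
  invisible(dir)
}
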