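# Fused nuclei/membrane instance segmentation and per-cell quantification.

#' Segmentation parameters
#'
#' @param sigma_dapi,sigma_epcam Gaussian smoothing sigma (px) applied to the
#'   normalized DAPI / EPCAM channels before detection.
#' @param expansion_um nucleus expansion radius (µm): the cytoplasm rim grown
#'   around each detected nucleus by nearest-nucleus assignment.
#' @param min_area,max_area sanity-filter bounds on cell area (px).
#' @param min_sep_px minimum separation (px) between distance-transform peaks
#'   when splitting touching nuclei.
#' @param floor_frac intensity sanity floor, as a fraction of the lower Otsu
#'   class boundary of the respective channel. A cell passes when its mean
#'   normalized DAPI or EPCAM exceeds `floor_frac` times the channel's lower
#'   cut; 0.5 by default because the nuclear signal is diluted roughly
#'   threefold when averaged over the expanded cell footprint.
#' @param connectivity pixel connectivity of the watershed flood (4 or 8).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_dapi = 2, sigma_epcam = 1,
                                expansion_um = 3, min_area = 20,
                                max_area = 5000, min_sep_px = 7,
                                floor_frac = 0.5, connectivity = 4L) {
  assert_that(expansion_um >= 0, "expansion radius must be >= 0")
  assert_that(min_area < max_area, "min_area must be below max_area")
  structure(list(sigma_dapi = sigma_dapi, sigma_epcam = sigma_epcam,
                 expansion_um = expansion_um, min_area = min_area,
                 max_area = max_area, min_sep_px = min_sep_px,
                 floor_frac = floor_frac,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Preprocess a channel: quantile background shift, min-max, multi-Otsu
#'
#' Subtracts the lower 0.01-percentile (the 1e-4 quantile) of the raw values,
#' min-max normalizes into \[0, 1\], and computes the two 3-class Otsu cut
#' points on the normalized values.
#'
#' @param raster numeric matrix of raw intensities.
#' @return list with `norm` (matrix in \[0, 1\]), `thresholds` (length-2,
#'   lower and upper cut), and `offset` (the subtracted quantile).
#' @export
preprocess_channel <- function(raster) {
  assert_that(is.numeric(raster), "raster must be numeric")
  rng <- range(raster)
  assert_that(rng[1] < rng[2], "constant image: no dynamic range")
  offset <- as.numeric(quantile(raster, 1e-4, names = FALSE))
  x <- pmax(raster - offset, 0)
  x <- (x - min(x)) / (max(x) - min(x))
  list(norm = x, thresholds = multiotsu_thresholds(x, classes = 3),
       offset = offset)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  EBImage::gblur(x, sigma = sigma)
}

# regional maxima of a smoothed raster, plateaus merged into one seed each;
# grayscale dilation (local maximum filter) runs on the [0, 1] scale
local_maxima_seeds <- function(x, fg, min_sep_px) {
  if (!any(fg)) return(matrix(0L, nrow(x), ncol(x)))
  br <- EBImage::makeBrush(2L * as.integer(min_sep_px) + 1L, shape = "disc")
  hi <- max(x)
  mx <- matrix(as.numeric(EBImage::dilate(x / hi, br)), nrow(x), ncol(x)) * hi
  peaks <- (x >= mx - 1e-9 * hi) & fg & x > 0
  lab <- EBImage::bwlabel(peaks)
  matrix(as.integer(lab), nrow(x), ncol(x))
}

#' Detect nuclei on preprocessed DAPI
#'
#' Classical detector: foreground is the smoothed channel above the lower
#' Otsu threshold; touching nuclei are split by a watershed on the (smoothed)
#' distance transform seeded at its regional maxima; each nucleus is then
#' expanded by `expansion_um` with contested pixels going to the nearest
#' nucleus, so expansions never overlap and each pure nucleus is contained in
#' its expansion.
#'
#' @param dapi_norm normalized DAPI matrix (from [preprocess_channel()]).
#' @param thresholds the channel's multi-Otsu cut points.
#' @param params a [segmentation_params()].
#' @param pixel_size µm per pixel (converts the expansion radius).
#' @return list with `nuclei` and `expanded` integer label matrices.
#' @export
detect_nuclei <- function(dapi_norm, thresholds, params = segmentation_params(),
                          pixel_size = 1) {
  sm <- gaussian_smooth(dapi_norm, params$sigma_dapi)
  fg <- sm > thresholds[1]
  H <- nrow(dapi_norm); W <- ncol(dapi_norm)
  if (!any(fg))
    return(list(nuclei = matrix(0L, H, W), expanded = matrix(0L, H, W)))
  dm <- EBImage::distmap(fg)
  dms <- gaussian_smooth(matrix(as.numeric(dm), H, W), 1.5)
  dms[!fg] <- 0
  seeds <- local_maxima_seeds(dms, fg, params$min_sep_px)
  nuclei <- seeded_watershed_cpp(-dms, seeds, fg, params$connectivity)
  # expansion: flood the distance-to-nucleus field outward up to the radius
  r_px <- params$expansion_um / pixel_size
  if (r_px > 0) {
    dout <- EBImage::distmap(nuclei == 0)
    dout <- matrix(as.numeric(dout), H, W)
    expanded <- seeded_watershed_cpp(dout, nuclei, dout <= r_px,
                                     params$connectivity)
  } else expanded <- nuclei
  list(nuclei = nuclei, expanded = expanded)
}

#' Membrane-bounded compartments from preprocessed EPCAM
#'
#' Watershed on the smoothed EPCAM intensity (membranes are the ridges),
#' seeded by the nuclei, by interior regions carrying no nucleus, and by the
#' below-threshold background; basins are clipped to the filled
#' EPCAM-positive region so compartment boundaries lie on membrane ridges.
#'
#' @param epcam_norm normalized EPCAM matrix.
#' @param nuclei nuclei label matrix (seeds).
#' @param thresholds EPCAM multi-Otsu cut points.
#' @param params a [segmentation_params()].
#' @return integer compartment label matrix (0 where no compartment).
#' @export
membrane_watershed <- function(epcam_norm, nuclei, thresholds,
                               params = segmentation_params()) {
  H <- nrow(epcam_norm); W <- ncol(epcam_norm)
  sm <- gaussian_smooth(epcam_norm, params$sigma_epcam)
  fg <- sm > thresholds[1]
  if (!any(fg)) return(matrix(0L, H, W))
  fg <- EBImage::fillHull(fg) > 0
  ridge <- sm > thresholds[2]
  # interior chambers: sub-ridge regions of the filled figure; only chambers
  # containing no nucleus anywhere become their own seeds, so a nucleus owns
  # its whole chamber
  chambers <- EBImage::bwlabel(fg & !ridge)
  chambers <- matrix(as.integer(chambers), H, W)
  if (max(chambers) > 0) {
    with_nuc <- unique(chambers[chambers > 0 & nuclei > 0])
    chambers[chambers %in% with_nuc] <- 0L
  }
  if (max(chambers) > 0) {
    # a genuine chamber is enclosed by membrane ridge; components adjacent to
    # the outside (blur halos at figure borders) are not seeds
    bg_nb <- !fg[c(2:H, H), ] | !fg[c(1, 1:(H - 1)), ] |
      !fg[, c(2:W, W)] | !fg[, c(1, 1:(W - 1))]
    touches <- unique(chambers[bg_nb & chambers > 0])
    chambers[chambers %in% touches] <- 0L
  }
  offset <- max(nuclei)
  seeds <- matrix(0L, H, W)
  seeds[nuclei > 0] <- nuclei[nuclei > 0]
  seeds[chambers > 0] <- chambers[chambers > 0] + offset
  # background seed: everything below the lower threshold outside the figures
  bg_lab <- offset + max(chambers) + 1L
  seeds[!fg & sm <= thresholds[1]] <- bg_lab
  ws <- seeded_watershed_cpp(sm, seeds, matrix(TRUE, H, W), params$connectivity)
  ws[ws == bg_lab] <- 0L
  ws[!fg] <- 0L
  # chambers reachable only through the background flood vanish with it;
  # relabel compartments contiguously, nuclei-seeded basins first
  relabel_mask(ws)
}

relabel_mask <- function(m) {
  u <- sort(unique(m[m > 0]))
  if (length(u) == 0) return(m)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  m[m > 0] <- lut[m[m > 0]]
  m
}

#' Fuse nuclei expansions with membrane compartments
#'
#' Each expanded nucleus is cut to the compartment holding the majority of
#' its pure nucleus (ties to the lower compartment label); compartments with
#' no nucleus become cells as-is; nuclei with no compartment keep their
#' expanded shape outside all compartments. Cells failing the area window or
#' failing both intensity floors (mean normalized DAPI and mean normalized
#' EPCAM both below the respective lower Otsu cut) are removed, and labels
#' are re-indexed 1..N (nucleus-derived cells first).
#'
#' @param nuclei,expanded,compartments label matrices of equal size.
#' @param params a [segmentation_params()].
#' @param dapi_norm,epcam_norm optional normalized channels for the intensity
#'   floor; omitted, only the area filter applies.
#' @param floors length-2 intensity floors (lower Otsu cut of DAPI and EPCAM).
#' @return integer cell label matrix.
#' @export
fuse_masks <- function(nuclei, expanded, compartments,
                       params = segmentation_params(),
                       dapi_norm = NULL, epcam_norm = NULL, floors = NULL) {
  assert_that(all(dim(nuclei) == dim(expanded)) &&
              all(dim(nuclei) == dim(compartments)),
              "mask shapes differ")
  H <- nrow(nuclei); W <- ncol(nuclei)
  nv <- as.integer(nuclei); ev <- as.integer(expanded); cv <- as.integer(compartments)
  n_nuc <- max(nv, 0L); n_comp <- max(cv, 0L)
  out <- integer(H * W)

  comp_assign <- rep(NA_integer_, n_nuc)
  if (n_nuc > 0 && n_comp > 0) {
    sel <- nv > 0L
    code <- (nv[sel] - 1) * (n_comp + 1) + cv[sel] # comp 0 included
    cnt <- tabulate(code + 1, nbins = n_nuc * (n_comp + 1))
    cnt <- matrix(cnt, nrow = n_comp + 1) # rows: comp 0..n_comp, cols: nucleus
    # majority over compartments 1..n_comp only if it beats "no compartment"?
    # rule: assign to the compartment with the largest pure-nucleus overlap,
    # provided it overlaps any compartment at all; ties to lower label
    in_comp <- cnt[-1, , drop = FALSE]
    best <- apply(in_comp, 2, function(col) {
      if (all(col == 0)) NA_integer_ else which.max(col)
    })
    comp_assign <- as.integer(best)
  }

  # rule (b): compartments with no assigned nucleus become cells as-is
  has_nuc <- rep(FALSE, max(n_comp, 1L))
  if (n_nuc > 0) has_nuc[stats::na.omit(comp_assign)] <- TRUE
  if (n_comp > 0) {
    orphan <- which(!has_nuc[seq_len(n_comp)])
    if (length(orphan) > 0) {
      new_id <- integer(n_comp)
      new_id[orphan] <- n_nuc + seq_along(orphan)
      selb <- cv > 0L
      idsb <- new_id[cv[selb]]
      hit <- idsb > 0L
      out[which(selb)[hit]] <- idsb[hit]
    }
  }
  # rules (a) and (c)
  if (n_nuc > 0) {
    sela <- ev > 0L
    a <- comp_assign[ev[sela]]
    keep <- (!is.na(a) & cv[sela] == a) | (is.na(a) & cv[sela] == 0L)
    idx <- which(sela)[keep]
    out[idx] <- ev[sela][keep]
  }

  out <- matrix(out, H, W)
  # sanity filter
  n_cells <- max(out, 0L)
  if (n_cells > 0) {
    areas <- tabulate(out[out > 0], nbins = n_cells)
    ok <- areas >= params$min_area & areas <= params$max_area
    if (!is.null(dapi_norm) && !is.null(epcam_norm) && !is.null(floors)) {
      live <- which(areas > 0)
      md <- rowsum(as.numeric(dapi_norm[out > 0]), out[out > 0])[, 1] / areas[live]
      me <- rowsum(as.numeric(epcam_norm[out > 0]), out[out > 0])[, 1] / areas[live]
      pass_int <- rep(FALSE, n_cells)
      pass_int[live] <- md >= params$floor_frac * floors[1] |
        me >= params$floor_frac * floors[2]
      ok <- ok & pass_int
    }
    drop <- which(!ok)
    if (length(drop) > 0) out[out %in% drop] <- 0L
  }
  relabel_mask(out)
}

#' Quantify cells on the original image
#'
#' Per cell: centroid (µm), areas, mean of the original (unnormalized)
#' intensity of every channel, and a binary positivity call per channel (mean
#' normalized intensity above the channel's upper multi-Otsu cut point).
#'
#' @param mask integer cell label matrix.
#' @param image a [multiplex_image()] sharing the mask's geometry.
#' @return tibble with `cell_id`, `x`, `y`, `area_px`, `area_um2`, one mean
#'   column per channel and one `<channel>_pos` logical column per channel.
#' @export
quantify_cells <- function(mask, image) {
  assert_that(all(dim(mask) == dim(image$data)[1:2]),
              "mask and image dimensions differ")
  n <- max(mask, 0L)
  if (n == 0) {
    return(tibble::tibble(cell_id = integer(), x = numeric(), y = numeric(),
                          area_px = integer(), area_um2 = numeric()))
  }
  ps <- image$pixel_size
  sel <- mask > 0L
  lab <- mask[sel]
  areas <- tabulate(lab, nbins = n)
  rr <- row(mask)[sel]; cc <- col(mask)[sel]
  live <- which(areas > 0)
  cy <- unname(rowsum(as.numeric(rr), lab)[, 1]) / areas[live]
  cx <- unname(rowsum(as.numeric(cc), lab)[, 1]) / areas[live]
  out <- tibble::tibble(cell_id = live,
                        x = (cx - 0.5) * ps, y = (cy - 0.5) * ps,
                        area_px = areas[live], area_um2 = areas[live] * ps^2)
  for (ch in image$channels) {
    m <- get_channel(image, ch)
    out[[ch]] <- unname(rowsum(as.numeric(m[sel]), lab)[, 1]) / areas[live]
    if (min(m) < max(m)) {
      pp <- preprocess_channel(m)
      mean_norm <- unname(rowsum(as.numeric(pp$norm[sel]), lab)[, 1]) / areas[live]
      out[[paste0(ch, "_pos")]] <- mean_norm > pp$thresholds[2]
    } else {
      # constant channel: no dynamic range, nothing can be called positive
      out[[paste0(ch, "_pos")]] <- FALSE
    }
  }
  out
}

#' Run the full segmentation pipeline on a multichannel image
#'
#' Preprocess DAPI and EPCAM, detect and expand nuclei, compute membrane
#' compartments, fuse, and quantify every channel.
#'
#' @param image a [multiplex_image()] containing `DAPI` and `EPCAM`.
#' @param params a [segmentation_params()].
#' @return list with `table` (cell tibble), `mask` (cell labels), `nuclei`,
#'   `expanded`, `compartments`.
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  pd <- preprocess_channel(get_channel(image, "DAPI"))
  pe <- preprocess_channel(get_channel(image, "EPCAM"))
  nuc <- detect_nuclei(pd$norm, pd$thresholds, params, image$pixel_size)
  comp <- membrane_watershed(pe$norm, nuc$nuclei, pe$thresholds, params)
  mask <- fuse_masks(nuc$nuclei, nuc$expanded, comp, params,
                     dapi_norm = pd$norm, epcam_norm = pe$norm,
                     floors = c(pd$thresholds[1], pe$thresholds[1]))
  list(table = quantify_cells(mask, image), mask = mask,
       nuclei = nuc$nuclei, expanded = nuc$expanded, compartments = comp)
}
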