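# Configuration for the synthetic lung-like tissue generator.

default_marker_panel <- function() {
  c("DAPI", "EPCAM", "SOX2", "SOX9", "ACTA2", "CD31", "CD144", "PDPN",
    "CD45", "VIM", "DCN", "CD90", "Ki67", "CD3", "CD4", "CD44", "CD56",
    "CD68", "CD163", "HLA-DR", "MRC1", "CD19")
}

# Per-type expected marker intensities (linear scale, arbitrary units).
# Baseline (off) markers sit at 2; lineage markers at 40-60 so that the
# log-normal draws of distinct types have essentially disjoint supports.
default_type_profiles <- function(markers = default_marker_panel()) {
  base <- 2
  types <- list(
    mesenchymal            = c(VIM = 60, DCN = 50, CD90 = 25),
    endothelial            = c(CD31 = 60, CD144 = 55),
    SOX2_epithelial        = c(EPCAM = 60, SOX2 = 55),
    SOX9_epithelial        = c(EPCAM = 60, SOX9 = 55),
    airway_smooth_muscle   = c(ACTA2 = 60, VIM = 20),
    vascular_smooth_muscle = c(ACTA2 = 60, CD90 = 40),
    pericyte               = c(CD90 = 50, ACTA2 = 25),
    macrophage             = c(CD45 = 60, CD68 = 55, CD163 = 45, MRC1 = 40,
                               `HLA-DR` = 45, CD44 = 35, CD90 = 12),
    ILC_T                  = c(CD45 = 60, CD3 = 55, CD4 = 40, CD44 = 25,
                               CD90 = 12),
    B_cell                 = c(CD45 = 60, CD19 = 55, `HLA-DR` = 30),
    NK_cell                = c(CD45 = 60, CD56 = 55),
    lymphatic_endothelial  = c(CD31 = 45, PDPN = 60)
  )
  prof <- matrix(base, nrow = length(types), ncol = length(markers),
                 dimnames = list(names(types), markers))
  prof[, "DAPI"] <- 50
  prof[, "Ki67"] <- 3
  for (ty in names(types)) {
    hi <- types[[ty]]
    prof[ty, names(hi)] <- hi
  }
  prof
}

default_cell_types <- function() {
  tibble::tribble(
    ~type,                    ~frac, ~nucleus_radius, ~proliferation_rate,
    "mesenchymal",             0.34,  4.0,             0.30,
    "endothelial",             0.20,  4.0,             0.30,
    "SOX2_epithelial",         0.10,  4.5,             0.35,
    "SOX9_epithelial",         0.14,  4.5,             0.60,
    "airway_smooth_muscle",    0.10,  4.0,             0.15,
    "macrophage",              0.06,  3.5,             0.10,
    "ILC_T",                   0.03,  3.5,             0.20,
    "B_cell",                  0.015, 3.5,             0.50,
    "NK_cell",                 0.015, 3.5,             0.20
  )
}

#' Configuration of the synthetic tissue generator
#'
#' The generator plants a field of non-overlapping cells with log-normal
#' marker profiles per (type, marker), optional spatial domains (regions with
#' distinct type mixtures), airway structures (a SOX2-high epithelial ring
#' around a lumen, wrapped by an airway-smooth-muscle ring), SOX9-high distal
#' tips, and arterial vessels (endothelial ring, vascular-smooth-muscle ring,
#' and an immune ring whose occupants carry shifted marker profiles, e.g.
#' CD90/HLA-DR up and CD163/MRC1 down). It emulates the statistical structure
#' the downstream analysis assumes — lineage-separable intensity profiles,
#' domain-specific mixtures, percentile-separable Ki67 — not optics.
#'
#' @param field_um numeric length-2, field width (x) and height (y) in µm.
#' @param pixel_size µm per pixel for rendered images.
#' @param cell_types tibble with columns `type`, one of `frac`/`n`,
#'   `nucleus_radius` (µm) and `proliferation_rate` in \[0, 1\].
#' @param type_profiles matrix (type × marker) of expected linear-scale
#'   intensities; rows must cover every type used anywhere in the config.
#' @param n_cells total number of free-field cells (ignored when `cell_types`
#'   carries exact `n` counts).
#' @param cv log-normal coefficient of variation shared by all (type, marker)
#'   pairs.
#' @param background named per-channel additive background (default 1 for
#'   every panel marker).
#' @param noise_sd_frac Gaussian image noise sd as a fraction of the nominal
#'   high-signal level.
#' @param poisson_noise if `TRUE`, Poisson resampling of the rendered signal
#'   before the Gaussian term.
#' @param ki67_shift multiplicative Ki67 elevation of proliferating cells.
#' @param cell_rim cytoplasm rim (µm) added to the nucleus radius to form the
#'   cell footprint.
#' @param min_spacing_factor minimum centre-to-centre distance between cells
#'   as a multiple of the larger nucleus radius; set 0 to allow touching or
#'   overlapping placements.
#' @param domains optional tibble (`domain`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `mixture` list column of named type fractions) defining axis-aligned
#'   domain bands with their own type mixtures.
#' @param airways,tips,vessels optional structure tibbles; see
#'   [synthetic_airways()], [synthetic_tips()], [synthetic_vessels()].
#' @param vessel_immune_shift named multipliers applied to the marker means
#'   of artery-close immune cells.
#' @param artery_close_um tag distance: immune ring cells are planted within
#'   this distance of the vessel wall.
#' @param week week label written into emitted tables.
#' @param seed default seed used when an operation is not given one.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(field_um = c(1000, 1000),
                             pixel_size = 0.51,
                             cell_types = default_cell_types(),
                             type_profiles = default_type_profiles(),
                             n_cells = 3000,
                             cv = 0.35,
                             background = NULL,
                             noise_sd_frac = 0.05,
                             poisson_noise = FALSE,
                             ki67_shift = 8,
                             cell_rim = 3,
                             min_spacing_factor = 2.8,
                             domains = NULL,
                             airways = NULL,
                             tips = NULL,
                             vessels = NULL,
                             vessel_immune_shift = c(CD90 = 4, `HLA-DR` = 4,
                                                     CD163 = 0.25, MRC1 = 0.25),
                             artery_close_um = 25,
                             week = 12,
                             seed = 1L) {
  markers <- colnames(type_profiles)
  if (is.null(background)) background <- setNames(rep(1, length(markers)), markers)
  cfg <- list(field_um = field_um, pixel_size = pixel_size,
              cell_types = cell_types, type_profiles = type_profiles,
              n_cells = n_cells, cv = cv, background = background,
              noise_sd_frac = noise_sd_frac, poisson_noise = poisson_noise,
              ki67_shift = ki67_shift, cell_rim = cell_rim,
              min_spacing_factor = min_spacing_factor, domains = domains,
              airways = airways, tips = tips, vessels = vessels,
              vessel_immune_shift = vessel_immune_shift,
              artery_close_um = artery_close_um, week = week, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  assert_that(length(cfg$field_um) == 2 && all(cfg$field_um > 0),
              "field_um must be two positive lengths")
  assert_that(cfg$pixel_size > 0, "pixel_size must be > 0")
  ct <- cfg$cell_types
  assert_that(all(c("type", "nucleus_radius", "proliferation_rate") %in% names(ct)),
              "cell_types needs columns type, nucleus_radius, proliferation_rate")
  assert_that(all(ct$proliferation_rate >= 0 & ct$proliferation_rate <= 1),
              "proliferation rates must lie in [0, 1]")
  assert_that(all(ct$nucleus_radius > 0), "nucleus radii must be > 0")
  if ("n" %in% names(ct)) assert_that(all(ct$n >= 0), "cell counts must be >= 0")
  missing_prof <- setdiff(ct$type, rownames(cfg$type_profiles))
  assert_that(length(missing_prof) == 0,
              paste("no marker profile for type(s):",
                    paste(missing_prof, collapse = ", ")))
  assert_that(cfg$min_spacing_factor >= 0, "min_spacing_factor must be >= 0")
  for (nm in c("airways", "tips", "vessels")) {
    st <- cfg[[nm]]
    if (is.null(st)) next
    outer <- switch(nm,
                    airways = st$lumen_r + 14,
                    tips = st$r,
                    vessels = st$r + 26)
    fits <- st$cx - outer >= 0 & st$cx + outer <= cfg$field_um[1] &
      st$cy - outer >= 0 & st$cy + outer <= cfg$field_um[2]
    assert_that(all(fits), paste0(nm, " geometry does not fit inside the field"))
  }
  invisible(cfg)
}

#' Structure tables for the synthetic generator
#'
#' Convenience constructors for the structure specs accepted by
#' [synthetic_config()]. Counts left `NA` are filled from ring circumference
#' at generation time.
#'
#' @param cx,cy centre coordinates (µm).
#' @param lumen_r airway lumen radius (µm): the SOX2-high epithelial ring sits
#'   on this circle and the ASM ring 8 µm outside it.
#' @param r tip radius / vessel endothelial-ring radius (µm).
#' @param n,n_epi,n_asm,n_endo,n_vsm,n_slots explicit cell counts (optional).
#' @param occupancy per-slot Bernoulli probability that an immune-ring slot is
#'   occupied.
#' @return a tibble understood by [synthetic_config()].
#' @export
synthetic_airways <- function(cx, cy, lumen_r, n_epi = NA, n_asm = NA) {
  tibble::tibble(cx = cx, cy = cy, lumen_r = lumen_r, n_epi = n_epi, n_asm = n_asm)
}

#' @rdname synthetic_airways
#' @export
synthetic_tips <- function(cx, cy, r, n = NA) {
  tibble::tibble(cx = cx, cy = cy, r = r, n = n)
}

#' @rdname synthetic_airways
#' @export
synthetic_vessels <- function(cx, cy, r, n_endo = NA, n_vsm = NA, n_slots = NA,
                              occupancy = 1) {
  tibble::tibble(cx = cx, cy = cy, r = r, n_endo = n_endo, n_vsm = n_vsm,
                 n_slots = n_slots, occupancy = occupancy)
}

#' Preset: three-domain tissue for spatial-domain recovery
#'
#' Three vertical tissue bands with distinct type mixtures sharing a 10%
#' macrophage infiltrate (so domains mix types): mesenchyme-dominated,
#' distal-epithelium-dominated (plus 10% endothelial), and a vascular zone
#' (endothelial-dominated with airway smooth muscle). Marker dispersion is
#' raised to cv = 2 because spatial-domain inference presumes expression
#' continua between neighbouring cells, not the fully separated lineage
#' islands of the phenotyping preset.
#'
#' @param n_cells total cells (default 10000).
#' @param seed generator seed.
#' @return a [synthetic_config()].
#' @export
synthetic_domain_config <- function(n_cells = 10000, seed = 1L) {
  side <- round(sqrt(n_cells / 2.77e-3))   # keep density near 2770 cells/mm^2
  b <- side / 3
  mix <- list(
    A = c(mesenchymal = 0.90, macrophage = 0.10),
    B = c(SOX9_epithelial = 0.80, macrophage = 0.10, endothelial = 0.10),
    C = c(endothelial = 0.75, airway_smooth_muscle = 0.15, macrophage = 0.10))
  doms <- tibble::tibble(domain = c("A", "B", "C"),
                         xmin = c(0, b, 2 * b), xmax = c(b, 2 * b, side),
                         ymin = 0, ymax = side, mixture = mix)
  synthetic_config(field_um = c(side, side), n_cells = n_cells,
                   domains = doms, cv = 2, seed = seed)
}

#' Preset: vessel-bearing tissue for the artery-proximity analyses
#'
#' Plants arterial vessels (endothelial ring, vascular-smooth-muscle ring,
#' solid ACTA2/CD144 annuli for the semantic masks) with a fully occupied
#' immune collar whose cells carry the configured marker shifts (CD90 and
#' HLA-DR up four-fold, CD163 and MRC1 down four-fold). The free-field
#' immune compartment uses the same macrophage:ILC-and-T ratio (7:3) as the
#' collar so the planted shifts are the only systematic difference between
#' artery-close and artery-distant immune cells.
#'
#' @param n_cells free-field cells (default 1500).
#' @param n_vessels number of vessels (1 to 4).
#' @param seed generator seed.
#' @return a [synthetic_config()].
#' @export
synthetic_vessel_config <- function(n_cells = 1500, n_vessels = 3, seed = 1L) {
  ct <- tibble::tribble(
    ~type,                  ~frac, ~nucleus_radius, ~proliferation_rate,
    "mesenchymal",           0.40,  4.0,             0.30,
    "endothelial",           0.18,  4.0,             0.30,
    "SOX2_epithelial",       0.08,  4.5,             0.35,
    "SOX9_epithelial",       0.12,  4.5,             0.60,
    "airway_smooth_muscle",  0.07,  4.0,             0.15,
    "macrophage",            0.105, 3.5,             0.10,
    "ILC_T",                 0.045, 3.5,             0.20
  )
  pos <- list(c(200, 200), c(600, 250), c(300, 580), c(620, 600))[seq_len(n_vessels)]
  vessels <- synthetic_vessels(cx = vapply(pos, `[`, numeric(1), 1),
                               cy = vapply(pos, `[`, numeric(1), 2),
                               r = 30, occupancy = 1)
  synthetic_config(field_um = c(800, 800), n_cells = n_cells,
                   cell_types = ct, vessels = vessels, seed = seed)
}
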