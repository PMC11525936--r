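# Per-cell table preprocessing: background subtraction, normalization,
# region-based spatial filtering. Canonical order: subtract -> exclude ->
# normalize.

#' Background specification
#'
#' Constant per-(marker, week) background intensities, as measured in
#' signal-free regions of interest.
#'
#' @param marker,week,value equal-length vectors.
#' @return tibble of class `background_spec`.
#' @export
background_spec <- function(marker, week, value) {
  assert_that(all(value >= 0), "background values must be >= 0")
  tb <- tibble::tibble(marker = as.character(marker), week = week,
                       value = as.numeric(value))
  assert_that(!anyDuplicated(tb[c("marker", "week")]),
              "one background value per (marker, week)")
  tibble::new_tibble(tb, class = "background_spec")
}

#' Subtract per-marker background
#'
#' `intensity' = max(intensity - bg, 0)`, matched on the table's `week`
#' column; all other columns are unchanged.
#'
#' @param table cell tibble with a `week` column and marker columns.
#' @param spec a [background_spec()] covering every marker in `markers`.
#' @param markers marker columns to treat (default: all markers in `spec`).
#' @return the table with background-subtracted marker columns.
#' @export
subtract_background <- function(table, spec, markers = unique(spec$marker)) {
  miss <- setdiff(markers, names(table))
  assert_that(length(miss) == 0,
              paste("markers absent from table:", paste(miss, collapse = ", ")))
  for (m in markers) {
    s <- spec[spec$marker == m, ]
    if (nrow(s) == 0)
      rlang::abort(paste0("no background value for marker '", m, "'"))
    bg <- s$value[match(table$week, s$week)]
    if (anyNA(bg))
      rlang::abort(paste0("no background value for marker '", m, "' in week(s) ",
                          paste(unique(table$week[is.na(bg)]), collapse = ", ")))
    table[[m]] <- pmax(table[[m]] - bg, 0)
  }
  table
}

#' Arcsinh marker normalization
#'
#' `x' = asinh(x / cofactor)`; monotone and order-preserving. The cofactor
#' default of 5 follows the flow/mass-cytometry convention.
#'
#' @param table cell tibble.
#' @param markers marker columns to transform.
#' @param cofactor positive scale.
#' @return the table with transformed marker columns.
#' @export
arcsinh_normalize <- function(table, markers, cofactor = 5) {
  assert_that(cofactor > 0, "cofactor must be > 0")
  miss <- setdiff(markers, names(table))
  assert_that(length(miss) == 0,
              paste("markers absent from table:", paste(miss, collapse = ", ")))
  for (m in markers) table[[m]] <- asinh(table[[m]] / cofactor)
  table
}

#' Drop cells inside exclusion regions (or outside all inclusion regions)
#'
#' Cells whose centroid falls inside any `exclude` polygon are dropped; if
#' `include` polygons are present, cells outside all of them are dropped too.
#' Boundary points count as inside (even-odd rule).
#'
#' @param table cell tibble with `x`, `y` in µm.
#' @param regions a [region_set()].
#' @return the filtered table.
#' @export
exclude_regions <- function(table, regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    rlang::inform("no regions supplied; table returned unchanged")
    return(table)
  }
  keep <- rep(TRUE, nrow(table))
  inc <- regions[regions$role == "include", ]
  exc <- regions[regions$role == "exclude", ]
  if (nrow(inc) > 0) {
    inside_any <- rep(FALSE, nrow(table))
    for (i in seq_len(nrow(inc)))
      inside_any <- inside_any | point_in_polygon(table$x, table$y, inc$coords[[i]])
    keep <- keep & inside_any
  }
  for (i in seq_len(nrow(exc)))
    keep <- keep & !point_in_polygon(table$x, table$y, exc$coords[[i]])
  table[keep, , drop = FALSE]
}

#' Cell density per analysis area
#'
#' Count divided by the total `include`-region area, per week.
#'
#' @param table cell tibble with `x`, `y`, `week`.
#' @param regions a [region_set()] with at least one `include` polygon.
#' @return tibble with `week`, `n_cells`, `area_mm2`, `density_mm2`.
#' @export
cell_density <- function(table, regions) {
  inc <- regions[regions$role == "include", ]
  assert_that(nrow(inc) > 0, "cell_density needs at least one include region")
  area_um2 <- sum(vapply(inc$coords, polygon_area, numeric(1)))
  assert_that(area_um2 > 0, "include regions have zero area")
  inside <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(inc)))
    inside <- inside | point_in_polygon(table$x, table$y, inc$coords[[i]])
  table[inside, , drop = FALSE] |>
    dplyr::count(.data$week, name = "n_cells") |>
    dplyr::mutate(area_mm2 = area_um2 / 1e6,
                  density_mm2 = .data$n_cells / .data$area_mm2)
}
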