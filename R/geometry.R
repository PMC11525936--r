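#' Construct a set of named analysis regions
#'
#' Regions are simple polygons in physical micrometre coordinates, each with a
#' role drawn from a closed vocabulary. They replace the interactive
#' selections (artifact exclusion, airway and immune-selection outlines) that
#' image viewers provide, so that a whole run is reproducible from files.
#'
#' @param name character vector of region names (unique).
#' @param role character vector of roles; one of `"include"`, `"exclude"`,
#'   `"airway-small-SOX2"`, `"airway-large-SOX2"`, `"airway-SOX9"`,
#'   `"artery-immune-selection"`.
#' @param coords list of two-column numeric matrices (x, y in µm), one
#'   polygon per region; the closing vertex may be omitted.
#' @return A tibble of class `region_set` with columns `name`, `role`,
#'   `coords` (list column).
#' @export
region_set <- function(name, role, coords) {
  roles <- c("include", "exclude", "airway-small-SOX2", "airway-large-SOX2",
             "airway-SOX9", "artery-immune-selection")
  assert_that(length(name) == length(role) && length(role) == length(coords),
              "name, role and coords must have equal length")
  assert_that(!anyDuplicated(name), "region names must be unique")
  bad <- setdiff(unique(role), roles)
  if (length(bad) > 0)
    rlang::abort(paste0("unknown region role(s): ", paste(bad, collapse = ", ")))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    assert_that(ncol(m) == 2 && nrow(m) >= 3, "polygons need >= 3 (x, y) vertices")
    # drop an explicitly closed last vertex
    if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    if (!polygon_is_simple(m)) rlang::abort("polygon is self-intersecting")
    unname(m)
  })
  tibble::new_tibble(
    tibble::tibble(name = as.character(name), role = as.character(role),
                   coords = coords),
    class = "region_set")
}

# segment intersection test used to reject self-intersecting polygons
polygon_is_simple <- function(m) {
  n <- nrow(m)
  seg <- cbind(m, m[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param x,y numeric vectors of point coordinates (µm).
#' @param poly two-column matrix of polygon vertices (µm), not closed.
#' @return logical vector, `TRUE` where the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  tol <- 1e-9
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- qx[k]; y2 <- qy[k]
    # boundary: collinear and within the segment's bounding box
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cr) <= tol * max(1, sqrt(seg_len2)) &
      x >= pmin(x1, x2) - tol & x <= pmax(x1, x2) + tol &
      y >= pmin(y1, y2) - tol & y <= pmax(y1, y2) + tol
    on_edge <- on_edge | on_seg
    # even-odd ray cast (horizontal ray towards +x)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix of vertices (µm), not closed.
#' @return area in µm².
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- x[c(2:n, 1)]; ys <- y[c(2:n, 1)]
  abs(sum(x * ys - xs * y)) / 2
}

#' Write / read a region set as a GeoJSON-like file
#'
#' Coordinates are stored in micrometres (not longitude/latitude); otherwise
#' the file follows the GeoJSON FeatureCollection layout so standard viewers
#' can display it.
#'
#' @param regions a [region_set()].
#' @param path file path.
#' @return `write_regions()` returns `path` invisibly; `read_regions()`
#'   returns a `region_set`.
#' @export
write_regions <- function(regions, path) {
  feats <- purrr::pmap(regions, function(name, role, coords) {
    ring <- rbind(coords, coords[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = name, role = role),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  region_set(
    name = purrr::map_chr(feats, ~ .x$properties$name),
    role = purrr::map_chr(feats, ~ .x$properties$role),
    coords = purrr::map(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      m
    }))
}
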