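# Image container and readers/writers for the standard artifacts.

#' Multichannel image container
#'
#' A channel-stacked intensity raster with channel names and physical pixel
#' size. Data are stored as an `H x W x C` numeric array; rows are the image
#' y axis (top-left origin), columns the x axis.
#'
#' @param data `H x W x C` array (or `H x W` matrix for one channel).
#' @param channels character vector of marker names, length `C`.
#' @param pixel_size µm per pixel (> 0).
#' @return object of class `multiplex_image`.
#' @export
multiplex_image <- function(data, channels, pixel_size) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  assert_that(length(dim(data)) == 3, "data must be an H x W x C array")
  assert_that(dim(data)[3] == length(channels),
              "number of channels must match the third array dimension")
  assert_that(pixel_size > 0, "pixel_size must be > 0")
  assert_that(!anyNA(data), "image contains NA values")
  dimnames(data)[[3]] <- channels
  structure(list(data = data, channels = as.character(channels),
                 pixel_size = pixel_size),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<multiplex_image> ", d[1], " x ", d[2], " px, ", d[3], " channel(s), ",
      x$pixel_size, " µm/px\n  channels: ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one channel as a matrix
#' @param image a [multiplex_image()].
#' @param channel channel name.
#' @return numeric `H x W` matrix.
#' @export
get_channel <- function(image, channel) {
  assert_that(channel %in% image$channels,
              paste0("channel '", channel, "' not present; have: ",
                     paste(image$channels, collapse = ", ")))
  image$data[, , match(channel, image$channels)]
}

#' Read / write a multichannel TIFF
#'
#' One page per channel. Channel names travel in a JSON sidecar
#' (`<path>.channels.json`), since baseline TIFF writers in R do not persist
#' per-page descriptions; a `channel_names` argument overrides the sidecar.
#' Integer intensities up to 65535 survive the roundtrip exactly (16-bit
#' pages); other values are written as 32-bit pages with a quantization step
#' of 2^-8 intensity units.
#'
#' @param path TIFF file path.
#' @param channel_names optional character vector naming the pages.
#' @param pixel_size µm per pixel to attach on read (default 1).
#' @param image a [multiplex_image()] to write.
#' @return `read_multichannel_image()` returns a [multiplex_image()];
#'   `write_multichannel_image()` returns `path` invisibly.
#' @export
read_multichannel_image <- function(path, channel_names = NULL, pixel_size = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".channels.json")
  if (is.null(channel_names)) {
    channel_names <- if (file.exists(sidecar)) {
      unlist(jsonlite::read_json(sidecar))
    } else paste0("ch", seq_along(pages))
  }
  if (length(channel_names) != length(pages))
    rlang::abort(paste0("channel count mismatch: file has ", length(pages),
                        " page(s) but ", length(channel_names),
                        " name(s) were supplied"))
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- restore_tiff_scale(p)
  }
  multiplex_image(arr, channel_names, pixel_size)
}

# 32-bit pages hold round(value / 2^24 * (2^32 - 1)); 8/16-bit pages come
# back natively via as.is = TRUE
restore_tiff_scale <- function(p) {
  bps <- attr(p, "bits.per.sample") %||% 16L
  if (bps == 32L) p / (2^32 - 1) * 2^24 else p
}

#' @rdname read_multichannel_image
#' @export
write_multichannel_image <- function(image, path) {
  pages <- lapply(seq_along(image$channels), function(i) {
    m <- image$data[, , i]
    if (all(m == round(m)) && min(m) >= 0 && max(m) <= 65535) {
      structure(m / 65535, bps = 16L)
    } else {
      assert_that(min(m) >= 0 && max(m) < 2^24,
                  "channels must lie in [0, 2^24) for 32-bit storage")
      structure(m / 2^24, bps = 32L)
    }
  })
  bps <- vapply(pages, attr, integer(1), "bps")
  assert_that(length(unique(bps)) == 1,
              "all channels must share a storage depth; mix of integer-range and float channels")
  pages <- lapply(pages, function(p) { attributes(p) <- list(dim = dim(p)); p })
  tiff::writeTIFF(pages, path, bits.per.sample = bps[1])
  jsonlite::write_json(image$channels, paste0(path, ".channels.json"))
  invisible(path)
}

#' Read / write an instance label mask TIFF
#'
#' Labels are non-negative integers, 0 = background.
#'
#' @param mask integer matrix of labels.
#' @param path file path.
#' @return `read_label_mask()` returns an integer matrix;
#'   `write_label_mask()` returns `path` invisibly.
#' @export
write_label_mask <- function(mask, path) {
  assert_that(all(mask >= 0) && all(mask == round(mask)),
              "labels must be non-negative integers")
  if (max(mask) <= 65535) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else {
    assert_that(max(mask) < 2^24, "labels above 2^24 are not supported")
    tiff::writeTIFF(mask / 2^24, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  p <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  m <- round(restore_tiff_scale(p))
  attributes(m) <- list(dim = dim(m))
  storage.mode(m) <- "integer"
  m
}

cell_table_required <- c("cell_id", "x", "y")

#' Read / write a per-cell table CSV
#'
#' The canonical per-cell record: `cell_id`, centroid `x`/`y` in µm, areas,
#' per-marker mean intensities and any annotation columns, which are
#' preserved verbatim. Reading validates the required columns.
#'
#' @param path CSV file path.
#' @param table tibble to write.
#' @return `read_cell_table()` returns a tibble; `write_cell_table()` returns
#'   `path` invisibly.
#' @export
read_cell_table <- function(path) {
  tb <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  miss <- setdiff(cell_table_required, names(tb))
  if (length(miss) > 0)
    rlang::abort(paste0("cell table is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  assert_that(!anyDuplicated(tb$cell_id), "cell ids must be unique")
  tb
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(table, path) {
  miss <- setdiff(cell_table_required, names(table))
  if (length(miss) > 0)
    rlang::abort(paste0("cell table is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
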