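# Immune subanalysis: subtype composition, proliferation, proximity network.

#' Immune marker panel and per-week subclustering resolutions
#'
#' @param markers the immune subclustering markers.
#' @param resolutions named per-week Leiden resolutions; weeks not listed use
#'   `default_resolution`.
#' @param default_resolution fallback resolution (0.2).
#' @return list of class `immune_panel`.
#' @export
immune_panel <- function(markers = c("CD3", "CD4", "CD44", "CD45", "CD56",
                                     "CD68", "CD163", "HLA-DR", "Ki67", "MRC1"),
                         resolutions = c("8.5" = 0.3, "12" = 0.3),
                         default_resolution = 0.2) {
  assert_that(all(resolutions > 0) && default_resolution > 0,
              "resolutions must be > 0")
  structure(list(markers = markers, resolutions = resolutions,
                 default_resolution = default_resolution),
            class = "immune_panel")
}

#' @rdname immune_panel
#' @param week week label.
#' @export
immune_resolution <- function(panel, week) {
  w <- as.character(week)
  if (w %in% names(panel$resolutions)) panel$resolutions[[w]]
  else panel$default_resolution
}

#' Immune subtype summary
#'
#' Subtype percentages per week and the proliferating fraction within each
#' subtype. Weeks without immune cells yield a notice and no rows. Manual
#' gate labels (B / NK), where present in `subtype`, already take precedence
#' over subcluster labels by construction (see [apply_immune_gates()]).
#'
#' @param table cell tibble with `subtype`, `week` and (optionally)
#'   `proliferating` columns; rows are immune cells.
#' @return list of tibbles `composition` and `proliferation`.
#' @export
immune_summary <- function(table) {
  assert_that("subtype" %in% names(table), "need a subtype column")
  tb <- table[!is.na(table$subtype), ]
  if (nrow(tb) == 0) {
    rlang::inform("no immune cells; empty summary")
    return(list(composition = tibble::tibble(), proliferation = tibble::tibble()))
  }
  comp <- composition(tb, type_col = "subtype")
  prol <- NULL
  if ("proliferating" %in% names(tb)) {
    prol <- tb |>
      dplyr::group_by(.data$week, .data$subtype) |>
      dplyr::summarise(n = dplyr::n(),
                       pct_proliferating = 100 * mean(.data$proliferating),
                       .groups = "drop")
  }
  list(composition = comp, proliferation = prol)
}

#' Override subcluster labels with manual B / NK gates
#'
#' Cells satisfying a gate receive the gate label regardless of their
#' subcluster assignment (manual gates take precedence).
#'
#' @param table cell tibble with a `subtype` column.
#' @param gates list of [gate()]s (default: CD19+CD45 B cells, CD56+CD45 NK
#'   cells at the 90th percentile).
#' @return the table with updated `subtype`.
#' @export
apply_immune_gates <- function(table,
                               gates = list(gate("B cell", c("CD19", "CD45")),
                                            gate("NK cell", c("CD56", "CD45")))) {
  g <- gate_cells(table, gates)
  table$subtype <- ifelse(!is.na(g), g, table$subtype)
  table
}

#' Physical-proximity network of immune subtypes
#'
#' Nodes are subtypes (optionally split by proliferation state); edge weight
#' is the observed neighbour-pair frequency normalized by the total immune
#' pair count, so weights over unordered pairs (self-loops included) sum
#' to 1.
#'
#' @param enrichment an [nhood_enrichment()] result computed over immune
#'   cells (its `obs` counts are used).
#' @return tibble edge list with `from`, `to`, `count`, `weight`.
#' @export
build_proximity_network <- function(enrichment) {
  obs <- enrichment$obs
  total <- sum(obs[upper.tri(obs, diag = TRUE)])
  assert_that(total > 0, "empty counts: no immune neighbour pairs")
  idx <- which(upper.tri(obs, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(from = rownames(obs)[idx[, 1]],
                 to = colnames(obs)[idx[, 2]],
                 count = obs[idx],
                 weight = obs[idx] / total) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(dplyr::desc(.data$weight))
}
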