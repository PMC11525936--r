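# Graph-based cell phenotyping: PCA -> kNN graph -> Leiden communities,
# rule-based annotation of cluster mean profiles, manual gates, composition.

#' Cluster cells on normalized marker intensities
#'
#' Principal-component reduction of the marker matrix, exact k-nearest-
#' neighbour graph (Euclidean), and Leiden community detection under the
#' modularity objective at the given resolution. Cluster ids are re-indexed
#' by decreasing size (ties to the lowest contained cell index), so labels
#' are deterministic given the seed.
#'
#' @param table cell tibble with normalized marker columns.
#' @param markers marker columns to cluster on.
#' @param k_neighbors neighbours per cell (default 10).
#' @param resolution Leiden resolution (default 1).
#' @param n_pcs number of principal components (capped at markers - 1).
#' @param seed integer seed for the community detection.
#' @return object of class `cluster_result`: `labels` (integer per cell),
#'   `means` (cluster x marker matrix on the input scale), `params`.
#' @export
cluster_cells <- function(table, markers, k_neighbors = 10, resolution = 1,
                          n_pcs = 20, seed = 0L) {
  X <- as.matrix(table[, markers, drop = FALSE])
  assert_that(!anyNA(X), "marker matrix contains NA")
  assert_that(nrow(X) > k_neighbors,
              paste0("need more than k_neighbors = ", k_neighbors, " cells"))
  cl <- graph_cluster(X, k_neighbors, resolution, n_pcs, seed)
  means <- rowsum(X, cl) / as.vector(table(cl))
  structure(list(labels = cl,
                 means = means,
                 params = list(markers = markers, k_neighbors = k_neighbors,
                               resolution = resolution,
                               n_pcs = min(n_pcs, ncol(X) - 1), seed = seed)),
            class = "cluster_result")
}

# shared machinery, also used for spatial-domain clustering
graph_cluster <- function(X, k_neighbors, resolution, n_pcs, seed) {
  npc <- min(n_pcs, ncol(X))
  if (npc >= 1 && ncol(X) > 1) {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    Y <- pc$x[, seq_len(min(npc, ncol(pc$x))), drop = FALSE]
  } else Y <- X
  nn <- knn_brute_cpp(Y, as.integer(k_neighbors))
  el <- cbind(rep(seq_len(nrow(Y)), times = ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  raw <- igraph::membership(comm)
  # stable re-indexing: by decreasing size, ties to lowest first member
  tab <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.vector(tab), as.vector(first))
  lut <- integer(length(tab))
  lut[as.integer(names(tab))[ord]] <- seq_along(ord)
  as.integer(lut[as.integer(raw)])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$labels), " cells in ",
      nrow(x$means), " clusters (resolution ", x$params$resolution, ")\n", sep = "")
  invisible(x)
}

#' Annotation rulebook
#'
#' Ordered rules mapping cluster mean profiles to cell-type labels. A marker
#' counts as high in a cluster when its z-scored cluster mean is at least
#' `z_high` AND its plain cluster mean is at least `min_mean` (the absolute
#' floor keeps silent markers, whose z-scores are pure noise, from firing);
#' it counts as low when the cluster mean is below `min_mean`. A rule fires
#' when every `high` marker is high, at least one `any` marker is high, and
#' every `low` marker is low. Z-scores are computed across cluster means
#' (dot-plot reading), not across cells. Unmatched clusters are labelled
#' "unassigned".
#'
#' @param rules list of [annotation_rule()]s.
#' @param z_high z-score cut for a high call.
#' @param min_mean absolute expression floor on the clustering scale
#'   (default 1.5 on arcsinh-normalized intensities, i.e. raw intensity of
#'   roughly twice the cofactor).
#' @return list of class `annotation_rulebook`.
#' @export
annotation_rulebook <- function(rules = default_annotation_rules(),
                                z_high = 0.5, min_mean = 1.5) {
  structure(list(rules = rules, z_high = z_high, min_mean = min_mean),
            class = "annotation_rulebook")
}

#' @rdname annotation_rulebook
#' @param label cell-type label the rule assigns.
#' @param high markers that must all be high.
#' @param any markers of which at least one must be high.
#' @param low markers that must all be low.
#' @export
annotation_rule <- function(label, high = character(), any = character(),
                            low = character()) {
  list(label = label, high = high, any = any, low = low)
}

#' @rdname annotation_rulebook
#' @export
default_annotation_rules <- function() {
  list(
    annotation_rule("B cell", high = c("CD19", "CD45")),
    annotation_rule("NK cell", high = c("CD56", "CD45"), low = "CD3"),
    annotation_rule("macrophage", high = c("CD68", "CD45")),
    annotation_rule("ILC & T", high = c("CD3", "CD45")),
    annotation_rule("immune", high = "CD45"),
    annotation_rule("lymphatic endothelial", high = c("PDPN", "CD31")),
    annotation_rule("endothelial", any = c("CD31", "CD144")),
    annotation_rule("SOX2-high epithelial", high = c("EPCAM", "SOX2")),
    annotation_rule("SOX9-high epithelial", high = c("EPCAM", "SOX9")),
    annotation_rule("vascular smooth muscle", high = c("ACTA2", "CD90")),
    annotation_rule("airway smooth muscle", high = "ACTA2"),
    annotation_rule("pericyte", high = "CD90", low = c("VIM", "DCN")),
    annotation_rule("mesenchymal", any = c("VIM", "DCN"))
  )
}

#' Annotate clusters by their mean marker profile
#'
#' @param result a [cluster_result][cluster_cells()].
#' @param rulebook an [annotation_rulebook()].
#' @return tibble with `cluster`, `cell_type` and `evidence` (top-3 markers
#'   by z-scored mean).
#' @export
annotate_clusters <- function(result, rulebook = annotation_rulebook()) {
  means <- result$means
  sds <- apply(means, 2, sd)
  mus <- colMeans(means)
  z <- sweep(sweep(means, 2, mus, "-"), 2, ifelse(sds > 0, sds, 1), "/")
  if (nrow(means) == 1) z[] <- 0
  labels <- character(nrow(means))
  evidence <- character(nrow(means))
  for (k in seq_len(nrow(means))) {
    zk <- z[k, ]; mk_mean <- means[k, ]
    is_high <- zk >= rulebook$z_high & mk_mean >= rulebook$min_mean
    is_low <- mk_mean < rulebook$min_mean
    evidence[k] <- paste(names(sort(zk, decreasing = TRUE))[1:min(3, length(zk))],
                         collapse = ",")
    labels[k] <- "unassigned"
    for (r in rulebook$rules) {
      mk <- c(r$high, r$any, r$low)
      if (!all(mk %in% names(zk))) next
      ok <- all(is_high[r$high]) &&
        (length(r$any) == 0 || any(is_high[r$any])) &&
        all(is_low[r$low])
      if (ok) { labels[k] <- r$label; break }
    }
  }
  tibble::tibble(cluster = seq_len(nrow(means)), cell_type = labels,
                 evidence = evidence)
}

#' Append a `cell_type` annotation column to a cell table
#'
#' Clusters sharing a label are implicitly merged by receiving the same
#' annotation.
#'
#' @param table the clustered cell tibble (same row order as the result).
#' @param result a [cluster_result][cluster_cells()].
#' @param rulebook an [annotation_rulebook()].
#' @return the table with `cluster` and `cell_type` columns.
#' @export
add_annotation <- function(table, result, rulebook = annotation_rulebook()) {
  ann <- annotate_clusters(result, rulebook)
  table$cluster <- result$labels
  table$cell_type <- ann$cell_type[result$labels]
  table
}

#' Subcluster the cells carrying a parent annotation
#'
#' Reruns [cluster_cells()] on the subset at the stated resolution; new
#' labels are namespaced `"<parent>.<k>"`.
#'
#' @param table annotated cell tibble (`cell_type` column).
#' @param parent parent annotation to refine.
#' @param markers markers for the subclustering.
#' @param resolution Leiden resolution for the subset.
#' @param k_neighbors,n_pcs,seed as in [cluster_cells()].
#' @return character vector (length `nrow(table)`): namespaced labels for the
#'   subset, `NA` elsewhere.
#' @export
subcluster <- function(table, parent, markers, resolution = 0.5,
                       k_neighbors = 10, n_pcs = 20, seed = 0L) {
  sel <- which(table$cell_type == parent)
  assert_that(length(sel) > k_neighbors,
              paste0("subset '", parent, "' too small: ", length(sel), " cells"))
  res <- cluster_cells(table[sel, ], markers, k_neighbors = k_neighbors,
                       resolution = resolution, n_pcs = n_pcs, seed = seed)
  out <- rep(NA_character_, nrow(table))
  out[sel] <- paste0(parent, ".", res$labels)
  out
}

#' Marker gates
#'
#' A gate is a conjunction of per-marker thresholds, either percentile-based
#' (computed on the supplied table) or absolute.
#'
#' @param label label assigned to gated cells.
#' @param markers character vector of markers (all must pass).
#' @param percentile percentile threshold(s) in (0, 100); a single value for
#'   all markers or a named vector per marker.
#' @param absolute optional named numeric absolute thresholds overriding the
#'   percentile for those markers.
#' @return list of class `marker_gate`.
#' @export
gate <- function(label, markers, percentile = 90, absolute = NULL) {
  structure(list(label = label, markers = markers, percentile = percentile,
                 absolute = absolute), class = "marker_gate")
}

#' Apply marker gates
#'
#' Cells satisfying every conjunct of a gate receive its label; earlier
#' gates take precedence for cells matching several.
#'
#' @param table cell tibble.
#' @param gates list of [gate()]s.
#' @return character vector of gate labels (`NA` where no gate fires).
#' @export
gate_cells <- function(table, gates) {
  out <- rep(NA_character_, nrow(table))
  for (g in gates) {
    miss <- setdiff(g$markers, names(table))
    if (length(miss) > 0)
      rlang::abort(paste0("gate '", g$label, "' references unknown marker(s): ",
                          paste(miss, collapse = ", ")))
    pass <- rep(TRUE, nrow(table))
    for (m in g$markers) {
      pctl <- if (!is.null(names(g$percentile))) g$percentile[[m]]
              else g$percentile
      thr <- if (!is.null(g$absolute) && m %in% names(g$absolute)) g$absolute[[m]]
             else quantile(table[[m]], pctl / 100, names = FALSE)
      pass <- pass & table[[m]] > thr
    }
    out[pass & is.na(out)] <- g$label
  }
  out
}

#' Cell-type composition per week
#'
#' @param table annotated cell tibble (`cell_type`, `week`).
#' @param type_col,by column names for type and grouping.
#' @return tibble with `week`, `cell_type`, `n`, `pct` (sums to 100 per week).
#' @export
composition <- function(table, type_col = "cell_type", by = "week") {
  assert_that(type_col %in% names(table), paste0("missing column ", type_col))
  tb <- table[!is.na(table[[type_col]]), ]
  assert_that(nrow(tb) > 0, "no annotated cells")
  tb |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, type_col)))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Pearson correlation between marker expression patterns
#'
#' @param table cell tibble.
#' @param markers marker columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
marker_correlation <- function(table, markers) {
  cor(as.matrix(table[, markers, drop = FALSE]), method = "pearson")
}
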