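# Spatial-domain inference from neighbour-augmented expression (λ-mixing).

#' Neighbour-augmented feature matrix
#'
#' Concatenates each cell's own expression block, weighted `sqrt(1 - lambda)`,
#' with the mean expression of its spatial neighbours, weighted
#' `sqrt(lambda)`, so that the squared feature norm decomposes as
#' `(1 - lambda) * |x|^2 + lambda * |neighbour mean|^2`. Neighbours come from
#' an exact k-nearest-neighbour query on the centroids (default k = 18) or
#' from a supplied fixed-radius [build_neighbor_graph()]. Isolated cells use
#' their own profile as the neighbour mean and are flagged.
#'
#' @param table cell tibble with `x`, `y` and marker columns.
#' @param markers marker columns.
#' @param lambda spatial mixing weight in \[0, 1\].
#' @param k number of spatial nearest neighbours (ignored when `graph` given).
#' @param graph optional [build_neighbor_graph()] result.
#' @return numeric matrix with `2 * length(markers)` columns; attribute
#'   `isolated` marks cells without neighbours.
#' @export
neighbor_augmented_features <- function(table, markers, lambda = 0.8, k = 18,
                                        graph = NULL) {
  assert_that(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  X <- as.matrix(table[, markers, drop = FALSE])
  n <- nrow(X)
  nb_mean <- X
  isolated <- rep(FALSE, n)
  if (is.null(graph)) {
    assert_that(n > k, "need more cells than k")
    nn <- knn_brute_cpp(cbind(table$x, table$y), as.integer(k))
    for (j in seq_len(ncol(X)))
      nb_mean[, j] <- rowMeans(matrix(X[nn, j], nrow = n))
  } else {
    deg <- numeric(n); acc <- matrix(0, n, ncol(X))
    ei <- graph$edges$from_idx; ej <- graph$edges$to_idx
    for (j in seq_len(ncol(X))) {
      s <- rep(0, n)
      s_add <- tapply(c(X[ej, j], X[ei, j]), c(ei, ej), sum)
      s[as.integer(names(s_add))] <- s_add
      acc[, j] <- s
    }
    d_add <- tapply(rep(1, 2 * length(ei)), c(ei, ej), sum)
    deg[as.integer(names(d_add))] <- d_add
    isolated <- deg == 0
    nb_mean[!isolated, ] <- acc[!isolated, , drop = FALSE] / deg[!isolated]
  }
  out <- cbind(sqrt(1 - lambda) * X, sqrt(lambda) * nb_mean)
  colnames(out) <- c(markers, paste0("nbr_", markers))
  attr(out, "isolated") <- isolated
  out
}

#' Cluster cells into spatial domains
#'
#' Applies the same PCA/kNN-graph/Leiden machinery as [cluster_cells()] to
#' the neighbour-augmented features. At `lambda = 0` this reduces exactly to
#' expression-only clustering (the neighbour block is zeroed).
#'
#' @inheritParams neighbor_augmented_features
#' @param resolution Leiden resolution for the domain partition.
#' @param k_expr neighbours of the expression-graph used for community
#'   detection.
#' @param n_pcs principal components retained.
#' @param seed integer seed.
#' @return object of class `domain_assignment`: `labels` (integer domain per
#'   cell), `lambda`, `params`, and `composition` (per-domain cell-type
#'   percentages when `table` carries `cell_type`).
#' @export
cluster_domains <- function(table, markers, lambda = 0.8, k = 18,
                            resolution = 0.3, k_expr = 10, n_pcs = 20,
                            seed = 0L, graph = NULL) {
  feats <- neighbor_augmented_features(table, markers, lambda, k, graph)
  labels <- graph_cluster(feats, k_expr, resolution, n_pcs, seed)
  comp <- NULL
  if ("cell_type" %in% names(table)) {
    comp <- tibble::tibble(domain = labels, cell_type = table$cell_type) |>
      dplyr::count(.data$domain, .data$cell_type) |>
      dplyr::group_by(.data$domain) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  structure(list(labels = labels, lambda = lambda,
                 params = list(markers = markers, k = k, k_expr = k_expr,
                               resolution = resolution, n_pcs = n_pcs,
                               seed = seed),
                 composition = comp),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("<domain_assignment> ", length(x$labels), " cells in ",
      length(unique(x$labels)), " domains (lambda ", x$lambda, ")\n", sep = "")
  invisible(x)
}

#' Domain composition tables and cross-week similarity
#'
#' Builds per-domain cell-type composition vectors over the shared type
#' vocabulary (absent types filled with 0), the all-pairs Pearson correlation
#' between domain compositions across weeks, and the Ward linkage order of
#' the correlation structure.
#'
#' @param tables named list (week -> annotated cell tibble with `domain` and
#'   `cell_type` columns).
#' @return list with `composition` (tibble: `week`, `domain`, `cell_type`,
#'   `pct`), `correlation` (matrix over week:domain), `order` (Ward linkage
#'   leaf order), `hclust`.
#' @export
domain_composition_and_similarity <- function(tables) {
  comp <- purrr::imap(tables, function(tb, wk) {
    tb |>
      dplyr::filter(!is.na(.data$domain)) |>
      dplyr::count(.data$domain, .data$cell_type) |>
      dplyr::group_by(.data$domain) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(week = wk)
  }) |> dplyr::bind_rows()
  if (nrow(comp) == 0) rlang::abort("no domains to compare")
  types <- sort(unique(comp$cell_type))
  wide <- comp |>
    dplyr::mutate(key = paste0(.data$week, ":", .data$domain)) |>
    dplyr::select("key", "cell_type", "pct") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "pct",
                       values_fill = 0) |>
    tibble::column_to_rownames("key")
  wide <- as.matrix(wide[, types, drop = FALSE])
  cc <- cor(t(wide))
  hc <- hclust(as.dist(1 - cc), method = "ward.D2")
  list(composition = comp, correlation = cc, order = rownames(cc)[hc$order],
       hclust = hc)
}
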