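# Fixed-radius spatial neighbour graph and permutation neighbourhood
# enrichment.

#' Build the fixed-radius spatial neighbour graph
#'
#' Undirected edge between two cells iff their centroid distance is at most
#' `radius` (physical µm). Uses uniform-grid bucketing; the edge set equals
#' the brute-force O(n²) result exactly.
#'
#' @param table cell tibble with `cell_id`, `x`, `y` (µm).
#' @param radius neighbourhood radius in µm (default 50).
#' @return object of class `neighbor_graph`: `edges` tibble (`from`, `to`,
#'   `dist`, plus row indices `from_idx`, `to_idx`), `ids`, `radius`.
#' @export
build_neighbor_graph <- function(table, radius = 50) {
  assert_that(radius >= 0, "radius must be non-negative")
  n <- nrow(table)
  x <- table$x; y <- table$y
  ids <- table$cell_id %||% seq_len(n)
  if (radius == 0 || n < 2) {
    edges <- tibble::tibble(from = ids[0], to = ids[0], dist = numeric(0),
                            from_idx = integer(0), to_idx = integer(0))
    return(structure(list(edges = edges, ids = ids, radius = radius),
                     class = "neighbor_graph"))
  }
  bx <- floor(x / radius); by <- floor(y / radius)
  key <- function(a, b) paste(a, b)
  pts <- tibble::tibble(idx = seq_len(n), x = x, y = y, bx = bx, by = by)
  pairs <- list()
  for (dx in -1:1) for (dy in -1:1) {
    a <- pts
    b <- dplyr::mutate(pts, bx = .data$bx - dx, by = .data$by - dy)
    m <- dplyr::inner_join(a, b, by = c("bx", "by"),
                           suffix = c("_i", "_j"), relationship = "many-to-many")
    m <- m[m$idx_i < m$idx_j, ]
    if (nrow(m) > 0) pairs[[length(pairs) + 1]] <- m
  }
  if (length(pairs) == 0) {
    cand <- tibble::tibble(idx_i = integer(0), idx_j = integer(0),
                           x_i = numeric(0), y_i = numeric(0),
                           x_j = numeric(0), y_j = numeric(0))
  } else cand <- dplyr::bind_rows(pairs)
  d <- sqrt((cand$x_i - cand$x_j)^2 + (cand$y_i - cand$y_j)^2)
  keep <- d <= radius
  edges <- tibble::tibble(from = ids[cand$idx_i[keep]],
                          to = ids[cand$idx_j[keep]],
                          dist = d[keep],
                          from_idx = cand$idx_i[keep],
                          to_idx = cand$idx_j[keep])
  edges <- dplyr::arrange(edges, .data$from_idx, .data$to_idx)
  structure(list(edges = edges, ids = ids, radius = radius),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", length(x$ids), " cells, ", nrow(x$edges),
      " edges at radius ", x$radius, " µm\n", sep = "")
  invisible(x)
}

pair_index <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo + hi * (hi - 1) / 2
}

#' Permutation neighbourhood enrichment
#'
#' Observed counts of unordered label pairs over the graph's edges are
#' compared with a null obtained by permuting labels over nodes (graph held
#' fixed): `Z(a, b) = (obs - mean_perm) / sd_perm`. Pairs whose permutation
#' counts never vary get `Z = 0` and a degenerate flag. The homotypic
#' diagonal counts pairs, not cells, and each unordered pair is counted once,
#' so the counts over all pairs sum to the edge count.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param labels character/factor vector of node labels, aligned with
#'   `graph$ids`.
#' @param n_perms number of label permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `enrichment_matrix` with `z`, `obs`, `perm_mean`,
#'   `perm_sd`, `degenerate` (L x L matrices), `labels`, `n_perms`, `seed`,
#'   `radius`.
#' @export
nhood_enrichment <- function(graph, labels, n_perms = 1000, seed = 0L) {
  assert_that(n_perms >= 1, "n_perms must be >= 1")
  assert_that(length(labels) == length(graph$ids),
              "labels must align with graph nodes")
  assert_that(!anyNA(labels), "every node must be labelled")
  f <- factor(labels)
  lev <- levels(f)
  L <- length(lev)
  li <- as.integer(f)
  ei <- graph$edges$from_idx; ej <- graph$edges$to_idx
  obs_v <- pair_counts_cpp(ei, ej, matrix(li, ncol = 1), L)[, 1]
  set.seed(seed)
  perms <- vapply(seq_len(n_perms), function(i) sample(li), integer(length(li)))
  cnts <- pair_counts_cpp(ei, ej, perms, L)
  pm <- rowMeans(cnts)
  psd <- apply(cnts, 1, sd)
  zv <- ifelse(psd > 0, (obs_v - pm) / psd, 0)
  expand <- function(v) {
    m <- matrix(0, L, L, dimnames = list(lev, lev))
    k <- 0
    for (b in seq_len(L)) for (a in seq_len(b)) {
      k <- k + 1
      m[a, b] <- v[k]; m[b, a] <- v[k]
    }
    m
  }
  structure(list(z = expand(zv), obs = expand(obs_v),
                 perm_mean = expand(pm), perm_sd = expand(psd),
                 degenerate = expand(as.numeric(psd == 0)) > 0,
                 labels = lev, n_perms = n_perms, seed = seed,
                 radius = graph$radius),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix> ", length(x$labels), " labels, ", x$n_perms,
      " permutations, radius ", x$radius, " µm\n", sep = "")
  print(round(x$z, 2))
  invisible(x)
}

#' Column-wise scaling of an enrichment Z matrix
#'
#' Centres each column and scales it to unit sample variance (n - 1
#' denominator). Zero-variance columns are set to 0 and flagged in the
#' `zero_variance` attribute.
#'
#' @param z numeric matrix (>= 2 rows).
#' @return scaled matrix.
#' @export
scale_enrichment <- function(z) {
  assert_that(nrow(z) >= 2, "need at least 2 rows to scale")
  mu <- colMeans(z)
  s <- apply(z, 2, sd)
  out <- sweep(sweep(z, 2, mu, "-"), 2, ifelse(s > 0, s, 1), "/")
  out[, s == 0] <- 0
  attr(out, "zero_variance") <- colnames(z)[s == 0] %||% which(s == 0)
  out
}

#' Cross-week series of scaled enrichment values
#'
#' Each week's Z matrix is scaled first; the common labels are subset
#' afterwards (scale per week, then subset).
#'
#' @param z_by_week named list of Z matrices (names = weeks, in temporal
#'   order), each with dimnames.
#' @param common_labels labels present in every week.
#' @return tibble with `focal`, `other`, `week`, `scaled_z`.
#' @export
temporal_series <- function(z_by_week, common_labels) {
  assert_that(length(z_by_week) >= 1, "need at least one week")
  rows <- purrr::imap(z_by_week, function(z, wk) {
    miss <- setdiff(common_labels, rownames(z))
    if (length(miss) > 0)
      rlang::abort(paste0("week ", wk, " is missing label(s): ",
                          paste(miss, collapse = ", ")))
    sz <- scale_enrichment(z)[common_labels, common_labels, drop = FALSE]
    tidyr::expand_grid(focal = common_labels, other = common_labels) |>
      dplyr::mutate(week = wk, scaled_z = as.vector(t(sz)))
  })
  out <- dplyr::bind_rows(rows)
  out$week <- factor(out$week, levels = names(z_by_week))
  out
}
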