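# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn cluster_cells long tibble of cluster mean profiles.
#' @param x a `cluster_result`.
#' @param ... unused.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(x$means, rownames = "cluster") |>
    dplyr::mutate(cluster = as.integer(.data$cluster)) |>
    tidyr::pivot_longer(-"cluster", names_to = "marker", values_to = "mean")
}

#' @describeIn cluster_cells one-row summary (cells, clusters, parameters).
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_cells = length(x$labels), n_clusters = nrow(x$means),
                 k_neighbors = x$params$k_neighbors,
                 resolution = x$params$resolution, n_pcs = x$params$n_pcs,
                 seed = x$params$seed)
}

#' @describeIn nhood_enrichment long tibble of unordered label pairs with
#'   observed counts, permutation mean/sd and Z.
#' @param x an `enrichment_matrix`.
#' @param ... unused.
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$z, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(label_a = x$labels[idx[, 1]], label_b = x$labels[idx[, 2]],
                 obs = x$obs[idx], perm_mean = x$perm_mean[idx],
                 perm_sd = x$perm_sd[idx], z = x$z[idx],
                 degenerate = x$degenerate[idx])
}

#' @describeIn nhood_enrichment one-row summary.
#' @export
glance.enrichment_matrix <- function(x, ...) {
  tibble::tibble(n_labels = length(x$labels), n_perms = x$n_perms,
                 radius = x$radius, seed = x$seed,
                 total_pairs = sum(x$obs[upper.tri(x$obs, diag = TRUE)]))
}

#' @describeIn cluster_domains per-domain composition (when available).
#' @param x a `domain_assignment`.
#' @param ... unused.
#' @export
tidy.domain_assignment <- function(x, ...) {
  if (is.null(x$composition))
    return(tibble::tibble(domain = sort(unique(x$labels))))
  x$composition
}

#' @describeIn cluster_domains one-row summary.
#' @export
glance.domain_assignment <- function(x, ...) {
  tibble::tibble(n_cells = length(x$labels),
                 n_domains = length(unique(x$labels)), lambda = x$lambda,
                 resolution = x$params$resolution, seed = x$params$seed)
}
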