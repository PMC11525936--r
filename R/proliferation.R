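# Ki67 percentile proliferation classification and its comparisons.

#' Per-week Ki67 percentile specification
#'
#' The default carries the study's per-week percentiles: 70 for weeks 6 and
#' 8.5, 85 for weeks 11 and 12, 86 for week 13.
#'
#' @param percentiles named numeric vector (names = weeks, values in (0, 100)).
#' @return named numeric vector of class `proliferation_spec`.
#' @export
proliferation_spec <- function(percentiles = c("6" = 70, "8.5" = 70,
                                               "11" = 85, "12" = 85,
                                               "13" = 86)) {
  assert_that(all(percentiles > 0 & percentiles < 100),
              "percentiles must lie in (0, 100)")
  structure(percentiles, class = "proliferation_spec")
}

#' Classify proliferating cells by per-week Ki67 percentile
#'
#' A cell is proliferating iff its (background-subtracted) Ki67 intensity is
#' strictly above the week's percentile of Ki67 within that week's cells.
#' Percentiles use linear interpolation between order statistics; the strict
#' inequality means an all-equal week yields no proliferating cells.
#'
#' @param table cell tibble with `Ki67` and `week` columns.
#' @param spec a [proliferation_spec()].
#' @param ki67_col Ki67 column name.
#' @return the table with a logical `proliferating` column.
#' @export
classify_proliferating <- function(table, spec = proliferation_spec(),
                                   ki67_col = "Ki67") {
  assert_that(ki67_col %in% names(table), "Ki67 column missing")
  wk <- as.character(table$week)
  miss <- setdiff(unique(wk), names(spec))
  if (length(miss) > 0)
    rlang::abort(paste0("no Ki67 percentile configured for week(s): ",
                        paste(miss, collapse = ", ")))
  out <- logical(nrow(table))
  for (w in unique(wk)) {
    sel <- wk == w
    thr <- quantile(table[[ki67_col]][sel], spec[[w]] / 100, names = FALSE,
                    type = 7)
    out[sel] <- table[[ki67_col]][sel] > thr
  }
  table$proliferating <- out
  table
}

#' Proliferation summaries
#'
#' Three views per week: overall proliferating fraction; fraction within each
#' cell type; and how proliferating cells distribute across types (sums to
#' 100%). Types with no cells in a week are absent from that week's rows.
#'
#' @param table cell tibble with `proliferating`, `cell_type`, `week`.
#' @return list of tibbles `overall`, `per_type`, `distribution`.
#' @export
proliferation_summary <- function(table) {
  assert_that(all(c("proliferating", "week") %in% names(table)),
              "need proliferating and week columns")
  overall <- table |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(n = dplyr::n(),
                     n_proliferating = sum(.data$proliferating),
                     pct = 100 * mean(.data$proliferating), .groups = "drop")
  per_type <- NULL; distribution <- NULL
  if ("cell_type" %in% names(table)) {
    per_type <- table |>
      dplyr::group_by(.data$week, .data$cell_type) |>
      dplyr::summarise(n = dplyr::n(),
                       pct = 100 * mean(.data$proliferating), .groups = "drop")
    distribution <- table |>
      dplyr::filter(.data$proliferating) |>
      dplyr::count(.data$week, .data$cell_type) |>
      dplyr::group_by(.data$week) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  list(overall = overall, per_type = per_type, distribution = distribution)
}

# Student (equal-variance) two-sample t with the degenerate convention:
# zero pooled variance gives t = 0 / p = 1 when the means agree and
# t = +-Inf / p = 0 when they differ.
student_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- mean(a) - mean(b)
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  tt <- d / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Compare homotypic adjacency of proliferating vs non-proliferating cells
#'
#' Input: per-week enrichment Z matrices whose labels are
#' `"<type>|proliferating"` / `"<type>|non-proliferating"` (see
#' [proliferation_state_labels()]). Each week's matrix is scaled
#' column-wise; the homotypic diagonal values are collected across weeks and
#' compared per type with a two-sided equal-variance Student t-test, and the
#' week-wise ratio non-proliferating / proliferating is reported (ratios with
#' near-zero denominator are `NA`).
#'
#' @param z_by_week named list (week -> Z matrix with dimnames).
#' @param eps denominator guard for the ratio series.
#' @return list with `tests` (tibble: `cell_type`, `t`, `df`, `p`) and
#'   `ratios` (tibble: `cell_type`, `week`, `ratio`).
#' @export
compare_homotypic_adjacency <- function(z_by_week, eps = 1e-8) {
  diag_tb <- purrr::imap(z_by_week, function(z, wk) {
    sz <- scale_enrichment(z)
    tibble::tibble(label = rownames(sz), value = diag(sz), week = wk)
  }) |> dplyr::bind_rows()
  parts <- strsplit(diag_tb$label, "|", fixed = TRUE)
  diag_tb$cell_type <- vapply(parts, `[`, character(1), 1)
  diag_tb$state <- vapply(parts, function(p) p[2] %||% NA_character_, character(1))
  diag_tb <- diag_tb[!is.na(diag_tb$state), ]
  tests <- diag_tb |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$state == "non-proliferating"]
      b <- d$value[d$state == "proliferating"]
      if (length(a) < 2 || length(b) < 2) {
        rlang::inform(paste0("fewer than 2 observations per state for '",
                             key$cell_type, "'; t-test is NA"))
        return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_))
      }
      tibble::as_tibble(student_t2(a, b))
    }) |>
    dplyr::ungroup()
  ratios <- diag_tb |>
    dplyr::select(-"label") |>
    tidyr::pivot_wider(names_from = "state", values_from = "value") |>
    dplyr::mutate(ratio = ifelse(abs(.data$proliferating) < eps, NA_real_,
                                 .data$`non-proliferating` / .data$proliferating)) |>
    dplyr::select("cell_type", "week", "ratio")
  list(tests = tests, ratios = ratios)
}

#' Combined type-and-proliferation-state labels
#'
#' @param table cell tibble with `cell_type` and `proliferating`.
#' @return character vector `"<type>|proliferating"` /
#'   `"<type>|non-proliferating"`.
#' @export
proliferation_state_labels <- function(table) {
  paste0(table$cell_type, "|",
         ifelse(table$proliferating, "proliferating", "non-proliferating"))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the point-probability rule: the
#' p-value sums the probabilities of all tables with the observed margins
#' whose point probability does not exceed the observed one (within a
#' relative tolerance of 1e-7 for ties).
#'
#' @param a,b,c,d cell counts, rows = condition, columns = group.
#' @return list with `p` and `odds_ratio` (sample odds ratio `ad/bc`).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  assert_that(all(c(a, b, c, d) >= 0) && all(c(a, b, c, d) == round(c(a, b, c, d))),
              "counts must be non-negative integers")
  m <- a + b; n <- c + d; k <- a + c
  assert_that(m + n > 0, "empty table")
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), odds_ratio = (a * d) / (b * c))
}

#' Pairwise Fisher tests of proliferation between airway region groups
#'
#' Cells are grouped by the airway-region polygons containing their
#' centroid (roles `airway-small-SOX2`, `airway-large-SOX2`, `airway-SOX9`);
#' for each pair of groups a two-sided Fisher's exact test compares
#' proliferating vs non-proliferating counts.
#'
#' @param table cell tibble with `x`, `y`, `proliferating`.
#' @param regions a [region_set()] carrying airway roles.
#' @return tibble with `group_a`, `group_b`, the four counts, `odds_ratio`,
#'   `p`.
#' @export
region_proliferation_fisher <- function(table, regions) {
  roles <- c("airway-small-SOX2", "airway-large-SOX2", "airway-SOX9")
  reg <- regions[regions$role %in% roles, ]
  assert_that(nrow(reg) > 0, "no airway regions supplied")
  groups <- unique(reg$role)
  counts <- purrr::map(setNames(groups, groups), function(g) {
    polys <- reg$coords[reg$role == g]
    inside <- rep(FALSE, nrow(table))
    for (p in polys) inside <- inside | point_in_polygon(table$x, table$y, p)
    if (!any(inside)) rlang::abort(paste0("region group '", g, "' contains no cells"))
    c(pos = sum(table$proliferating[inside]),
      neg = sum(!table$proliferating[inside]))
  })
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    ca <- counts[[pr[1]]]; cb <- counts[[pr[2]]]
    ft <- fisher_exact_2x2(ca["pos"], ca["neg"], cb["pos"], cb["neg"])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   a_pos = ca["pos"], a_neg = ca["neg"],
                   b_pos = cb["pos"], b_neg = cb["neg"],
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
}
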