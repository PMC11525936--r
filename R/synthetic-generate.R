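# Ground-truth generation: cell placement, structures, domains, tags.

ring_offsets <- list(airway_asm = 8, vessel_vsm = 6, vessel_immune = 22)

# sequential placement with a uniform occupancy grid; min centre distance
# between two cells is factor * max of their nucleus radii
new_placer <- function(field, factor, r_max) {
  cell <- if (factor > 0) factor * r_max else max(field)
  nx <- max(1L, ceiling(field[1] / cell))
  ny <- max(1L, ceiling(field[2] / cell))
  env <- new.env(parent = emptyenv())
  env$x <- numeric(0); env$y <- numeric(0); env$r <- numeric(0)
  env$grid <- vector("list", nx * ny)
  env$cell <- cell; env$nx <- nx; env$ny <- ny; env$factor <- factor
  env
}

placer_key <- function(env, x, y) {
  gx <- pmin(pmax(floor(x / env$cell), 0), env$nx - 1)
  gy <- pmin(pmax(floor(y / env$cell), 0), env$ny - 1)
  gx + gy * env$nx + 1
}

placer_ok <- function(env, x, y, r) {
  if (env$factor == 0) return(TRUE)
  gx <- floor(x / env$cell); gy <- floor(y / env$cell)
  for (dx in -1:1) for (dy in -1:1) {
    cx <- gx + dx; cy <- gy + dy
    if (cx < 0 || cx >= env$nx || cy < 0 || cy >= env$ny) next
    idx <- env$grid[[cx + cy * env$nx + 1]]
    if (is.null(idx)) next
    d2 <- (env$x[idx] - x)^2 + (env$y[idx] - y)^2
    lim <- env$factor * pmax(env$r[idx], r)
    if (any(d2 < lim^2)) return(FALSE)
  }
  TRUE
}

placer_add <- function(env, x, y, r) {
  i <- length(env$x) + 1L
  env$x[i] <- x; env$y[i] <- y; env$r[i] <- r
  if (env$factor > 0) {
    k <- placer_key(env, x, y)
    env$grid[[k]] <- c(env$grid[[k]], i)
  }
  invisible(i)
}

auto_ring_n <- function(radius, nucleus_r) max(3L, floor(2 * pi * radius / (2.2 * nucleus_r)))

ring_points <- function(cx, cy, radius, n, jitter_sd = 0.4) {
  th <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rr <- radius + rnorm(n, 0, jitter_sd)
  list(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

type_radius <- function(cfg, type) {
  ct <- cfg$cell_types
  r <- ct$nucleus_radius[match(type, ct$type)]
  extra <- c(SOX2_epithelial = 4.5, SOX9_epithelial = 4.5, endothelial = 4.0,
             airway_smooth_muscle = 4.0, vascular_smooth_muscle = 4.0,
             pericyte = 3.8, macrophage = 3.5, ILC_T = 3.5)
  ifelse(is.na(r), unname(extra[type]), r)
}

domain_of <- function(cfg, x, y) {
  if (is.null(cfg$domains)) return(rep("tissue", length(x)))
  dom <- rep("tissue", length(x))
  d <- cfg$domains
  for (i in rev(seq_len(nrow(d)))) {
    hit <- x >= d$xmin[i] & x <= d$xmax[i] & y >= d$ymin[i] & y <= d$ymax[i]
    dom[hit] <- d$domain[i]
  }
  dom
}

sample_type_for_domain <- function(cfg, dom) {
  d <- cfg$domains
  i <- match(dom, d$domain)
  if (is.na(i)) {
    ct <- cfg$cell_types
    p <- ct$frac / sum(ct$frac)
    return(sample(ct$type, 1, prob = p))
  }
  mix <- d$mixture[[i]]
  sample(names(mix), 1, prob = mix)
}

#' Generate ground-truthed synthetic tissue
#'
#' Places structure cells (airway rings, distal tips, vessel rings with their
#' immune collar) deterministically on their configured geometry, then fills
#' the remaining field with free cells by rejection sampling under the
#' configured minimum spacing. Every cell receives a type, a proliferation
#' flag (Bernoulli at its type's rate), a domain label derived from the
#' configured domain bands, and a structure tag.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed fixing all randomness (defaults to the config's).
#' @return A list of class `synthetic_ground_truth` with elements `cells`
#'   (tibble: `id`, `type`, `x`, `y`, `nucleus_radius`, `proliferating`,
#'   `domain`, `tag`, `structure_id`), `structures` (tibble registry) and
#'   `config`.
#' @export
generate_ground_truth <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  set.seed(seed)
  cfg <- config
  field <- cfg$field_um
  ct <- cfg$cell_types
  r_max <- max(c(ct$nucleus_radius, 4.5))
  placer <- new_placer(field, cfg$min_spacing_factor, r_max)

  rows <- list()
  structures <- list()
  add_cells <- function(type, x, y, tag, sid) {
    r <- type_radius(cfg, type)[1]
    for (i in seq_along(x)) placer_add(placer, x[i], y[i], r)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      type = type, x = x, y = y, nucleus_radius = r, tag = tag, structure_id = sid)
  }

  check_ring_feasible <- function(what, radius, n, nuc_r) {
    if (n < 1) return(invisible())
    chord <- 2 * radius * sin(pi / max(n, 1))
    if (n > 1 && chord < 1.6 * nuc_r)
      rlang::abort(paste0("infeasible packing: ", what, " ring of ", n,
                          " cells does not fit on radius ", radius, " µm"))
  }

  # -- airways: SOX2-high epithelial ring on the lumen, ASM ring outside
  if (!is.null(cfg$airways)) {
    for (i in seq_len(nrow(cfg$airways))) {
      a <- cfg$airways[i, ]
      n_epi <- if (is.na(a$n_epi)) auto_ring_n(a$lumen_r, 4.5) else a$n_epi
      n_asm <- if (is.na(a$n_asm)) auto_ring_n(a$lumen_r + ring_offsets$airway_asm, 4) else a$n_asm
      check_ring_feasible(sprintf("airway %d epithelial", i), a$lumen_r, n_epi, 4.5)
      sid <- paste0("airway_", i)
      p <- ring_points(a$cx, a$cy, a$lumen_r, n_epi)
      add_cells("SOX2_epithelial", p$x, p$y, "airway-epithelial", sid)
      p <- ring_points(a$cx, a$cy, a$lumen_r + ring_offsets$airway_asm, n_asm)
      add_cells("airway_smooth_muscle", p$x, p$y, "airway-asm", sid)
      structures[[length(structures) + 1]] <- tibble::tibble(
        structure_id = sid, kind = "airway", cx = a$cx, cy = a$cy,
        r_inner = a$lumen_r, r_outer = a$lumen_r + ring_offsets$airway_asm + 4)
    }
  }

  # -- distal tips: SOX9-high epithelial disks
  if (!is.null(cfg$tips)) {
    for (i in seq_len(nrow(cfg$tips))) {
      tp <- cfg$tips[i, ]
      n <- if (is.na(tp$n)) max(3L, floor(pi * tp$r^2 / (2.2 * 4.5)^2)) else tp$n
      sid <- paste0("tip_", i)
      placed <- 0; attempts <- 0
      xs <- ys <- numeric(0)
      while (placed < n && attempts < 200 * n) {
        attempts <- attempts + 1
        rr <- tp$r * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
        x <- tp$cx + rr * cos(th); y <- tp$cy + rr * sin(th)
        if (placer_ok(placer, x, y, 4.5)) {
          placer_add(placer, x, y, 4.5)
          xs <- c(xs, x); ys <- c(ys, y); placed <- placed + 1
        }
      }
      if (placed < n)
        rlang::abort(paste0("infeasible packing: tip ", i, " requested ", n,
                            " cells, placed ", placed))
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = "SOX9_epithelial", x = xs, y = ys, nucleus_radius = 4.5,
        tag = "tip", structure_id = sid)
      structures[[length(structures) + 1]] <- tibble::tibble(
        structure_id = sid, kind = "tip", cx = tp$cx, cy = tp$cy,
        r_inner = 0, r_outer = tp$r)
    }
  }

  # -- vessels: endothelial ring, VSM ring, immune collar with marker shifts
  if (!is.null(cfg$vessels)) {
    for (i in seq_len(nrow(cfg$vessels))) {
      v <- cfg$vessels[i, ]
      n_endo <- if (is.na(v$n_endo)) auto_ring_n(v$r, 4) else v$n_endo
      n_vsm <- if (is.na(v$n_vsm)) auto_ring_n(v$r + ring_offsets$vessel_vsm, 4) else v$n_vsm
      n_slots <- if (is.na(v$n_slots)) auto_ring_n(v$r + ring_offsets$vessel_immune, 3.5) else v$n_slots
      check_ring_feasible(sprintf("vessel %d endothelial", i), v$r, n_endo, 4)
      sid <- paste0("vessel_", i)
      p <- ring_points(v$cx, v$cy, v$r, n_endo)
      add_cells("endothelial", p$x, p$y, "vessel-endothelial", sid)
      p <- ring_points(v$cx, v$cy, v$r + ring_offsets$vessel_vsm, n_vsm)
      add_cells("vascular_smooth_muscle", p$x, p$y, "vessel-vsm", sid)
      p <- ring_points(v$cx, v$cy, v$r + ring_offsets$vessel_immune, n_slots)
      occupied <- runif(n_slots) < v$occupancy
      if (any(occupied)) {
        imm_types <- sample(c("macrophage", "ILC_T"), sum(occupied),
                            replace = TRUE, prob = c(0.7, 0.3))
        rows[[length(rows) + 1]] <- tibble::tibble(
          type = imm_types, x = p$x[occupied], y = p$y[occupied],
          nucleus_radius = 3.5, tag = "artery-close", structure_id = sid)
        for (j in which(occupied)) placer_add(placer, p$x[j], p$y[j], 3.5)
      }
      structures[[length(structures) + 1]] <- tibble::tibble(
        structure_id = sid, kind = "vessel", cx = v$cx, cy = v$cy,
        r_inner = v$r, r_outer = v$r + ring_offsets$vessel_vsm + 4)
    }
  }

  # -- free field cells
  exact <- "n" %in% names(ct) && !anyNA(ct$n)
  n_free <- if (exact) sum(ct$n) else cfg$n_cells
  keepout <- dplyr::bind_rows(structures)
  in_keepout <- function(x, y) {
    if (is.null(keepout) || nrow(keepout) == 0) return(FALSE)
    any((x - keepout$cx)^2 + (y - keepout$cy)^2 < (keepout$r_outer + 6)^2)
  }
  type_pool <- if (exact) sample(rep(ct$type, times = ct$n)) else NULL
  placed <- 0; attempts <- 0
  fx <- fy <- numeric(n_free); ftype <- character(n_free)
  while (placed < n_free && attempts < 200 * n_free) {
    attempts <- attempts + 1
    x <- runif(1, 0, field[1]); y <- runif(1, 0, field[2])
    if (in_keepout(x, y)) next
    type <- if (exact) type_pool[placed + 1] else
      sample_type_for_domain(cfg, domain_of(cfg, x, y))
    # spacing uses the panel-wide maximum radius so that acceptance does not
    # depend on the sampled type (keeps realized fractions unbiased)
    if (!placer_ok(placer, x, y, r_max)) next
    placer_add(placer, x, y, r_max)
    placed <- placed + 1
    fx[placed] <- x; fy[placed] <- y; ftype[placed] <- type
  }
  if (placed < n_free)
    rlang::abort(paste0("infeasible packing: free field requested ", n_free,
                        " cells, placed ", placed,
                        " (density exceeds capacity at the configured spacing)"))
  if (n_free > 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = ftype, x = fx, y = fy,
      nucleus_radius = type_radius(cfg, ftype),
      tag = "free", structure_id = NA_character_)

  cells <- dplyr::bind_rows(rows)
  if (nrow(cells) == 0) rlang::abort("configuration yields no cells")
  rates <- setNames(ct$proliferation_rate, ct$type)
  extra_rates <- c(vascular_smooth_muscle = 0.15, pericyte = 0.2,
                   SOX2_epithelial = 0.35, SOX9_epithelial = 0.6,
                   endothelial = 0.3, macrophage = 0.1, ILC_T = 0.2)
  rate <- rates[cells$type]
  rate[is.na(rate)] <- extra_rates[cells$type[is.na(rate)]]
  rate[is.na(rate)] <- 0.2
  cells$proliferating <- runif(nrow(cells)) < rate
  cells$domain <- domain_of(cfg, cells$x, cells$y)
  cells <- dplyr::mutate(cells, id = dplyr::row_number(), .before = 1)

  structure(list(cells = cells,
                 structures = if (length(structures)) dplyr::bind_rows(structures)
                              else tibble::tibble(structure_id = character(),
                                                  kind = character(), cx = numeric(),
                                                  cy = numeric(), r_inner = numeric(),
                                                  r_outer = numeric()),
                 config = cfg, seed = seed),
            class = "synthetic_ground_truth")
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat("<synthetic_ground_truth> ", nrow(x$cells), " cells, ",
      nrow(x$structures), " structures, field ",
      paste(x$config$field_um, collapse = " x "), " µm\n", sep = "")
  print(dplyr::count(x$cells, .data$type))
  invisible(x)
}
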