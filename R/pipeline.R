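# Config-driven orchestration of the full per-week analysis.

default_pipeline_config <- function() {
  list(seed = 1L, week = 12, cofactor = 5, background = 1,
       adjacency = list(radius = 50, n_perms = 200),
       phenotyping = list(resolution = 1.0, k_neighbors = 10, n_pcs = 20),
       domains = list(lambda = 0.8, resolution = 0.3, k = 18),
       proliferation = list(percentiles = list("12" = 85)),
       immune = list(default_resolution = 0.2, resolutions = list()),
       regions = NULL, outdir = "spatmux_out")
}

#' Read a pipeline configuration file
#'
#' YAML key/value config; unset keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), cfg)
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e))))
  log(sprintf("stage %-14s ok (%.1fs)", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline from a config
#'
#' Stages: input (synthetic generation or cell-table read), preprocessing
#' (background subtraction, region exclusion, arcsinh normalization),
#' phenotyping (clustering + rule annotation), adjacency enrichment, spatial
#' domains, proliferation, immune summary, and — when artery-close focal
#' cells are identifiable (synthetic vessel tags or an
#' `artery-immune-selection` region) — the instance-based vasculature
#' analysis. Writes all tables and a run log capturing every parameter and
#' seed into the output directory.
#'
#' @param config config list from [read_pipeline_config()], or a path.
#' @param outdir,seed optional overrides of the config values.
#' @return (invisibly) a list with the annotated `table` and all result
#'   objects; artifacts are written to `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- modifyList(default_pipeline_config(), config)
  # a user-supplied percentile map replaces the default outright: silently
  # inheriting a default week's percentile would mask config omissions
  if (!is.null(config$proliferation$percentiles))
    cfg$proliferation$percentiles <- config$proliferation$percentiles
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(paste0("spatmux ", as.character(utils::packageVersion("spatmux")),
             " | seed ", cfg$seed, " | week ", cfg$week))
  log(paste0("config: ", paste(utils::capture.output(utils::str(cfg)), collapse = " ")))

  # ---- input
  gt <- NULL
  inp <- run_stage("input", log, {
    if (!is.null(cfg$synthetic)) {
      sc_args <- cfg$synthetic
      for (st in c("vessels", "airways", "tips"))
        if (!is.null(sc_args[[st]])) sc_args[[st]] <- tibble::as_tibble(sc_args[[st]])
      if (!is.null(sc_args$vessels) && !"n_endo" %in% names(sc_args$vessels))
        sc_args$vessels <- do.call(synthetic_vessels, as.list(sc_args$vessels))
      sc_args$week <- cfg$week
      sc_args$seed <- cfg$seed
      scfg <- do.call(synthetic_config, sc_args)
      gt <- generate_ground_truth(scfg, seed = cfg$seed)
      emit_cell_table(gt, seed = cfg$seed + 1L)
    } else if (!is.null(cfg$cell_table)) {
      read_cell_table(cfg$cell_table)
    } else rlang::abort("config must provide either 'synthetic' or 'cell_table'")
  })
  markers <- setdiff(intersect(names(inp), default_marker_panel()), character(0))
  if (!is.null(cfg$markers)) markers <- cfg$markers
  if (!"week" %in% names(inp)) inp$week <- cfg$week

  # ---- preprocessing
  regions <- if (is.character(cfg$regions)) read_regions(cfg$regions) else cfg$regions
  raw <- run_stage("preprocess", log, {
    bg <- cfg$background
    spec <- if (is.list(bg)) {
      background_spec(names(bg), rep(cfg$week, length(bg)), unlist(bg))
    } else background_spec(markers, rep(cfg$week, length(markers)),
                           rep(bg, length(markers)))
    tb <- subtract_background(inp, spec, markers)
    if (!is.null(regions)) tb <- exclude_regions(tb, regions)
    tb
  })
  norm <- arcsinh_normalize(raw, markers, cfg$cofactor)

  # ---- phenotyping
  pheno <- run_stage("phenotype", log, {
    res <- cluster_cells(norm, markers,
                         k_neighbors = cfg$phenotyping$k_neighbors,
                         resolution = cfg$phenotyping$resolution,
                         n_pcs = cfg$phenotyping$n_pcs, seed = cfg$seed)
    norm <- add_annotation(norm, res)
    raw$cluster <- norm$cluster
    raw$cell_type <- norm$cell_type
    res
  })
  comp <- composition(norm)

  # ---- adjacency
  adj <- run_stage("adjacency", log, {
    g <- build_neighbor_graph(norm, radius = cfg$adjacency$radius)
    nhood_enrichment(g, norm$cell_type, n_perms = cfg$adjacency$n_perms,
                     seed = cfg$seed)
  })

  # ---- domains
  dom <- run_stage("domains", log, {
    d <- cluster_domains(norm, markers, lambda = cfg$domains$lambda,
                         k = cfg$domains$k,
                         resolution = cfg$domains$resolution,
                         seed = cfg$seed)
    raw$domain <- d$labels
    norm$domain <- d$labels
    d
  })

  # ---- proliferation
  prol <- run_stage("proliferation", log, {
    pct <- unlist(cfg$proliferation$percentiles)
    raw <- classify_proliferating(raw, proliferation_spec(pct))
    norm$proliferating <- raw$proliferating
    proliferation_summary(raw)
  })

  # ---- immune
  immune_set <- c("macrophage", "ILC & T", "B cell", "NK cell", "immune")
  imm <- run_stage("immune", log, {
    raw$is_immune <- raw$cell_type %in% immune_set
    raw$subtype <- ifelse(raw$is_immune, raw$cell_type, NA_character_)
    raw <- apply_immune_gates(raw)
    out <- list(summary = immune_summary(raw[raw$is_immune, , drop = FALSE]))
    if (sum(raw$is_immune) >= 10) {
      gi <- build_neighbor_graph(raw[raw$is_immune, , drop = FALSE],
                                 radius = cfg$adjacency$radius)
      ei <- nhood_enrichment(gi, raw$subtype[raw$is_immune],
                             n_perms = cfg$adjacency$n_perms, seed = cfg$seed)
      out$network <- build_proximity_network(ei)
    }
    out
  })

  # ---- vasculature (instance route)
  vasc <- NULL
  focal <- character(0)
  if (!is.null(gt)) {
    focal <- raw$cell_id[raw$cell_id %in% gt$cells$id[gt$cells$tag == "artery-close"]]
  } else if (!is.null(regions) && any(regions$role == "artery-immune-selection")) {
    sel <- regions[regions$role == "artery-immune-selection", ]
    inside <- rep(FALSE, nrow(raw))
    for (i in seq_len(nrow(sel)))
      inside <- inside | point_in_polygon(raw$x, raw$y, sel$coords[[i]])
    focal <- raw$cell_id[inside & raw$is_immune]
  }
  if (length(focal) >= 3 && sum(raw$is_immune & !raw$cell_id %in% focal) >= length(focal)) {
    vasc <- run_stage("vasculature", log, {
      ctrl <- sample_controls(raw, length(focal), pool = "immune",
                              seed = cfg$seed, exclude = focal)
      list(differential = differential_markers(raw, focal, ctrl, markers),
           profile = neighborhood_composition_profile(raw, focal,
                                                      radius = cfg$adjacency$radius))
    })
  }

  # ---- outputs
  run_stage("write", log, {
    write_cell_table(raw, file.path(cfg$outdir, "cells.csv"))
    write.csv(comp, file.path(cfg$outdir, "composition.csv"), row.names = FALSE)
    write.csv(as.data.frame(adj$z), file.path(cfg$outdir, "enrichment_z.csv"))
    write.csv(prol$overall, file.path(cfg$outdir, "proliferation_overall.csv"),
              row.names = FALSE)
    if (!is.null(prol$per_type))
      write.csv(prol$per_type, file.path(cfg$outdir, "proliferation_per_type.csv"),
                row.names = FALSE)
    if (nrow(imm$summary$composition) > 0)
      write.csv(imm$summary$composition,
                file.path(cfg$outdir, "immune_composition.csv"), row.names = FALSE)
    if (!is.null(imm$network))
      write.csv(imm$network, file.path(cfg$outdir, "immune_network.csv"),
                row.names = FALSE)
    if (!is.null(dom$composition))
      write.csv(dom$composition, file.path(cfg$outdir, "domain_composition.csv"),
                row.names = FALSE)
    if (!is.null(vasc)) {
      write.csv(vasc$differential,
                file.path(cfg$outdir, "vasculature_differential.csv"),
                row.names = FALSE)
      write.csv(vasc$profile,
                file.path(cfg$outdir, "vasculature_profile.csv"), row.names = FALSE)
    }
    TRUE
  })
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(list(table = raw, normalized = norm, phenotype = pheno,
                 composition = comp, adjacency = adj, domains = dom,
                 proliferation = prol, immune = imm, vasculature = vasc,
                 ground_truth = gt, config = cfg))
}
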