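# One-shot orchestration of the pipeline stages, on synthetic or user data.

#' Pipeline run configuration
#'
#' Builds the configuration consumed by [run_pipeline()]. Either
#' `simulate = TRUE` (the bundled scenario generates all inputs) or the
#' input paths must be supplied. Any YAML file with these fields can be
#' loaded via `yaml::read_yaml()` and passed through [pipeline_config()].
#'
#' @param out_dir output directory.
#' @param simulate generate inputs with [default_bcaa_scenario()].
#' @param profile,module_map,metadata input paths (ignored when
#'   simulating).
#' @param metabolites named list of compartment = path entries (ignored
#'   when simulating).
#' @param reporter list of [reporter_config()] overrides.
#' @param network_modules modules for the contribution network; default:
#'   all biosynthesis modules of the map.
#' @param alpha significance level used by the correlation and network
#'   stages.
#' @param seed integer seed governing simulation and background draws.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            profile = NULL, module_map = NULL,
                            metadata = NULL, metabolites = NULL,
                            reporter = list(), network_modules = NULL,
                            alpha = 0.05, seed = 1) {
  cfg <- list(out_dir = out_dir, simulate = isTRUE(simulate),
              profile = profile, module_map = module_map,
              metadata = metadata, metabolites = metabolites,
              reporter = reporter, network_modules = network_modules,
              alpha = alpha, seed = as.integer(seed))
  if (!cfg$simulate) {
    for (f in c("profile", "module_map", "metadata"))
      if (is.null(cfg[[f]]))
        stop("pipeline config needs '", f, "' unless simulate = TRUE")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in order: input simulation (optional), derived-panel cohort
#' statistics, reporter scoring, gene-set correlation, and contribution
#' network construction. Every output is written under `out_dir` and
#' listed, with its MD5 checksum, in `manifest.tsv`; an identical
#' configuration and seed reproduces identical checksums. A failing stage
#' aborts with a stage-named error. Inputs are never modified.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  ## inputs ---------------------------------------------------------------
  if (config$simulate) {
    sim <- stage("simulate",
                 simulate_cohort(default_bcaa_scenario(config$seed)))
    profile <- sim$profile; map <- sim$module_map; design <- sim$design
    panels <- sim$panels
    depleted <- sim$truth$depleted_genera$genus
    in_dir <- file.path(config$out_dir, "inputs")
    for (p in stage("simulate", write_sim_cohort(sim, in_dir))) emit(p)
  } else {
    profile <- stage("read-inputs", read_ko_profile(config$profile))
    map <- stage("read-inputs", read_module_map(config$module_map))
    design <- stage("read-inputs", read_cohort_design(config$metadata))
    panels <- lapply(names(config$metabolites %||% list()), function(comp)
      stage("read-inputs",
            read_metabolite_panel(config$metabolites[[comp]], comp)))
    names(panels) <- names(config$metabolites %||% list())
    depleted <- character(0)
  }

  ## cohort statistics ----------------------------------------------------
  if (length(panels)) {
    for (comp in names(panels)) {
      cs <- stage("cohort-stats", {
        derived <- derive_panels(panels[[comp]])
        conc <- panels[[comp]]$concentrations
        cohort_comparison(cbind(as.data.frame(conc),
                                derived[, -1, drop = FALSE][
                                  match(rownames(conc), derived$sample_id), ,
                                  drop = FALSE]),
                          design)
      })
      p <- file.path(config$out_dir,
                     paste0("cohort_stats_", comp, ".tsv"))
      write.table(cs, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
    }
  }

  ## reporter -------------------------------------------------------------
  rcfg <- do.call(reporter_config,
                  modifyList(list(seed = config$seed), config$reporter))
  scores <- stage("reporter",
                  reporter_scores(profile, map, design, rcfg))
  p <- file.path(config$out_dir, "reporter_scores.tsv")
  write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(p)

  ## correlation ----------------------------------------------------------
  if (length(panels)) {
    corr <- stage("correlate",
                  correlation_matrix(profile, map, panels, design,
                                     alpha = config$alpha))
    p <- file.path(config$out_dir, "correlations.tsv")
    write.table(corr, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  ## network --------------------------------------------------------------
  mods <- config$network_modules %||%
    map$module_id[map$role == "biosynthesis"]
  if (length(mods) && !is.null(profile$strata)) {
    graph <- stage("network", {
      filt <- filter_kos(profile, rcfg$min_occurrence)
      build_module_network(filt, design, map, mods,
                           depleted_genera = depleted,
                           alpha = config$alpha)
    })
    p <- file.path(config$out_dir, "contribution_network.graphml")
    write_graphml(graph, p)
    emit(p)
    p <- file.path(config$out_dir, "contribution_edges.tsv")
    write.table(network_edge_list(graph), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p)
  }

  manifest <- data.frame(file = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
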