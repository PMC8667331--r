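# Synthetic two-group cohort generator with known ground truth: genus-level
# log-normal abundances, a fixed genus x KO incidence matrix, planted genus
# depletions and module-level shifts, and metabolite panels linked to
# gene-set abundances at a configurable Spearman rho.

DEFAULT_AA_NAMES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                      "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                      "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

# plausible baseline concentration scales per compartment
plasma_aa_means <- c(Ala = 350, Arg = 80, Asn = 45, Asp = 5, Cys = 30,
                     Gln = 550, Glu = 40, Gly = 220, His = 80, Ile = 60,
                     Leu = 120, Lys = 180, Met = 25, Phe = 55, Pro = 170,
                     Ser = 110, Thr = 120, Trp = 50, Tyr = 60, Val = 220)
fecal_aa_means <- setNames(rep(500, length(DEFAULT_AA_NAMES)),
                           DEFAULT_AA_NAMES)

#' Simulation configuration
#'
#' Defines a two-group synthetic cohort. Defaults mirror the study design
#' the package targets: 22 case and 11 control samples.
#'
#' @param n_case,n_control group sizes (each >= 3; defaults 22 and 11).
#' @param n_genera number of genera.
#' @param n_kos number of KO gene families.
#' @param incidence_density fraction of (genus, KO) pairs present.
#' @param depleted_genera list of `list(genus =, fold =)` entries: genus
#'   name or index whose abundance is multiplied by `fold` (< 1 for a
#'   depletion) in case samples.
#' @param planted_modules list of `list(module_id =, n_kos =, fold =,
#'   carriers = NULL, aa_target = "other", role = "other")` entries. The
#'   module's KOs get `carriers` (genus names/indices) as their only
#'   carriers when supplied; their stratified abundances are additionally
#'   multiplied by `fold` in case samples (`fold = 1` means the shift, if
#'   any, comes entirely from carrier depletion).
#' @param n_null_modules number of additional unplanted modules whose KO
#'   sets are drawn at random.
#' @param module_k_range integer range (lo, hi) of null-module sizes.
#' @param metabolite_links list of `list(analyte =, gene_set =, rho =,
#'   group = "case", compartment = "plasma")` entries; `gene_set` is a
#'   module id or `"target/role"` key (see [resolve_gene_set()]). The
#'   analyte is constructed to have Spearman correlation `rho` with the
#'   gene-set abundance within `group`, and to be independent of it in the
#'   other group.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal) KO-level noise.
#' @param genus_names optional genus names (defaults `Genus01`, ...).
#' @param compartments metabolite compartments to generate.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_case = 22, n_control = 11,
                       n_genera = 30, n_kos = 300,
                       incidence_density = 0.15,
                       depleted_genera = list(),
                       planted_modules = list(),
                       n_null_modules = 16,
                       module_k_range = c(3, 8),
                       metabolite_links = list(),
                       noise_cv = 0.25,
                       genus_names = NULL,
                       compartments = c("plasma", "fecal"),
                       seed = 1) {
  stopifnot(n_case >= 3, n_control >= 3, n_genera >= 2, n_kos >= 2,
            incidence_density > 0, incidence_density <= 1,
            noise_cv >= 0, length(module_k_range) == 2,
            module_k_range[1] >= 1,
            module_k_range[2] >= module_k_range[1])
  for (d in depleted_genera)
    if (is.null(d$genus) || is.null(d$fold) || d$fold <= 0)
      stop("each depleted_genera entry needs a genus and a fold > 0")
  for (pm in planted_modules)
    if (is.null(pm$module_id) || is.null(pm$n_kos) ||
        is.null(pm$fold) || pm$fold <= 0)
      stop("each planted_modules entry needs module_id, n_kos, fold > 0")
  for (l in metabolite_links)
    if (is.null(l$analyte) || is.null(l$gene_set) || is.null(l$rho) ||
        abs(l$rho) > 1)
      stop("each metabolite link needs analyte, gene_set and |rho| <= 1")
  if (is.null(genus_names))
    genus_names <- sprintf("Genus%02d", seq_len(n_genera))
  if (length(genus_names) != n_genera || anyDuplicated(genus_names))
    stop("'genus_names' must be ", n_genera, " unique names")
  structure(list(n_case = n_case, n_control = n_control,
                 n_genera = n_genera, n_kos = n_kos,
                 incidence_density = incidence_density,
                 depleted_genera = depleted_genera,
                 planted_modules = planted_modules,
                 n_null_modules = n_null_modules,
                 module_k_range = as.integer(module_k_range),
                 metabolite_links = metabolite_links,
                 noise_cv = noise_cv,
                 genus_names = genus_names,
                 compartments = match.arg(compartments,
                                          c("plasma", "fecal"),
                                          several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "sim_config")
}

genus_index <- function(config, g) {
  if (is.numeric(g)) return(as.integer(g))
  i <- match(g, config$genus_names)
  if (is.na(i)) stop("unknown genus in config: ", g)
  i
}

#' Simulate a two-group cohort with planted ground truth
#'
#' Genus abundances are drawn log-normal per sample (per-genus location and
#' scale drawn once from seed-governed hyperpriors); a fixed genus x KO
#' incidence matrix determines which genera carry which KOs; stratified
#' abundances are genus abundance times multiplicative log-normal noise,
#' and community KO abundance is their sum over genera, so stratified sums
#' match community totals exactly. Case-group depletions and planted
#' module shifts are applied multiplicatively. Metabolite analytes named in
#' the links are rank-preserving transforms of the linked gene-set
#' abundance plus Gaussian noise, calibrated through the normal-scores
#' relation `r_pearson = 2 sin(pi * rho_spearman / 6)` to reach the target
#' Spearman rho in expectation within the linked group.
#'
#' A per-stage seed ladder (`seed + stage offset`) keeps the community,
#' module-map and metabolite stages independently reproducible.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `profile` ([ko_profile()]),
#'   `design` ([cohort_design()]), `module_map` ([module_map()]), `panels`
#'   (named list of [metabolite_panel()] by compartment), and `truth`, a
#'   record of every planted effect as realised.
#' @examples
#' sim <- simulate_cohort(sim_config(n_kos = 50, n_null_modules = 5,
#'                                   seed = 7))
#' sim$profile
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genera; K <- config$n_kos
  S <- config$n_case + config$n_control
  samples <- sprintf("S%03d", seq_len(S))
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))
  design <- cohort_design(samples, groups)
  case_cols <- which(groups == "case")

  ## stage 1: genus hyperparameters and incidence ------------------------
  set.seed(config$seed + 101L)
  mu_g <- rnorm(G, mean = log(50), sd = 1.5)
  sigma_g <- runif(G, 0.3, 0.8)
  incidence <- matrix(rbinom(G * K, 1, config$incidence_density), G, K,
                      dimnames = list(config$genus_names,
                                      sprintf("K%05d", seq_len(K))))
  # every KO needs at least one carrier
  empty <- which(colSums(incidence) == 0)
  if (length(empty))
    incidence[cbind(sample.int(G, length(empty), replace = TRUE), empty)] <- 1L

  ## module map: planted modules claim disjoint KO blocks first ----------
  ko_names <- colnames(incidence)
  next_ko <- 1L
  pm_ids <- character(0); pm_kos <- list()
  pm_target <- character(0); pm_role <- character(0)
  for (pm in config$planted_modules) {
    idx <- next_ko:(next_ko + pm$n_kos - 1L)
    if (max(idx) > K) stop("n_kos too small for the planted modules")
    next_ko <- next_ko + pm$n_kos
    pm_ids <- c(pm_ids, pm$module_id)
    pm_kos <- c(pm_kos, list(ko_names[idx]))
    pm_target <- c(pm_target, pm$aa_target %||% "other")
    pm_role <- c(pm_role, pm$role %||% "other")
    if (!is.null(pm$carriers)) {
      ci <- vapply(pm$carriers, genus_index, integer(1), config = config)
      incidence[, idx] <- 0L
      incidence[ci, idx] <- 1L
    }
  }
  null_ids <- sprintf("M9%04d", seq_len(config$n_null_modules))
  null_pool <- if (next_ko <= K) ko_names[next_ko:K] else character(0)
  if (config$n_null_modules > 0 &&
      length(null_pool) < config$module_k_range[2])
    stop("n_kos too small for the requested null modules")
  null_kos <- lapply(seq_len(config$n_null_modules), function(i) {
    k <- sample(config$module_k_range[1]:config$module_k_range[2], 1)
    sample(null_pool, k)
  })
  map <- module_map(c(pm_ids, null_ids), c(pm_kos, null_kos),
                    aa_target = c(pm_target,
                                  rep("other", config$n_null_modules)),
                    role = c(pm_role, rep("other", config$n_null_modules)))

  ## stage 2: abundances -------------------------------------------------
  set.seed(config$seed + 202L)
  A <- exp(mu_g + sigma_g * matrix(rnorm(G * S), G, S))
  dimnames(A) <- list(config$genus_names, samples)
  dep_idx <- integer(0); dep_fold <- numeric(0)
  for (d in config$depleted_genera) {
    i <- genus_index(config, d$genus)
    A[i, case_cols] <- A[i, case_cols] * d$fold
    dep_idx <- c(dep_idx, i); dep_fold <- c(dep_fold, d$fold)
  }

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  carrier <- which(incidence == 1L, arr.ind = TRUE)  # (genus, ko) pairs
  nr <- nrow(carrier)
  noise <- exp(matrix(rnorm(nr * S, -sdlog^2 / 2, sdlog), nr, S))
  strata <- A[carrier[, 1], , drop = FALSE] * noise
  rownames(strata) <- paste0(ko_names[carrier[, 2]], "|g__",
                             config$genus_names[carrier[, 1]])

  # planted module-level shifts (applied to every carrier stratum)
  for (j in seq_along(config$planted_modules)) {
    pm <- config$planted_modules[[j]]
    if (pm$fold != 1) {
      rows <- carrier[, 2] %in% match(pm_kos[[j]], ko_names)
      strata[rows, case_cols] <- strata[rows, case_cols] * pm$fold
    }
  }

  community <- rowsum(strata, ko_names[carrier[, 2]])
  community <- community[ko_names, , drop = FALSE]
  # fixed global rescale to a copies-per-million-like magnitude; a single
  # constant, so per-sample rank structure is untouched
  scale <- 1e6 / mean(colSums(community))
  community <- community * scale
  strata <- strata * scale
  profile <- ko_profile(community, strata)

  ## stage 3: metabolites -------------------------------------------------
  set.seed(config$seed + 303L)
  panels <- list()
  realized <- list()
  for (comp in config$compartments) {
    means <- if (comp == "plasma") plasma_aa_means else fecal_aa_means
    conc <- matrix(NA_real_, S, length(DEFAULT_AA_NAMES),
                   dimnames = list(samples, DEFAULT_AA_NAMES))
    for (a in DEFAULT_AA_NAMES)
      conc[, a] <- means[a] * exp(0.3 * rnorm(S))
    links <- Filter(function(l) (l$compartment %||% "plasma") == comp,
                    config$metabolite_links)
    for (l in links) {
      kos <- resolve_gene_set(map, l$gene_set)
      sset <- geneset_abundance(profile, kos)
      grp <- l$group %||% "case"
      in_grp <- samples %in% group_samples(design, grp)
      s_grp <- sset[in_grp]
      if (length(unique(s_grp)) < 2)
        stop("infeasible metabolite link (constant gene-set abundance): ",
             l$analyte, " ~ ", l$gene_set)
      r_p <- 2 * sin(pi * l$rho / 6)
      ns <- qnorm(rank(s_grp) / (sum(in_grp) + 1))
      raw <- r_p * ns + sqrt(1 - r_p^2) * rnorm(sum(in_grp))
      latent <- rnorm(S)
      latent[in_grp] <- raw
      conc[, l$analyte] <- means[l$analyte] * exp(0.3 * latent)
      realized[[length(realized) + 1L]] <- data.frame(
        analyte = l$analyte, gene_set = l$gene_set, compartment = comp,
        group = grp, target_rho = l$rho,
        realized_rho = suppressWarnings(
          cor(s_grp, conc[in_grp, l$analyte], method = "spearman")),
        stringsAsFactors = FALSE)
    }
    panels[[comp]] <- metabolite_panel(conc, comp)
  }

  truth <- structure(list(
    depleted_genera = data.frame(
      genus = config$genus_names[dep_idx],
      fold = dep_fold, stringsAsFactors = FALSE),
    planted_modules = data.frame(
      module_id = pm_ids,
      n_kos = vapply(config$planted_modules,
                     function(x) as.integer(x$n_kos), 0L),
      fold = vapply(config$planted_modules, function(x) x$fold, 0),
      direction = vapply(config$planted_modules, function(pm) {
        depleted_carrier <- !is.null(pm$carriers) &&
          any(vapply(pm$carriers, genus_index, integer(1),
                     config = config) %in% dep_idx)
        if (pm$fold < 1 || (pm$fold == 1 && depleted_carrier)) "down"
        else if (pm$fold > 1) "up" else "none"
      }, ""), stringsAsFactors = FALSE),
    links = if (length(realized)) do.call(rbind, realized) else NULL,
    seed = config$seed), class = "sim_truth")

  structure(list(profile = profile, design = design, module_map = map,
                 panels = panels, truth = truth, config = config),
            class = "sim_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged BCAA-depletion scenario
#'
#' A ready-made simulation configuration emulating the study pattern the
#' package targets: 22 case vs 11 control samples; the genera *Eubacterium*
#' and *Prevotella* depleted five-fold in cases and carrying the KOs of two
#' branched-chain amino-acid biosynthesis modules (M00535, M00432) and
#' (for *Eubacterium*) a histidine biosynthesis module (M00026), so those
#' modules shift down in cases; a histidine degradation module (M00045,
#' carried by *Bifidobacterium* and others) planted three-fold up in cases;
#' and plasma Leu/Ile/Val concentrations linked to the summed
#' BCAA-biosynthesis gene-set abundance at Spearman rho 0.6 in the case
#' group only.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
default_bcaa_scenario <- function(seed = 1) {
  genera <- c("Bacteroides", "Prevotella", "Subdoligranulum", "Eubacterium",
              "Escherichia", "Streptococcus", "Bifidobacterium",
              "Faecalibacterium", "Alistipes", "Parabacteroides",
              sprintf("Genus%02d", 11:30))
  sim_config(
    n_case = 22, n_control = 11,
    n_genera = 30, n_kos = 300,
    incidence_density = 0.15,
    genus_names = genera,
    depleted_genera = list(list(genus = "Eubacterium", fold = 0.2),
                           list(genus = "Prevotella", fold = 0.2)),
    planted_modules = list(
      list(module_id = "M00535", n_kos = 4, fold = 1,
           carriers = c("Eubacterium", "Prevotella"),
           aa_target = "BCAA", role = "biosynthesis"),
      list(module_id = "M00432", n_kos = 4, fold = 1,
           carriers = c("Eubacterium", "Prevotella"),
           aa_target = "BCAA", role = "biosynthesis"),
      list(module_id = "M00026", n_kos = 5, fold = 1,
           carriers = "Eubacterium",
           aa_target = "histidine", role = "biosynthesis"),
      list(module_id = "M00045", n_kos = 4, fold = 3,
           carriers = c("Bifidobacterium", "Streptococcus", "Escherichia"),
           aa_target = "histidine", role = "degradation")),
    n_null_modules = 16,
    module_k_range = c(3, 8),
    metabolite_links = list(
      list(analyte = "Leu", gene_set = "BCAA/biosynthesis", rho = 0.6,
           group = "case", compartment = "plasma"),
      list(analyte = "Ile", gene_set = "BCAA/biosynthesis", rho = 0.6,
           group = "case", compartment = "plasma"),
      list(analyte = "Val", gene_set = "BCAA/biosynthesis", rho = 0.6,
           group = "case", compartment = "plasma")),
    noise_cv = 0.25,
    seed = seed)
}

#' Write all artifacts of a simulated cohort
#'
#' Writes the KO profile, metadata, module map and metabolite panels in
#' the package's TSV dialects plus the ground truth as YAML.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profile = file.path(dir, "ko_profile.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             module_map = file.path(dir, "module_map.tsv"),
             truth = file.path(dir, "truth.yaml"))
  write_ko_profile(sim$profile, paths["profile"])
  write_cohort_design(sim$design, paths["metadata"])
  write_module_map(sim$module_map, paths["module_map"])
  for (comp in names(sim$panels)) {
    p <- file.path(dir, paste0("metabolites_", comp, ".tsv"))
    write_metabolite_panel(sim$panels[[comp]], p)
    paths[paste0("metabolites_", comp)] <- p
  }
  yaml::write_yaml(list(
    depleted_genera = sim$truth$depleted_genera,
    planted_modules = sim$truth$planted_modules,
    links = sim$truth$links, seed = sim$truth$seed), paths["truth"])
  invisible(paths)
}
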