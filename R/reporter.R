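# Module-level reporter scoring: per-KO one-tailed differential testing,
# p -> Z transformation, module aggregation, and random-set background
# correction.

#' Reporter-scoring configuration
#'
#' @param min_occurrence KOs must be non-zero in strictly more than this
#'   many samples to be tested (default 5, i.e. "more than five samples").
#' @param z_variant `"inverse_normal"` (default): `z = qnorm(1 - p)`, so
#'   positive scores mean enrichment in the case group;
#'   `"literal_standardized_p"`: `z = (p - mean(p)) / sd(p)` across all
#'   tested KOs (note this variant's sign runs opposite: small p gives
#'   negative z).
#' @param n_random_sets number of random KO sets per distinct module size
#'   used to estimate the background mean and SD (default 1000).
#' @param call_threshold absolute adjusted score at or above which a module
#'   is called differentially enriched (default 1.6, approximately 90%
#'   two-sided confidence under a standard normal background).
#' @param p_clip_epsilon p-values are clipped to
#'   `[epsilon, 1 - epsilon]` before the quantile transform so exact
#'   p = 0/1 cannot produce infinite z (default 1e-15).
#' @param seed integer seed for the background draws.
#' @return a `reporter_config` list.
#' @export
reporter_config <- function(min_occurrence = 5,
                            z_variant = c("inverse_normal",
                                          "literal_standardized_p"),
                            n_random_sets = 1000,
                            call_threshold = 1.6,
                            p_clip_epsilon = 1e-15,
                            seed = 1) {
  z_variant <- match.arg(z_variant)
  stopifnot(min_occurrence >= 0, n_random_sets >= 100, call_threshold > 0,
            p_clip_epsilon > 0, p_clip_epsilon < 0.5)
  structure(list(min_occurrence = as.integer(min_occurrence),
                 z_variant = z_variant,
                 n_random_sets = as.integer(n_random_sets),
                 call_threshold = call_threshold,
                 p_clip_epsilon = p_clip_epsilon,
                 seed = as.integer(seed)),
            class = "reporter_config")
}

#' Filter rare KOs
#'
#' Retains KOs with non-zero abundance in strictly more than
#' `min_occurrence` samples, counted over all samples of both groups.
#'
#' @param profile a [ko_profile()].
#' @param min_occurrence occurrence cutoff (strict greater-than; default 5).
#' @return the filtered [ko_profile()] (strata of removed KOs are dropped
#'   too). May be empty, with a warning.
#' @export
filter_kos <- function(profile, min_occurrence = 5) {
  stopifnot(inherits(profile, "ko_profile"))
  keep <- rowSums(profile$community > 0) > min_occurrence
  if (!any(keep))
    warning("no KOs occur in more than ", min_occurrence,
            " samples; profile is empty after filtering")
  comm <- profile$community[keep, , drop = FALSE]
  strata <- profile$strata
  if (!is.null(strata)) {
    parents <- sub("\\|.*$", "", rownames(strata))
    strata <- strata[parents %in% rownames(comm), , drop = FALSE]
    if (nrow(strata) == 0) strata <- NULL
  }
  ko_profile(comm, strata)
}

#' Per-KO one-tailed differential abundance
#'
#' One-tailed Mann-Whitney U test per KO with alternative "abundance
#' greater in the case group": small p indicates case enrichment, p near 1
#' indicates control enrichment. The exact null distribution is used when
#' there are no ties (see the package's Mann-Whitney backend).
#'
#' @param profile a (filtered) [ko_profile()].
#' @param design a [cohort_design()] covering all profile samples, with at
#'   least 3 samples per group.
#' @return data.frame with columns `ko_id`, `n_present`, `p_value`, and a
#'   placeholder `z` column (`NA` until [p_to_z()]).
#' @export
ko_differential <- function(profile, design) {
  stopifnot(inherits(profile, "ko_profile"),
            inherits(design, "cohort_design"))
  check_design_covers(design, sample_ids(profile))
  cs <- group_samples(design, "case", sample_ids(profile))
  ct <- group_samples(design, "control", sample_ids(profile))
  if (length(cs) < 3 || length(ct) < 3)
    stop("need at least 3 profiled samples per group")
  p <- mwu_matrix(profile$community, cs, ct, alternative = "greater")
  data.frame(ko_id = ko_ids(profile),
             n_present = unname(rowSums(profile$community > 0)),
             p_value = p, z = NA_real_,
             stringsAsFactors = FALSE)
}

#' Transform per-KO p-values to Z-scores
#'
#' Default variant `inverse_normal`: `z = qnorm(1 - p)` after clipping p to
#' `[eps, 1 - eps]`; large positive z = enriched in cases, negative z =
#' enriched in controls. Variant `literal_standardized_p` standardises the
#' p-values themselves, `z = (p - mean(p)) / sd(p)` over all tested KOs.
#'
#' @param results output of [ko_differential()].
#' @param config a [reporter_config()].
#' @return `results` with the `z` column filled.
#' @export
p_to_z <- function(results, config = reporter_config()) {
  stopifnot(is.data.frame(results), "p_value" %in% colnames(results))
  p <- results$p_value
  eps <- config$p_clip_epsilon
  if (config$z_variant == "inverse_normal") {
    results$z <- qnorm(1 - pmin(pmax(p, eps), 1 - eps))
  } else {
    if (length(p) < 2)
      stop("literal_standardized_p needs at least 2 tested KOs")
    results$z <- (p - mean(p)) / sd(p)
  }
  results
}

#' Aggregate KO Z-scores into raw module scores
#'
#' For each module, the raw score is the sum of the member KOs' Z-scores
#' divided by the square root of k, where k counts the module KOs that were
#' actually tested; untested KOs are dropped from k and reflected in
#' `coverage = k / |ko_set|`. Modules with k = 0 are omitted with a
#' warning.
#'
#' @param z_results output of [p_to_z()].
#' @param map a [module_map()].
#' @return data.frame: `module_id`, `label`, `aa_target`, `role`, `k`,
#'   `coverage`, `raw`.
#' @export
module_scores <- function(z_results, map) {
  stopifnot(inherits(map, "module_map"))
  if (anyNA(z_results$z)) stop("run p_to_z() before module_scores()")
  z <- setNames(z_results$z, z_results$ko_id)
  k <- integer(nrow(map)); raw <- numeric(nrow(map))
  for (i in seq_len(nrow(map))) {
    hit <- intersect(map$kos[[i]], names(z))
    k[i] <- length(hit)
    raw[i] <- if (k[i] > 0) sum(z[hit]) / sqrt(k[i]) else NA_real_
  }
  drop <- k == 0
  if (any(drop))
    warning(sum(drop), " module(s) had no tested KOs and were omitted: ",
            paste(head(map$module_id[drop], 5), collapse = ", "))
  data.frame(module_id = map$module_id, label = map$label,
             aa_target = map$aa_target, role = map$role,
             k = k, coverage = k / lengths(map$kos), raw = raw,
             stringsAsFactors = FALSE)[!drop, , drop = FALSE]
}

#' Random-set background correction
#'
#' For each distinct module size k, draws `n_random_sets` size-k subsets of
#' the tested-KO universe without replacement, computes their raw scores,
#' and standardises each module's raw score by the background mean and SD:
#' `adjusted = (raw - mu_k) / sigma_k`. The adjusted score is the final
#' reporter score. Backgrounds are shared between modules of equal k.
#'
#' @param scores output of [module_scores()].
#' @param z_results output of [p_to_z()] (defines the KO universe).
#' @param config a [reporter_config()]; `seed` makes the draws
#'   reproducible.
#' @return `scores` with columns `bg_mean`, `bg_sd`, `adjusted` added. A
#'   degenerate background (`sigma_k = 0`) leaves `adjusted` `NA` with a
#'   warning.
#' @export
background_correct <- function(scores, z_results,
                               config = reporter_config()) {
  z <- z_results$z
  if (anyNA(z)) stop("run p_to_z() before background_correct()")
  n_universe <- length(z)
  ks <- sort(unique(scores$k))
  if (any(ks > n_universe))
    stop("module size k exceeds the tested-KO universe (",
         n_universe, " KOs)")
  set.seed(config$seed)
  bg <- lapply(ks, function(k) {
    draws <- vapply(seq_len(config$n_random_sets),
                    function(i) sum(z[sample.int(n_universe, k)]) / sqrt(k),
                    numeric(1))
    c(mean = mean(draws), sd = sd(draws))
  })
  names(bg) <- as.character(ks)
  scores$bg_mean <- vapply(as.character(scores$k),
                           function(k) bg[[k]]["mean"], numeric(1),
                           USE.NAMES = FALSE)
  scores$bg_sd <- vapply(as.character(scores$k),
                         function(k) bg[[k]]["sd"], numeric(1),
                         USE.NAMES = FALSE)
  scores$adjusted <- (scores$raw - scores$bg_mean) / scores$bg_sd
  degen <- scores$bg_sd == 0
  if (any(degen)) {
    warning(sum(degen), " module(s) have a degenerate background ",
            "(sigma_k = 0); adjusted score undefined")
    scores$adjusted[degen] <- NA_real_
  }
  scores
}

#' Call module enrichment from adjusted reporter scores
#'
#' `adjusted >= threshold` is called `enriched_case`,
#' `adjusted <= -threshold` is `enriched_control` (both bounds inclusive),
#' anything else (including an undefined adjusted score) is `none`.
#'
#' @param scores output of [background_correct()].
#' @param config a [reporter_config()] supplying `call_threshold`.
#' @return `scores` with a `call` column.
#' @export
call_enrichment <- function(scores, config = reporter_config()) {
  thr <- config$call_threshold
  a <- scores$adjusted
  call <- rep("none", length(a))
  call[!is.na(a) & a >= thr] <- "enriched_case"
  call[!is.na(a) & a <= -thr] <- "enriched_control"
  scores$call <- call
  scores
}

#' Full reporter-score analysis
#'
#' Convenience wrapper chaining [filter_kos()], [ko_differential()],
#' [p_to_z()], [module_scores()], [background_correct()] and
#' [call_enrichment()].
#'
#' @param profile a [ko_profile()].
#' @param map a [module_map()].
#' @param design a [cohort_design()].
#' @param config a [reporter_config()].
#' @return data.frame of per-module reporter scores and enrichment calls.
#' @examples
#' sim <- simulate_cohort(default_bcaa_scenario(seed = 1))
#' head(reporter_scores(sim$profile, sim$module_map, sim$design,
#'                      reporter_config(n_random_sets = 200)))
#' @export
reporter_scores <- function(profile, map, design,
                            config = reporter_config()) {
  prof <- filter_kos(profile, config$min_occurrence)
  res <- ko_differential(prof, design)
  res <- p_to_z(res, config)
  sc <- module_scores(res, map)
  sc <- background_correct(sc, res, config)
  call_enrichment(sc, config)
}
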