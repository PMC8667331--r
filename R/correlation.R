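# Group-stratified Spearman correlation of summed gene-set abundances with
# metabolite concentrations.

#' Per-sample summed abundance of a KO gene set
#'
#' @param profile a [ko_profile()].
#' @param ko_set character vector of KO ids; KOs absent from the profile
#'   are skipped (the number actually used is attached as an attribute).
#' @return named numeric vector of per-sample sums, with attributes
#'   `n_kos_used` and `kos_used`.
#' @export
geneset_abundance <- function(profile, ko_set) {
  stopifnot(inherits(profile, "ko_profile"))
  hit <- intersect(unique(ko_set), ko_ids(profile))
  if (length(hit) == 0)
    stop("none of the gene-set KOs are present in the profile")
  out <- colSums(profile$community[hit, , drop = FALSE])
  attr(out, "n_kos_used") <- length(hit)
  attr(out, "kos_used") <- hit
  out
}

#' Spearman rank correlation with pairwise-complete deletion
#'
#' Average ranks are used for ties. The p-value is exact (permutation
#' enumeration) when n <= 9 with no ties, otherwise the asymptotic
#' t-approximation — the conventions of [stats::cor.test()], which does
#' the computation. With zero rank variance in either variable the
#' coefficient is undefined and flagged.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list: `rho`, `p_value`, `n_pairs`, `undefined`.
#' @examples
#' spearman_cor(1:5, c(3, 1, 2, 5, 4))  # rho = 0.7
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = n,
                undefined = TRUE))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = n,
       undefined = FALSE)
}

#' Gene-set x metabolite Spearman correlation matrix
#'
#' For every requested gene set, every analyte of every panel, and each
#' cohort group separately (plus optionally the pooled cohort), computes
#' the Spearman correlation between the per-sample gene-set abundance and
#' the analyte concentration, with pairwise-complete deletion of
#' not-detected values. Output is heatmap-ready long format. Cells whose
#' group has fewer than 3 usable samples are skipped with a warning; cells
#' with an undefined coefficient (constant ranks) are kept, flagged via
#' `rho = NA`. No multiple-testing correction is applied; `significant`
#' flags raw p < `alpha`.
#'
#' @param profile a [ko_profile()].
#' @param map a [module_map()].
#' @param panels a [metabolite_panel()] or list of them.
#' @param design a [cohort_design()].
#' @param gene_sets character vector of gene sets ([resolve_gene_set()]
#'   keys); default: every module id in the map.
#' @param analytes analytes to correlate; default: all panel analytes.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param pooled also compute pooled (both groups) correlations.
#' @return data.frame: `gene_set`, `analyte`, `compartment`, `group`,
#'   `n_pairs`, `rho`, `p_value`, `significant`.
#' @export
correlation_matrix <- function(profile, map, panels, design,
                               gene_sets = NULL, analytes = NULL,
                               alpha = 0.05, pooled = FALSE) {
  stopifnot(inherits(profile, "ko_profile"),
            inherits(design, "cohort_design"))
  if (inherits(panels, "metabolite_panel")) panels <- list(panels)
  if (is.null(gene_sets)) gene_sets <- map$module_id
  groups <- c("case", "control", if (pooled) "pooled")
  rows <- list()
  for (gs in gene_sets) {
    kos <- resolve_gene_set(map, gs)
    abund <- geneset_abundance(profile, kos)
    for (panel in panels) {
      conc <- panel$concentrations
      shared <- intersect(names(abund), rownames(conc))
      ans <- if (is.null(analytes)) colnames(conc) else
        match_analytes(panel, analytes)
      for (grp in groups) {
        ids <- if (grp == "pooled") shared else
          group_samples(design, grp, shared)
        for (an in ans) {
          x <- abund[ids]; y <- conc[ids, an]
          n_ok <- sum(complete.cases(x, y))
          if (n_ok < 3) {
            warning("skipping ", gs, " ~ ", an, " (", panel$compartment,
                    ", ", grp, "): fewer than 3 complete pairs")
            next
          }
          sp <- spearman_cor(x, y)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_set = gs, analyte = an,
            compartment = panel$compartment, group = grp,
            n_pairs = sp$n_pairs, rho = sp$rho, p_value = sp$p_value,
            significant = !sp$undefined && !is.na(sp$p_value) &&
              sp$p_value < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) stop("no correlation cells could be computed")
  do.call(rbind, rows)
}
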