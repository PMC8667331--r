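# Genus -> KO -> module contribution networks: which genera carry each KO
# of a module, which are its top contributors, and which genus-level KO
# abundances differ between groups.

#' Ranked genus contributions to one KO
#'
#' Genera are ranked by mean stratified abundance over all samples,
#' descending; ties are broken alphabetically. The implicit `unclassified`
#' stratum is excluded from the ranking but its mean is reported as an
#' attribute.
#'
#' @param profile a [ko_profile()] with strata.
#' @param ko_id a single KO id.
#' @return data.frame `genus`, `mean_abundance`, `rank` (empty, with a
#'   warning, when the KO has no stratified rows), with attribute
#'   `unclassified_mean`.
#' @export
genus_contributions <- function(profile, ko_id) {
  st <- ko_strata(profile, ko_id)
  if (is.null(st)) {
    warning("KO ", ko_id, " has no genus strata")
    out <- data.frame(genus = character(0), mean_abundance = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    attr(out, "unclassified_mean") <- NA_real_
    return(out)
  }
  uncl <- mean(st["unclassified", ])
  st <- st[setdiff(rownames(st), "unclassified"), , drop = FALSE]
  mn <- rowMeans(st)
  ord <- order(-mn, names(mn))
  out <- data.frame(genus = names(mn)[ord],
                    mean_abundance = unname(mn[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "unclassified_mean") <- uncl
  out
}

#' Between-group test of one genus-level KO stratum
#'
#' Two-sided Mann-Whitney U test on the stratified abundance of
#' (`ko_id`, `genus`) between case and control samples. When p < `alpha`,
#' the direction is set by comparing group medians (falling back to means
#' when the medians tie); otherwise `"none"`.
#'
#' @param profile a [ko_profile()] with strata.
#' @param design a [cohort_design()].
#' @param ko_id KO id.
#' @param genus bare genus name (no `g__` prefix).
#' @param alpha significance level (default 0.05).
#' @return list: `direction` (`"up_in_case"`, `"down_in_case"`, `"none"`),
#'   `p_value`, `degenerate` (all-zero stratum).
#' @export
genus_ko_differential <- function(profile, design, ko_id, genus,
                                  alpha = 0.05) {
  st <- ko_strata(profile, ko_id)
  if (is.null(st) || !genus %in% rownames(st))
    stop("no stratum for ", ko_id, " in genus ", genus)
  v <- st[genus, ]
  if (all(v == 0))
    return(list(direction = "none", p_value = NA_real_, degenerate = TRUE))
  cs <- group_samples(design, "case", sample_ids(profile))
  ct <- group_samples(design, "control", sample_ids(profile))
  p <- mwu_p(v[cs], v[ct], "two.sided")
  direction <- "none"
  if (p < alpha) {
    d <- median(v[cs]) - median(v[ct])
    if (d == 0) d <- mean(v[cs]) - mean(v[ct])
    direction <- if (d > 0) "up_in_case" else "down_in_case"
  }
  list(direction = direction, p_value = p, degenerate = FALSE)
}

#' Build a genus-KO-module contribution network
#'
#' For each requested module, adds a module node, nodes for its KOs that
#' are present in the profile, KO-to-module membership edges, and
#' genus-to-KO contribution edges for every genus that is either a top-n
#' contributor to the KO or has a significantly different stratified
#' abundance between groups. Genus nodes carry their overall mean
#' community contribution (summed over all stratified KOs), a flag marking
#' the overall top `overall_top_genera` genera, and a `depleted` flag set
#' from a supplied differential-taxa list (e.g. the output of an external
#' differential-abundance tool, or the simulation truth). Edges carry the
#' contribution rank, a top-n flag, the two-sided Mann-Whitney p-value and
#' the significant differential direction.
#'
#' @param profile a [ko_profile()] with strata (use [filter_kos()] first
#'   so only tested KOs appear).
#' @param design a [cohort_design()].
#' @param map a [module_map()].
#' @param module_ids modules to include.
#' @param top_n contribution-rank cutoff for drawing an edge (default 5).
#' @param overall_top_genera size of the overall-abundance highlight set
#'   (default 10).
#' @param depleted_genera character vector of genera to flag as depleted.
#' @param alpha edge significance level (default 0.05, two-sided).
#' @return an [igraph::igraph] with vertex attributes `type`
#'   (`genus`/`ko`/`module`), `mean_abundance`, `top10`, `depleted` and
#'   edge attributes `kind` (`contribution`/`membership`), `rank`, `top5`,
#'   `direction`, `p_value`.
#' @export
build_module_network <- function(profile, design, map, module_ids,
                                 top_n = 5, overall_top_genera = 10,
                                 depleted_genera = character(0),
                                 alpha = 0.05) {
  stopifnot(inherits(profile, "ko_profile"), inherits(map, "module_map"))
  unknown <- setdiff(module_ids, map$module_id)
  if (length(unknown))
    stop("unknown module(s): ", paste(unknown, collapse = ", "))
  if (is.null(profile$strata))
    stop("profile has no genus strata; a contribution network needs them")

  # overall genus abundance = per-sample sum of all its stratified rows
  genus_of <- sub("^.*\\|g__", "", rownames(profile$strata))
  overall <- rowsum(rowMeans(profile$strata), genus_of)[, 1]
  top_overall <- names(sort(overall, decreasing = TRUE))
  top_overall <- head(top_overall, overall_top_genera)

  nodes <- list(); edges <- list()
  add_node <- function(name, type, mean_abundance = NA_real_) {
    if (!name %in% names(nodes))
      nodes[[name]] <<- list(type = type, mean_abundance = mean_abundance)
  }
  for (mid in module_ids) {
    add_node(mid, "module")
    kos <- intersect(map$kos[[match(mid, map$module_id)]], ko_ids(profile))
    for (ko in kos) {
      add_node(ko, "ko", mean(profile$community[ko, ]))
      # NaN / "" mark not-applicable annotations on membership edges so
      # the graph round-trips GraphML without sentinel surprises
      edges[[length(edges) + 1L]] <- data.frame(
        from = ko, to = mid, kind = "membership", rank = NaN,
        top5 = FALSE, direction = "", p_value = NaN,
        stringsAsFactors = FALSE)
      contrib <- genus_contributions(profile, ko)
      if (nrow(contrib) == 0) next
      for (i in seq_len(nrow(contrib))) {
        g <- contrib$genus[i]
        diffr <- genus_ko_differential(profile, design, ko, g, alpha)
        in_top <- contrib$rank[i] <= top_n
        signif <- !is.na(diffr$p_value) && diffr$p_value < alpha
        if (!in_top && !signif) next
        add_node(g, "genus", unname(overall[g]))
        edges[[length(edges) + 1L]] <- data.frame(
          from = g, to = ko, kind = "contribution",
          rank = as.numeric(contrib$rank[i]), top5 = in_top,
          direction = diffr$direction,
          p_value = if (is.na(diffr$p_value)) NaN else diffr$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  vdf <- data.frame(
    name = names(nodes),
    type = vapply(nodes, `[[`, "", "type"),
    mean_abundance = vapply(nodes, `[[`, 0, "mean_abundance"),
    stringsAsFactors = FALSE)
  vdf$top10 <- vdf$type == "genus" & vdf$name %in% top_overall
  vdf$depleted <- vdf$type == "genus" & vdf$name %in% depleted_genera
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0))
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Write / read a contribution network as GraphML
#'
#' Thin wrappers over [igraph::write_graph()] / [igraph::read_graph()];
#' the document parses under any standard GraphML reader and round-trips
#' node and edge attributes.
#'
#' @param graph an igraph, e.g. from [build_module_network()].
#' @param path file path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' Edge-list view of a contribution network
#'
#' @param graph an igraph from [build_module_network()].
#' @return data.frame of edges with their annotations.
#' @export
network_edge_list <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  igraph::as_data_frame(graph, what = "edges")
}
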