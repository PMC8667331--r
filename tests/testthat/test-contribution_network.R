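# Genus contribution ranking, stratified differential testing, and the
# contribution network with its GraphML round-trip.

test_that("genus contributions rank by mean abundance with alphabetical ties", {
  st <- rbind("K00001|g__Beta" = c(10, 10),
              "K00001|g__Alpha" = c(10, 10),
              "K00001|g__Gamma" = c(30, 30))
  colnames(st) <- c("S1", "S2")
  comm <- matrix(c(60, 60), 1, 2, dimnames = list("K00001", c("S1", "S2")))
  p <- ko_profile(comm, st)
  gc <- genus_contributions(p, "K00001")
  expect_equal(gc$genus, c("Gamma", "Alpha", "Beta"))
  expect_equal(gc$rank, 1:3)
  expect_equal(attr(gc, "unclassified_mean"), 10)

  # single-genus KO gets rank 1; KOs without strata warn
  st1 <- matrix(c(5, 5), 1, 2,
                dimnames = list("K00002|g__Solo", c("S1", "S2")))
  p2 <- ko_profile(rbind(comm, K00002 = c(5, 5)), rbind(st, st1))
  expect_equal(genus_contributions(p2, "K00002")$rank, 1)

  # a KO without stratified rows yields an empty ranking with a warning
  p3 <- ko_profile(rbind(comm, K00003 = c(2, 2)), st)
  expect_warning(gc0 <- genus_contributions(p3, "K00003"), "no genus")
  expect_equal(nrow(gc0), 0)
})

test_that("ranks equal a brute-force sort of stratum means", {
  p <- make_profile(n_kos = 5, n_samples = 10, strata = TRUE,
                    n_genera = 4, seed = 15)
  for (ko in ko_ids(p)) {
    gc <- genus_contributions(p, ko)
    st <- ko_strata(p, ko)
    mn <- rowMeans(st[setdiff(rownames(st), "unclassified"), ])
    expect_equal(gc$genus, names(mn)[order(-mn, names(mn))])
    expect_equal(gc$mean_abundance, unname(sort(mn, decreasing = TRUE)))
  }
})

test_that("genus_ko_differential finds planted stratum shifts", {
  mk <- function(mult_case) {
    set.seed(33)
    vals <- rexp(16, 1 / 10)
    vals[1:8] <- vals[1:8] * mult_case
    st <- matrix(vals, 1, dimnames = list("K00001|g__X",
                                          sprintf("S%02d", 1:16)))
    ko_profile(matrix(vals * 1.2, 1,
                      dimnames = list("K00001", sprintf("S%02d", 1:16))),
               st)
  }
  d <- make_design(8, 8)
  up <- genus_ko_differential(mk(10), d, "K00001", "X")
  expect_equal(up$direction, "up_in_case")
  expect_lt(up$p_value, 0.05)

  none <- genus_ko_differential(mk(1), d, "K00001", "X")
  # identical group generation -> label swap symmetry check
  swapped <- d; swapped$group <- rev(swapped$group)
  class(swapped) <- class(d)
  down <- genus_ko_differential(mk(10), swapped, "K00001", "X")
  expect_equal(down$direction, "down_in_case")
  expect_equal(down$p_value, up$p_value)

  # all-zero stratum is degenerate
  z <- mk(1); z$strata[1, ] <- 0
  z <- ko_profile(z$community, z$strata)
  deg <- genus_ko_differential(z, d, "K00001", "X")
  expect_true(deg$degenerate)
  expect_equal(deg$direction, "none")
})

test_that("planted 10-fold stratum enrichment is recovered in most replicates", {
  hits <- vapply(1:20, function(i) {
    set.seed(50000 + i)
    n <- 33
    v <- rexp(n, 1 / 10)
    v[1:22] <- v[1:22] * 10
    st <- matrix(v, 1, dimnames = list("K00001|g__X",
                                       sprintf("S%03d", 1:n)))
    p <- ko_profile(matrix(v, 1, dimnames = list("K00001",
                                                 sprintf("S%03d", 1:n))),
                    st)
    d <- cohort_design(sprintf("S%03d", 1:n),
                       rep(c("case", "control"), c(22, 11)))
    genus_ko_differential(p, d, "K00001", "X")$direction == "up_in_case"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the network contains exactly the carrying genera and typed nodes", {
  sim <- simulate_cohort(default_bcaa_scenario(seed = 9))
  filt <- filter_kos(sim$profile, 5)
  g <- build_module_network(filt, sim$design, sim$module_map, "M00535",
                            depleted_genera =
                              sim$truth$depleted_genera$genus)
  vt <- igraph::V(g)$type
  # M00535's KOs are carried only by Eubacterium and Prevotella
  genera <- igraph::V(g)$name[vt == "genus"]
  expect_setequal(genera, c("Eubacterium", "Prevotella"))
  expect_true(all(igraph::V(g)$depleted[vt == "genus"]))
  expect_equal(sum(vt == "module"), 1)
  expect_equal(sum(vt == "ko"), 4)
  ed <- network_edge_list(g)
  expect_equal(sum(ed$kind == "membership"), 4)
  # per-KO ranks are a permutation of 1..(number of contributing genera)
  for (ko in unique(ed$to[ed$kind == "contribution"])) {
    r <- sort(ed$rank[ed$kind == "contribution" & ed$to == ko])
    expect_equal(r, seq_along(r))
  }
  expect_error(build_module_network(filt, sim$design, sim$module_map,
                                    "M99999"), "unknown")
})

test_that("top5 flags cap at top_n per KO and genus edge sums stay below community", {
  sim <- simulate_cohort(sim_config(n_genera = 12, n_kos = 60,
                                    n_null_modules = 4,
                                    incidence_density = 0.6,
                                    compartments = "plasma", seed = 14))
  filt <- filter_kos(sim$profile, 5)
  mods <- sim$module_map$module_id[1]
  g <- build_module_network(filt, sim$design, sim$module_map, mods)
  ed <- network_edge_list(g)
  contrib <- ed[ed$kind == "contribution", ]
  for (ko in unique(contrib$to)) {
    expect_lte(sum(contrib$top5[contrib$to == ko]), 5)
    # genus mean contributions never exceed the community mean
    st <- ko_strata(filt, ko)
    mns <- rowMeans(st[setdiff(rownames(st), "unclassified"), ,
                       drop = FALSE])
    expect_lte(sum(mns), mean(filt$community[ko, ]) + 1e-9)
  }
})

test_that("contribution graphs round-trip through GraphML", {
  sim <- simulate_cohort(default_bcaa_scenario(seed = 4))
  filt <- filter_kos(sim$profile, 5)
  g <- build_module_network(filt, sim$design, sim$module_map,
                            c("M00535", "M00432"),
                            depleted_genera =
                              sim$truth$depleted_genera$genus)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, tmp)
  g2 <- read_graphml(tmp)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  e1 <- network_edge_list(g); e2 <- network_edge_list(g2)
  ord <- function(d) d[order(d$from, d$to), ]
  expect_equal(ord(e2)$direction, ord(e1)$direction)
  expect_equal(ord(e2)$rank, ord(e1)$rank)
  expect_equal(ord(e2)$p_value, ord(e1)$p_value, tolerance = 1e-9)

  # an independent (non-igraph) GraphML parser sees the same counts
  doc <- xml2::read_xml(tmp)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", ns)),
               igraph::vcount(g))
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", ns)),
               igraph::ecount(g))

  # degenerate cases: tiny and empty graphs still produce valid documents
  tiny <- igraph::make_graph(c("GenusA", "K00001"), directed = TRUE)
  write_graphml(tiny, tmp)
  expect_equal(igraph::vcount(read_graphml(tmp)), 2)
  empty <- igraph::make_empty_graph()
  write_graphml(empty, tmp)
  expect_equal(igraph::vcount(read_graphml(tmp)), 0)
})
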