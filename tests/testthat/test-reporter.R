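# Per-KO differential testing, the p -> Z transform, module aggregation,
# random-set background correction and enrichment calling.

test_that("filter_kos keeps KOs present in strictly more samples than the cutoff", {
  comm <- matrix(0, 3, 8,
                 dimnames = list(c("K00001", "K00002", "K00003"),
                                 sprintf("S%02d", 1:8)))
  comm["K00001", 1:5] <- 1  # exactly 5 samples -> removed at min = 5
  comm["K00002", 1:6] <- 1  # 6 samples -> retained
  p <- filter_kos(ko_profile(comm), min_occurrence = 5)
  expect_equal(ko_ids(p), "K00002")
  expect_warning(filter_kos(ko_profile(comm * 0), 5), "empty")
})

test_that("filter_kos drops the strata of removed KOs", {
  p <- make_profile(n_kos = 4, n_samples = 8, strata = TRUE)
  p$community["K00001", ] <- 0
  p$strata[startsWith(rownames(p$strata), "K00001|"), ] <- 0
  f <- filter_kos(ko_profile(p$community, p$strata), 5)
  expect_false("K00001" %in% ko_ids(f))
  expect_false(any(startsWith(rownames(f$strata), "K00001|")))
})

test_that("one-tailed MWU p-values match exhaustive label enumeration", {
  # spec anchor: case {4,5,6} vs control {1,2,3} -> p = 1/20
  expect_equal(mwu_p(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  expect_equal(enum_mwu_p(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)

  set.seed(7)
  for (m in 3:4) for (n in 3:4) {
    x <- rnorm(m); y <- rnorm(n)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(mwu_p(x, y, alt), enum_mwu_p(x, y, alt),
                   tolerance = 1e-12,
                   info = paste(m, n, alt))
      # and against the stock implementation
      expect_equal(mwu_p(x, y, alt),
                   wilcox.test(x, y, alternative = alt)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 2, 4, 5, 6, 6)
  for (alt in c("greater", "less", "two.sided"))
    expect_equal(mwu_p(x, y, alt),
                 suppressWarnings(
                   wilcox.test(x, y, alternative = alt,
                               correct = TRUE)$p.value),
                 tolerance = 1e-12)
})

test_that("swapping group labels maps one-tailed p to the opposite tail", {
  set.seed(3)
  x <- rnorm(4); y <- rnorm(3)
  p_gt <- mwu_p(x, y, "greater")
  p_swapped <- mwu_p(y, x, "less")
  # same tail of the same exact distribution, seen from the other group
  expect_equal(p_swapped, enum_mwu_p(y, x, "less"))
  expect_equal(p_gt, enum_mwu_p(x, y, "greater"))
})

test_that("ko_differential tests case-greater and counts presence", {
  p <- make_profile(n_kos = 5, n_samples = 8)
  d <- make_design(4, 4)
  res <- ko_differential(p, d)
  expect_equal(res$ko_id, ko_ids(p))
  for (i in seq_len(nrow(res)))
    expect_equal(res$p_value[i],
                 mwu_p(p$community[i, 1:4], p$community[i, 5:8],
                       "greater"))
  expect_equal(res$n_present, unname(rowSums(p$community > 0)))
  # identical case and control multisets cannot favour the case group
  comm <- matrix(rep(c(1, 5, 2, 9, 1, 5, 2, 9), 2), 2, byrow = TRUE,
                 dimnames = list(c("K00001", "K00002"),
                                 sprintf("S%02d", 1:8)))
  res0 <- ko_differential(ko_profile(comm), make_design(4, 4))
  expect_true(all(res0$p_value >= 0.5))
})

test_that("p_to_z implements both transform variants", {
  res <- data.frame(ko_id = sprintf("K%05d", 1:4),
                    n_present = 8,
                    p_value = c(0.5, 0.05, 0.2, 0.8),
                    z = NA_real_)
  z1 <- p_to_z(res, reporter_config(z_variant = "inverse_normal"))
  expect_equal(z1$z[1], 0)
  expect_equal(z1$z[2], qnorm(0.95), tolerance = 1e-12)
  expect_equal(z1$z[2], 1.6449, tolerance = 1e-4)

  z2 <- p_to_z(res, reporter_config(z_variant = "literal_standardized_p"))
  expect_equal(z2$z, (res$p_value - mean(res$p_value)) / sd(res$p_value))
  expect_error(p_to_z(res[1, ],
                      reporter_config(z_variant = "literal_standardized_p")),
               "at least 2")

  # clipping keeps z finite at exact p = 0 / 1
  res$p_value <- c(0, 1, 0.5, 0.5)
  zc <- p_to_z(res, reporter_config())
  expect_true(all(is.finite(zc$z)))
})

test_that("module raw scores equal sum(z)/sqrt(k) with dropped-KO bookkeeping", {
  z <- data.frame(ko_id = sprintf("K%05d", 1:6), n_present = 8,
                  p_value = 0.5, z = c(2, 2, 2, 2, 1.3, -0.7))
  mm <- module_map(c("M00001", "M00002", "M00003"),
                   list(sprintf("K%05d", 1:4),
                        "K00005",
                        c("K00006", "K99999")),  # K99999 untested
                   label = c("four", "one", "partial"))
  sc <- module_scores(z, mm)
  expect_equal(sc$raw[1], 8 / 2)          # {2,2,2,2}: 8/sqrt(4)
  expect_equal(sc$raw[2], 1.3)            # k = 1
  expect_equal(sc$k[3], 1)
  expect_equal(sc$coverage[3], 0.5)
  expect_equal(sc$raw[3], -0.7)

  # brute-force recomputation on random z, module = all KOs
  set.seed(11)
  z$z <- rnorm(6)
  mm_all <- module_map("M00009", list(z$ko_id))
  expect_equal(module_scores(z, mm_all)$raw,
               sum(z$z) / sqrt(6), tolerance = 1e-12)

  # modules with no tested KO are omitted with a warning
  mm_none <- module_map(c("M00001", "M00002"),
                        list("K88888", "K00001"))
  expect_warning(sc2 <- module_scores(z, mm_none), "omitted")
  expect_equal(sc2$module_id, "M00002")
})

test_that("background correction standardises against random same-k sets", {
  set.seed(21)
  z <- data.frame(ko_id = sprintf("K%05d", 1:200), n_present = 33,
                  p_value = 0.5, z = rnorm(200))
  mm <- module_map(sprintf("M%05d", 1:40),
                   lapply(1:40, function(i) sample(z$ko_id, 5)))
  cfg <- reporter_config(n_random_sets = 1000, seed = 4)
  sc <- background_correct(module_scores(z, mm), z, cfg)
  # identity raw = adjusted * sd + mean holds exactly
  expect_equal(sc$adjusted * sc$bg_sd + sc$bg_mean, sc$raw,
               tolerance = 1e-12)
  # same seed -> identical backgrounds
  sc2 <- background_correct(module_scores(z, mm), z, cfg)
  expect_identical(sc$bg_mean, sc2$bg_mean)
  expect_identical(sc$bg_sd, sc2$bg_sd)
  # null modules: adjusted approximately standard normal
  expect_lt(abs(mean(sc$adjusted)), 0.5)

  # degenerate universe: all z equal -> sd 0 -> undefined adjusted
  zc <- z; zc$z <- rep(1.5, 200)
  expect_warning(scd <- background_correct(module_scores(zc, mm), zc, cfg),
                 "degenerate")
  expect_true(all(is.na(scd$adjusted)))
  # k larger than the universe is an error
  mm_big <- module_map("M00001", list(sprintf("K%05d", 1:10)))
  z_small <- z[1:5, ]
  sc_big <- module_scores(z, mm_big)
  expect_error(background_correct(sc_big, z_small, cfg), "universe")
})

test_that("enrichment calls respect the inclusive 1.6 threshold", {
  sc <- data.frame(module_id = sprintf("M%05d", 1:4),
                   adjusted = c(1.60, -1.59, -1.60, NA))
  out <- call_enrichment(sc, reporter_config())
  expect_equal(out$call,
               c("enriched_case", "none", "enriched_control", "none"))
})

test_that("label swap flips module raw scores on continuous data", {
  sim <- simulate_cohort(sim_config(n_kos = 80, n_null_modules = 10,
                                    compartments = "plasma", seed = 13))
  cfg <- reporter_config(n_random_sets = 200, seed = 13)
  swap <- sim$design
  swap$group <- ifelse(swap$group == "case", "control", "case")
  class(swap) <- class(sim$design)
  z1 <- p_to_z(ko_differential(filter_kos(sim$profile, 5), sim$design), cfg)
  z2 <- p_to_z(ko_differential(filter_kos(sim$profile, 5), swap), cfg)
  # per-KO antisymmetry up to the exact-test tail asymmetry P(U = u)
  expect_true(all(abs(z1$z + z2$z) < 0.05))
  r1 <- module_scores(z1, sim$module_map)
  r2 <- module_scores(z2, sim$module_map)
  # module raw scores change sign; the per-KO tail asymmetry accumulates
  # over k members, bounding the residual by 0.05 * sqrt(k)
  expect_true(all(abs(r1$raw + r2$raw) < 0.05 * sqrt(r1$k)))
  away <- abs(r1$raw) > 0.3
  expect_true(all(sign(r2$raw[away]) == -sign(r1$raw[away])))
})
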