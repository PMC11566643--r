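make_edge <- function(prototype_id, feature_id, category = "predictable",
                      pathway = "oxidation", total = 90, retained = TRUE) {
  data.frame(prototype_id = prototype_id, feature_id = feature_id,
             category = category, pathway = pathway, n_steps = 1L,
             match_degree = 1L, delta_ppm = 0, base = 70,
             ms2_similarity = 20, ms2_defect_bonus = 0, confidence = 0,
             total = total, retained = retained, stringsAsFactors = FALSE)
}

test_that("one prototype with three retained edges is a single component", {
  protos <- make_prototypes(mz = 457.1478, rt = 5, compound_id = "P1")
  feats <- make_features(mz = c(295.1, 473.14, 633.2), rt = c(2, 4, 6),
                         feature_id = c("a", "b", "c"))
  feats$category <- "predictable"
  edges <- rbind(make_edge("P1", "a"), make_edge("P1", "b"),
                 make_edge("P1", "c"))
  net <- build_network(edges, protos, feats)
  expect_equal(net$summary$n_components, 1L)
  expect_equal(igraph::vcount(net$graph), 4L)
  expect_true(all(net$components$family == "P1"))
})

test_that("disjoint families give separate components that a shared metabolite merges", {
  protos <- make_prototypes(mz = c(457.1478, 295.1056), rt = c(5, 7),
                            compound_id = c("AMY", "PRU"))
  feats <- make_features(mz = c(295.1, 311.1, 473.14), rt = c(2, 4, 6),
                         feature_id = c("a", "b", "c"))
  disjoint <- rbind(make_edge("AMY", "a"), make_edge("PRU", "b"))
  net2 <- build_network(disjoint, protos, feats)
  # c is an isolated elusive feature: 2 family components + 1 singleton
  expect_equal(net2$summary$n_components, 3L)
  fam <- net2$components$family
  expect_setequal(stats::na.omit(unique(fam)), c("AMY", "PRU"))

  # a metabolite bridging both prototypes merges the families
  bridged <- rbind(disjoint, make_edge("AMY", "b", total = 75))
  net1 <- build_network(bridged, protos, feats)
  expect_equal(net1$summary$n_components, 2L)  # merged family + singleton c
})

test_that("dangling edge endpoints are an integrity error", {
  protos <- make_prototypes(mz = 457.1478, rt = 5, compound_id = "P1")
  feats <- make_features(mz = 295.1, rt = 2, feature_id = "a")
  expect_error(build_network(make_edge("P1", "ghost"), protos, feats),
               "endpoint")
  expect_error(build_network(make_edge("P9", "a"), protos, feats),
               "endpoint")
})

test_that("duplicate (prototype, feature, pathway) edges are rejected", {
  protos <- make_prototypes(mz = 457.1478, rt = 5, compound_id = "P1")
  feats <- make_features(mz = 295.1, rt = 2, feature_id = "a")
  expect_error(build_network(rbind(make_edge("P1", "a"),
                                   make_edge("P1", "a")),
                             protos, feats),
               "duplicate")
})

test_that("matrix summaries report the characterized fraction", {
  protos <- make_prototypes(mz = 457.1478, rt = 5, compound_id = "P1")
  feats <- make_features(mz = c(295.1, 311.1), rt = c(2, 4),
                         matrix = c("plasma", "plasma"),
                         feature_id = c("a", "b"))
  all_matched <- build_network(rbind(make_edge("P1", "a"),
                                     make_edge("P1", "b")),
                               protos, feats)
  ms <- matrix_summary(all_matched)
  expect_equal(ms$characterized_fraction[ms$matrix == "plasma"], 1.0)

  none <- build_network(make_edge("P1", "a", retained = FALSE),
                        protos, feats)
  ms0 <- matrix_summary(none)
  expect_equal(ms0$characterized_fraction[ms0$matrix == "plasma"], 0.0)
})

test_that("exposure fractions are intensity shares per polarity", {
  protos <- make_prototypes(mz = c(457.1478, 295.1056), rt = c(5, 7),
                            compound_id = c("AMY", "PRU"))
  feats <- make_features(mz = c(295.1, 311.1), rt = c(2, 4),
                         intensity = c(4e5, 4e5),
                         feature_id = c("a", "b"))
  # both features in AMY's family
  net <- build_network(rbind(make_edge("AMY", "a"), make_edge("AMY", "b")),
                       protos, feats)
  expect_equal(exposure_fraction(net, "AMY")$percent, 100)
  # equal-intensity features split across families: 50% each
  split <- build_network(rbind(make_edge("AMY", "a"), make_edge("PRU", "b")),
                         protos, feats)
  expect_equal(exposure_fraction(split, "AMY")$percent, 50)
  expect_equal(exposure_fraction(split, "PRU")$percent, 50)
  # fractions over a partition of the features sum to 100%
  expect_equal(exposure_fraction(split, "AMY")$percent +
                 exposure_fraction(split, "PRU")$percent, 100)
})

test_that("a planted exposure share is recovered exactly", {
  protos <- make_prototypes(mz = c(457.1478, 295.1056), rt = c(5, 7),
                            compound_id = c("AMY", "PRU"))
  feats <- make_features(mz = c(295.1, 311.1), rt = c(2, 4),
                         intensity = c(43.16, 100 - 43.16),
                         feature_id = c("a", "b"))
  net <- build_network(rbind(make_edge("AMY", "a"), make_edge("PRU", "b")),
                       protos, feats)
  expect_equal(exposure_fraction(net, "AMY")$percent, 43.16,
               tolerance = 1e-9)
})

test_that("component structure is invariant under edge permutation", {
  sim <- simulate_herb(sim_config(seed = 21, n_endogenous = 0))
  net <- run_mdrb(sim$prototypes, sim$features)
  edges <- net$edges
  set.seed(1)
  shuffled <- edges[sample(nrow(edges)), ]
  net2 <- build_network(shuffled, net$prototypes, net$features)
  expect_equal(net2$summary$n_components, net$summary$n_components)
  m1 <- net$components[order(net$components$name), ]
  m2 <- net2$components[order(net2$components$name), ]
  expect_equal(m1$family, m2$family)
})
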