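test_that("prototype vs isomer assignment follows the RT and ppm windows", {
  proto <- make_prototypes(mz = 457.1478, rt = 10.2,
                           ms2 = list(frags(c(151.1, 221.3))))
  params <- mdrb_params()
  f1 <- make_features(mz = 457.1477, rt = 10.0)   # 12 s, 0.2 ppm
  e1 <- match_prototype(f1, proto, params)
  expect_equal(e1$category, "prototype")
  expect_equal(e1$total, 100)
  expect_equal(e1$pathway, "")
  expect_true(e1$retained)

  f2 <- make_features(mz = 457.1477, rt = 12.2)   # 120 s away
  expect_equal(match_prototype(f2, proto, params)$category, "isomer")

  f3 <- make_features(mz = 457.1478 * (1 + 20e-6), rt = 10.0)
  expect_null(match_prototype(f3, proto, params))

  f4 <- make_features(mz = 457.1477, rt = 10.0, polarity = "positive")
  expect_null(match_prototype(f4, proto, params))
})

test_that("MS2 similarity scoring assigns the published tiers", {
  params <- mdrb_params()
  p <- frags(c(119.035, 161.0455, 263.0925))
  # three exact matches
  s3 <- score_ms2(p, p, params, precursor_mz = 294.0983)
  expect_equal(s3$match_degree, 3L)
  expect_equal(s3$similarity, 30)
  expect_equal(s3$defect_bonus, 0)
  # one exact match
  s1 <- score_ms2(frags(161.0455), p, params, precursor_mz = 294.0983)
  expect_equal(s1$match_degree, 1L)
  expect_equal(s1$similarity, 20)
  # two exact matches
  s2 <- score_ms2(frags(c(119.035, 263.0925)), p, params, 294.0983)
  expect_equal(s2$similarity, 30)
  # empty vs empty
  s0 <- score_ms2(frags(numeric(0)), frags(numeric(0)), params)
  expect_equal(unlist(s0[c("match_degree", "similarity", "defect_bonus",
                           "confidence")]),
               c(match_degree = 0, similarity = 0, defect_bonus = 0,
                 confidence = 0))
})

test_that("defect-tier fragment pairs extend the degree at 5 points each", {
  params <- mdrb_params()
  p <- frags(c(150.1000, 210.1200))
  # shifted by ~10 amu with defect differences of 10 and 5 mmu: no exact
  # match, two defect matches
  f <- frags(c(160.1100, 220.1150))
  s <- score_ms2(f, p, params, precursor_mz = 310.11)
  expect_equal(s$n_exact, 0L)
  expect_equal(s$n_defect, 2L)
  expect_equal(s$match_degree, 2L)
  expect_equal(s$similarity, 0)     # the 20/30 tier counts exact matches
  expect_equal(s$defect_bonus, 10)
  # under the pooled reading the same pair reaches the 30-point tier
  pooled <- mdrb_params(pooled_degree_scoring = TRUE)
  expect_equal(score_ms2(f, p, pooled, 310.11)$similarity, 30)
  # outside the 50 amu window no defect match is possible
  far <- frags(c(330.1000, 340.1200))
  expect_equal(score_ms2(far, p, params, 350.1)$match_degree, 0L)
})

test_that("fragment pairing is one-to-one", {
  params <- mdrb_params()
  p <- frags(100.0000)
  f <- frags(c(99.9995, 100.0005))
  s <- score_ms2(f, p, params, 200.0)
  expect_equal(s$n_exact, 1L)
  # the leftover feature fragment cannot re-use the paired prototype fragment
  expect_equal(s$n_defect, 0L)
  expect_equal(s$match_degree, 1L)
})

test_that("predictable matching screens on the predicted mass at 5 ppm", {
  wx <- worked_example(3)
  params <- mdrb_params()
  pathways <- enumerate_pathways(default_catalog())
  edges <- match_predictable(wx$features, wx$prototypes, pathways, params)
  hex <- edges[edges$pathway == "deglycosylation (hexose)", ]
  expect_equal(nrow(hex), 1L)
  expect_equal(hex$base, 70)
  expect_equal(hex$total, 100)
  expect_true(hex$retained)
  expect_lt(abs(hex$delta_ppm), 0.01)

  # 50 ppm off the predicted mass: no pathway can absorb the error
  off <- wx$features
  off$mz <- off$mz * (1 + 50e-6)
  expect_equal(nrow(match_predictable(off, wx$prototypes, pathways, params)),
               0L)
})

test_that("candidates without MS2 stay at base score with degree missing", {
  wx <- worked_example(3)
  params <- mdrb_params()
  pathways <- enumerate_pathways(default_catalog())
  bare <- wx$features
  bare$ms2 <- I(list(frags(numeric(0))))
  edges <- match_predictable(bare, wx$prototypes, pathways, params)
  hex <- edges[edges$pathway == "deglycosylation (hexose)", ]
  expect_equal(hex$total, 70)
  expect_true(hex$retained)
  expect_true(is.na(hex$match_degree))
})

test_that("predictable candidates sharing no fragment are not retained", {
  wx <- worked_example(3)
  params <- mdrb_params()
  pathways <- enumerate_pathways(default_catalog())
  nomatch <- wx$features
  # fragments far from the prototype's in both m/z and defect
  nomatch$ms2 <- I(list(frags(c(88.5250, 250.4100))))
  edges <- match_predictable(nomatch, wx$prototypes, pathways, params)
  hex <- edges[edges$pathway == "deglycosylation (hexose)", ]
  expect_equal(hex$ms2_similarity, 0)
  expect_equal(hex$match_degree, 0L)
  expect_false(hex$retained)
})

test_that("unpredictable matching uses MS1 proximity plus mass defect", {
  params <- mdrb_params()
  proto <- make_prototypes(mz = 457.1478, rt = 5,
                           ms2 = list(frags(c(151.1, 221.3))))
  f <- make_features(mz = 475.1583, rt = 8)  # +18.0105, defect diff 10.5 mmu
  e <- match_unpredictable(f, proto, params, default_catalog())
  expect_equal(e$base, 50)
  expect_match(e$pathway, "hydration")
  expect_match(e$pathway, "\\+18.010")

  far <- make_features(mz = 600.20, rt = 8)  # 143 amu away
  expect_null(match_unpredictable(far, proto, params))

  defect_off <- make_features(mz = 475.2100, rt = 8)  # 62 mmu defect shift
  expect_null(match_unpredictable(defect_off, proto, params))

  # base 50, no MS2: lands exactly on the retention threshold
  expect_equal(e$total, 50)
  expect_true(e$retained)
  strict <- mdrb_params(retention_score = 55)
  expect_false(match_unpredictable(f, proto, strict)$retained)
})

test_that("a self-matched metabolite list yields only prototype edges", {
  set.seed(5)
  protos <- make_prototypes(mz = sort(runif(5, 150, 800)),
                            rt = runif(5, 1, 20))
  feats <- make_features(mz = protos$mz, rt = protos$rt,
                         feature_id = paste0("F_", protos$compound_id))
  net <- run_mdrb(protos, feats)
  expect_true(all(net$edges$category == "prototype"))
  expect_equal(nrow(net$edges), 5L)
  expect_true(all(net$features$category == "prototype"))
})

test_that("a signal matched by two prototypes keeps both edges, ranked", {
  base <- formula_mass("C20H27NO11")
  frag_set <- frags(c(119.035, 161.0455, 263.0925))
  protoA <- list(mz = mz_from_neutral(base, "M-H"), ms2 = frag_set)
  # prototype B sits 13.979 Da above A, so that A + oxidation and
  # B + reduction predict the same metabolite mass
  protoB <- list(mz = mz_from_neutral(base + formula_mass("+O-H2"), "M-H"),
                 ms2 = frags(c(161.0455, 350.21, 370.88)))
  protos <- make_prototypes(
    mz = c(protoA$mz, protoB$mz), rt = c(5, 9),
    ms2 = list(protoA$ms2, protoB$ms2),
    compound_id = c("A", "B")
  )
  feat <- make_features(
    mz = mz_from_neutral(base + formula_mass("+O"), "M-H"), rt = 12,
    adduct = "M-H", ms2 = list(frag_set), feature_id = "MET1"
  )
  net <- run_mdrb(protos, feat)
  retained <- net$edges[net$edges$retained, ]
  perproto <- tapply(retained$total, retained$prototype_id, max)
  expect_equal(unname(perproto[["A"]]), 100)  # three shared fragments
  expect_equal(unname(perproto[["B"]]), 90)   # one shared fragment
  best <- retained[retained$rank == 1L, ]
  expect_equal(unique(best$prototype_id), "A")
  expect_gt(min(retained$rank[retained$prototype_id == "B"]),
            max(retained$rank[retained$prototype_id == "A" &
                                retained$total == 100]))
})

test_that("an empty prototype list is a configuration error", {
  feats <- make_features(mz = 200.1, rt = 1)
  protos <- make_prototypes(mz = 300.1, rt = 1)[0, ]
  expect_error(run_mdrb(protos, feats), "empty")
  expect_error(run_mdrb(make_prototypes(mz = 300.1, rt = 1), feats[0, ]),
               "empty")
})

test_that("score totals stay on the 5-point lattice", {
  sim <- simulate_herb(sim_config(seed = 9, n_endogenous = 0))
  net <- run_mdrb(sim$prototypes, sim$features)
  e <- net$edges
  expect_true(all(e$total == e$base + e$ms2_similarity + e$ms2_defect_bonus))
  expect_true(all(e$base %in% c(50, 70, 100)))
  expect_true(all(e$ms2_similarity %in% c(0, 20, 30)))
  expect_true(all(e$ms2_defect_bonus %% 5 == 0))
  expect_true(all(e$confidence %in% c(0, 2)))
  expect_true(all(e$total %% 5 == 0))
})

test_that("adding a matching fragment never lowers a candidate's total", {
  params <- mdrb_params()
  set.seed(17)
  for (rep in 1:20) {
    np <- sample(2:6, 1)
    p <- frags(sort(runif(np, 80, 400)), rlnorm(np, 10, 1))
    nf <- sample(0:4, 1)
    keep <- sample(np, min(nf, np))
    f <- frags(p$mz[keep] + rnorm(length(keep), 0, 0.002),
               rlnorm(length(keep), 10, 1))
    before <- score_ms2(f, p, params, 450.1)
    unused <- setdiff(seq_len(np), keep)
    if (!length(unused)) next
    f2 <- rbind(f, frags(p$mz[unused[1]], 500))
    after <- score_ms2(f2, p, params, 450.1)
    expect_gte(after$similarity + after$defect_bonus,
               before$similarity + before$defect_bonus)
    expect_gte(after$match_degree, before$match_degree)
  }
})

test_that("the 2-point MS1/MS2 confidence is reported, not totalled", {
  wx <- worked_example(3)
  net <- run_mdrb(wx$prototypes, wx$features)
  hex <- net$edges[net$edges$pathway == "deglycosylation (hexose)", ]
  expect_equal(hex$confidence, 2)
  expect_equal(hex$total, 100)
  with_conf <- run_mdrb(wx$prototypes, wx$features,
                        params = mdrb_params(include_confidence_in_total = TRUE))
  hex2 <- with_conf$edges[with_conf$edges$pathway ==
                            "deglycosylation (hexose)", ]
  expect_equal(hex2$total, 102)
})

test_that("widening the MS1 defect window never loses candidates", {
  sim <- simulate_herb(sim_config(seed = 13))
  sw <- sweep_defect_window(sim$prototypes, sim$features,
                            tols = c(10, 25, 50, 75))
  expect_true(all(diff(sw$n_candidates) >= 0))
  expect_equal(sw$defect_tol_mmu, c(10, 25, 50, 75))
})
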