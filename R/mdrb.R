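# Mass dataset relevance bridging (MDRB): stepwise matching of an in vivo
# component list against an herb prototype list.
#
# Step 1 characterizes prototypes (m/z within +/- 5 ppm, RT within +/- 25 s)
# and isomers (m/z only). Step 2 screens predictable metabolites: a feature
# whose neutral mass sits within +/- 5 ppm of prototype mass + a one- or
# two-step catalog pathway is a candidate with base score 70. Step 3 screens
# unpredictable metabolites: within +/- 100 amu of the prototype and with a
# mass-defect difference of +/- 25 mmu or less, base score 50. MS2 fragment
# similarity then adds 20 (match degree 1) or 30 (degree >= 2) points, MS2
# mass-defect matches add 5 points each, and candidates are retained when the
# total reaches the retention score (50).

#' MDRB matching parameters
#'
#' Defaults are the published screening standards of the scoring mechanism.
#'
#' @param rt_tol Prototype RT tolerance, seconds (default 25).
#' @param mz_tol m/z tolerance, ppm (default 5), applied to the predicted
#'   metabolite mass in the predictable pass.
#' @param ms1_window MS1 proximity window for the unpredictable pass, amu
#'   (default 100).
#' @param ms1_defect_tol MS1 mass-defect window, mmu (default 25).
#' @param ms2_window MS2 fragment proximity window for defect matching, amu
#'   (default 50).
#' @param ms2_defect_tol MS2 mass-defect window, mmu (default 25).
#' @param ms2_frag_tol Exact MS2 fragment match tolerance, Da (default 0.01).
#' @param ms1_ms2_defect_tol Precursor-to-fragment defect window for the
#'   2-point confidence flag, mmu (default 50).
#' @param retention_score Minimum total for an unpredictable candidate to be
#'   kept (default 50).
#' @param max_delta_n N-rule: maximum |net nitrogen change| along a pathway
#'   (default 3).
#' @param include_confidence_in_total Add the 2-point MS1/MS2 defect
#'   confidence into the total (default FALSE; it is reported separately).
#' @param pooled_degree_scoring If TRUE, the 20/30-point similarity tier is
#'   computed from the pooled match degree (exact + defect matches) instead
#'   of exact fragment matches only. Default FALSE; see the methods vignette.
#' @return An `mdrb_params` object.
#' @export
mdrb_params <- function(rt_tol = 25, mz_tol = 5, ms1_window = 100,
                        ms1_defect_tol = 25, ms2_window = 50,
                        ms2_defect_tol = 25, ms2_frag_tol = 0.01,
                        ms1_ms2_defect_tol = 50, retention_score = 50,
                        max_delta_n = 3L,
                        include_confidence_in_total = FALSE,
                        pooled_degree_scoring = FALSE) {
  p <- list(rt_tol = rt_tol, mz_tol = mz_tol, ms1_window = ms1_window,
            ms1_defect_tol = ms1_defect_tol, ms2_window = ms2_window,
            ms2_defect_tol = ms2_defect_tol, ms2_frag_tol = ms2_frag_tol,
            ms1_ms2_defect_tol = ms1_ms2_defect_tol,
            retention_score = retention_score,
            max_delta_n = as.integer(max_delta_n),
            include_confidence_in_total = isTRUE(include_confidence_in_total),
            pooled_degree_scoring = isTRUE(pooled_degree_scoring))
  num <- c("rt_tol", "mz_tol", "ms1_window", "ms1_defect_tol", "ms2_window",
           "ms2_defect_tol", "ms2_frag_tol", "ms1_ms2_defect_tol")
  if (any(vapply(p[num], function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all MDRB tolerances must be positive", call. = FALSE)
  }
  if (p$retention_score < 0) {
    stop("retention_score must be >= 0", call. = FALSE)
  }
  structure(p, class = "mdrb_params")
}

#' Score MS2 fragment similarity between a candidate and a prototype
#'
#' Fragments are first paired one-to-one by exact m/z agreement (within
#' `ms2_frag_tol`, greedy nearest pairing, ties broken toward higher summed
#' intensity, each fragment used once). Unpaired fragments are then paired by
#' the MS2 mass-defect standard: within `ms2_window` amu and a defect
#' difference of at most `ms2_defect_tol` mmu. Each defect pair raises the
#' match degree by one and contributes 5 points. The 20/30-point similarity
#' tier is assigned from the exact-match count (or the pooled degree when
#' `pooled_degree_scoring` is set). A separate 2-point confidence flag marks
#' candidates holding a fragment whose mass defect agrees with the precursor
#' defect within `ms1_ms2_defect_tol` mmu.
#'
#' @param feature_ms2,prototype_ms2 Fragment data.frames (`mz`, `intensity`).
#' @param params An [mdrb_params()] object.
#' @param precursor_mz Precursor m/z of the candidate feature (for the
#'   confidence flag); `NA` disables it.
#' @return A list with `match_degree`, `similarity`, `defect_bonus`,
#'   `confidence`, `n_exact`, `n_defect`.
#' @export
score_ms2 <- function(feature_ms2, prototype_ms2, params = mdrb_params(),
                      precursor_mz = NA_real_) {
  f <- feature_ms2
  p <- prototype_ms2
  nf <- if (is.null(f)) 0L else nrow(f)
  np <- if (is.null(p)) 0L else nrow(p)
  f_used <- logical(nf)
  p_used <- logical(np)
  n_exact <- 0L
  first_exact_frag <- NA_real_
  if (nf > 0L && np > 0L) {
    d <- abs(outer(f$mz, p$mz, "-"))
    cand <- which(d <= params$ms2_frag_tol, arr.ind = TRUE)
    if (nrow(cand)) {
      pri <- f$intensity[cand[, 1L]] + p$intensity[cand[, 2L]]
      ord <- order(d[cand], -pri)
      for (k in ord) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (f_used[i] || p_used[j]) next
        f_used[i] <- TRUE; p_used[j] <- TRUE
        n_exact <- n_exact + 1L
        if (is.na(first_exact_frag)) first_exact_frag <- f$mz[i]
      }
    }
  }
  n_defect <- 0L
  if (nf > 0L && np > 0L && any(!f_used) && any(!p_used)) {
    fi <- which(!f_used); pj <- which(!p_used)
    d <- abs(outer(f$mz[fi], p$mz[pj], "-"))
    dd <- abs(outer(mass_defect(f$mz[fi], warn_half = FALSE),
                    mass_defect(p$mz[pj], warn_half = FALSE), "-"))
    cand <- which(d <= params$ms2_window & dd <= params$ms2_defect_tol,
                  arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dd[cand], d[cand])
      for (k in ord) {
        i <- fi[cand[k, 1L]]; j <- pj[cand[k, 2L]]
        if (f_used[i] || p_used[j]) next
        f_used[i] <- TRUE; p_used[j] <- TRUE
        n_defect <- n_defect + 1L
      }
    }
  }
  degree <- n_exact + n_defect
  tier_basis <- if (params$pooled_degree_scoring) degree else n_exact
  similarity <- if (tier_basis >= 2L) 30 else if (tier_basis == 1L) 20 else 0
  confidence <- 0
  if (nf > 0L && !is.na(precursor_mz)) {
    # best fragment = the one whose defect is closest to the precursor's
    dd <- min(abs(mass_defect(precursor_mz, warn_half = FALSE) -
                  mass_defect(f$mz, warn_half = FALSE)))
    if (dd <= params$ms1_ms2_defect_tol) confidence <- 2
  }
  list(match_degree = degree, similarity = similarity,
       defect_bonus = 5 * n_defect, confidence = confidence,
       n_exact = n_exact, n_defect = n_defect)
}

.edge_row <- function(prototype_id, feature_id, category, pathway, n_steps,
                      match_degree, delta_ppm, base, similarity, bonus,
                      confidence, retained, params) {
  total <- base + similarity + bonus +
    if (params$include_confidence_in_total) confidence else 0
  data.frame(prototype_id = prototype_id, feature_id = feature_id,
             category = category, pathway = pathway, n_steps = n_steps,
             match_degree = match_degree, delta_ppm = delta_ppm, base = base,
             ms2_similarity = similarity, ms2_defect_bonus = bonus,
             confidence = confidence, total = total, retained = retained,
             stringsAsFactors = FALSE)
}

.empty_edges <- function() {
  data.frame(prototype_id = character(0), feature_id = character(0),
             category = character(0), pathway = character(0),
             n_steps = integer(0), match_degree = integer(0),
             delta_ppm = numeric(0), base = numeric(0),
             ms2_similarity = numeric(0), ms2_defect_bonus = numeric(0),
             confidence = numeric(0), total = numeric(0),
             retained = logical(0), stringsAsFactors = FALSE)
}

# neutral-mass hypothesis for a feature: annotated adduct when present,
# otherwise the polarity's primary adduct
.feature_neutral <- function(feature) {
  ad <- feature$adduct
  if (is.na(ad) || !nzchar(ad)) ad <- default_adduct(feature$polarity)
  neutral_mass(feature$mz, ad)
}

#' Match a feature against one prototype (prototype/isomer step)
#'
#' A feature is the prototype itself when both m/z (within `mz_tol` ppm) and
#' RT (within `rt_tol` s) agree, and an isomer when only m/z agrees.
#' Prototype and isomer edges carry no pathway and a sentinel full score of
#' 100.
#'
#' @param feature,prototype Single-row feature / prototype data.frames.
#' @param params An [mdrb_params()] object.
#' @return A one-row edge data.frame, or `NULL` when m/z does not match.
#' @export
match_prototype <- function(feature, prototype, params = mdrb_params()) {
  if (feature$polarity != prototype$polarity) return(NULL)
  dppm <- (feature$mz - prototype$mz) / prototype$mz * 1e6
  if (abs(dppm) > params$mz_tol) return(NULL)
  drt_s <- abs(feature$rt - prototype$rt) * 60
  category <- if (drt_s <= params$rt_tol) "prototype" else "isomer"
  .edge_row(prototype$compound_id, feature$feature_id, category,
            pathway = "", n_steps = 0L, match_degree = NA_integer_,
            delta_ppm = dppm, base = 100, similarity = 0, bonus = 0,
            confidence = 0, retained = TRUE, params)
}

#' Match a feature against one prototype through catalog pathways
#'
#' For every enumerated pathway whose predicted mass (prototype neutral mass
#' plus net pathway delta) agrees with the feature's neutral mass within
#' `mz_tol` ppm of the predicted mass, a candidate edge with base score 70 is
#' produced and its MS2 similarity scored. Candidates whose feature carries
#' MS2 but shares no fragment (match degree 0) are marked not retained; MS1-
#' only features are retained at base score with the match degree recorded as
#' missing.
#'
#' @param feature,prototype Single-row feature / prototype data.frames.
#' @param pathways Output of [enumerate_pathways()].
#' @param params An [mdrb_params()] object.
#' @return An edge data.frame (possibly empty).
#' @export
match_predictable <- function(feature, prototype, pathways,
                              params = mdrb_params()) {
  if (feature$polarity != prototype$polarity) return(.empty_edges())
  fn <- .feature_neutral(feature)
  predicted <- prototype$neutral_mass + pathways$delta_mass
  dppm <- (fn - predicted) / predicted * 1e6
  ok <- predicted > 0 & abs(dppm) <= params$mz_tol
  # N-rule feasibility against the prototype's known nitrogen count
  if (!is.na(prototype$n_count)) {
    ok <- ok & (prototype$n_count + pathways$delta_n >= 0)
  }
  hits <- which(ok)
  if (!length(hits)) return(.empty_edges())
  fms2 <- feature$ms2[[1L]]
  pms2 <- prototype$ms2[[1L]]
  s <- score_ms2(fms2, pms2, params, precursor_mz = feature$mz)
  has_ms2 <- !is.null(fms2) && nrow(fms2) > 0L
  rows <- lapply(hits, function(h) {
    if (has_ms2) {
      .edge_row(prototype$compound_id, feature$feature_id, "predictable",
                pathways$pathway[h], pathways$n_steps[h],
                as.integer(s$match_degree), dppm[h], base = 70,
                similarity = s$similarity, bonus = s$defect_bonus,
                confidence = s$confidence,
                retained = s$match_degree > 0L, params)
    } else {
      .edge_row(prototype$compound_id, feature$feature_id, "predictable",
                pathways$pathway[h], pathways$n_steps[h],
                match_degree = NA_integer_, dppm[h], base = 70,
                similarity = 0, bonus = 0, confidence = 0,
                retained = TRUE, params)
    }
  })
  do.call(rbind, rows)
}

#' Match a feature against one prototype by MS1 proximity and mass defect
#'
#' The unpredictable-metabolite screen: the feature must fall within
#' `ms1_window` amu of the prototype and the two mass defects must agree
#' within `ms1_defect_tol` mmu. Candidates start at base score 50, MS2 is
#' scored exactly as for predictable candidates, and the edge is retained
#' when the total reaches `retention_score`. The pathway field records the
#' signed mass difference, annotated with a catalog rule when one matches it
#' within 5 mmu.
#'
#' @param feature,prototype Single-row feature / prototype data.frames.
#' @param params An [mdrb_params()] object.
#' @param catalog Optional `pathway_catalog` used to annotate the mass
#'   difference.
#' @return A one-row edge data.frame, or `NULL` when the screen fails.
#' @export
match_unpredictable <- function(feature, prototype, params = mdrb_params(),
                                catalog = NULL) {
  if (feature$polarity != prototype$polarity) return(NULL)
  if (!is.na(feature$adduct) && nzchar(feature$adduct)) {
    fm <- neutral_mass(feature$mz, feature$adduct)
    pm <- prototype$neutral_mass
  } else {
    fm <- feature$mz
    pm <- prototype$mz
  }
  delta <- fm - pm
  if (abs(delta) > params$ms1_window) return(NULL)
  dd <- abs(mass_defect(fm, warn_half = FALSE) -
            mass_defect(pm, warn_half = FALSE))
  if (dd > params$ms1_defect_tol) return(NULL)
  fms2 <- feature$ms2[[1L]]
  s <- score_ms2(fms2, prototype$ms2[[1L]], params,
                 precursor_mz = feature$mz)
  has_ms2 <- !is.null(fms2) && nrow(fms2) > 0L
  pathway <- sprintf("%+.4f Da", delta)
  if (!is.null(catalog)) {
    rules <- catalog$rules[abs(catalog$rules$delta_n) <= params$max_delta_n, ]
    hit <- which(abs(rules$delta_mass - delta) <= 0.005)
    if (length(hit)) {
      hit <- hit[which.min(abs(rules$delta_mass[hit] - delta))]
      pathway <- paste0(pathway, " (~", rules$label[hit], ")")
    }
  }
  edge <- .edge_row(prototype$compound_id, feature$feature_id,
                    "unpredictable", pathway, n_steps = NA_integer_,
                    match_degree = if (has_ms2) as.integer(s$match_degree)
                                   else NA_integer_,
                    delta_ppm = NA_real_, base = 50,
                    similarity = if (has_ms2) s$similarity else 0,
                    bonus = if (has_ms2) s$defect_bonus else 0,
                    confidence = if (has_ms2) s$confidence else 0,
                    retained = FALSE, params)
  edge$retained <- edge$total >= params$retention_score
  edge
}

#' Run the full stepwise MDRB bridging of a metabolite list to a prototype list
#'
#' Pass 1 assigns prototype/isomer edges; features so matched are final.
#' Pass 2 screens the remaining features against every prototype and every
#' one- or two-step catalog pathway (base 70 + MS2 scoring). Features still
#' without a retained edge enter pass 3, the unpredictable mass-defect screen
#' (base 50 + MS2 scoring, retention threshold). Features ending with no
#' retained edge are labeled elusive. A feature may bridge to several
#' prototypes; its retained edges are ranked by total score, then smaller
#' |delta ppm|, then fewer pathway steps, then prototype id. The engine is
#' deterministic.
#'
#' @param prototypes Prototype data.frame (see [as_prototypes()]).
#' @param features Feature data.frame (see [as_features()]); usually the
#'   PATBS-subtracted, matrix-pooled component list.
#' @param catalog A `pathway_catalog` (default [default_catalog()]).
#' @param params An [mdrb_params()] object.
#' @return A `component_network` (see [build_network()]) whose `edges` table
#'   carries all candidate edges (retained and not), whose `features` table
#'   carries the per-feature category, and whose `summary` counts features
#'   per category.
#' @export
run_mdrb <- function(prototypes, features, catalog = default_catalog(),
                     params = mdrb_params()) {
  prototypes <- as_prototypes(prototypes)
  features <- as_features(features)
  if (nrow(prototypes) == 0L) {
    stop("prototype list is empty", call. = FALSE)
  }
  if (nrow(features) == 0L) {
    stop("feature list is empty", call. = FALSE)
  }
  pathways <- enumerate_pathways(catalog, max_delta_n = params$max_delta_n)
  all_edges <- list()
  k <- 0L
  push <- function(e) {
    if (!is.null(e) && nrow(e)) {
      k <<- k + 1L
      all_edges[[k]] <<- e
    }
  }
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    # pass 1: prototype / isomer
    step1 <- FALSE
    for (j in seq_len(nrow(prototypes))) {
      e <- match_prototype(f, prototypes[j, , drop = FALSE], params)
      if (!is.null(e)) {
        push(e)
        step1 <- TRUE
      }
    }
    if (step1) next
    # pass 2: predictable pathways
    feature_edges <- list()
    for (j in seq_len(nrow(prototypes))) {
      e <- match_predictable(f, prototypes[j, , drop = FALSE], pathways,
                             params)
      if (nrow(e)) feature_edges[[length(feature_edges) + 1L]] <- e
    }
    fe <- if (length(feature_edges)) do.call(rbind, feature_edges)
          else .empty_edges()
    push(fe)
    if (any(fe$retained)) next
    # pass 3: unpredictable (skip prototypes already holding an edge)
    seen <- unique(fe$prototype_id)
    for (j in seq_len(nrow(prototypes))) {
      if (prototypes$compound_id[j] %in% seen) next
      e <- match_unpredictable(f, prototypes[j, , drop = FALSE], params,
                               catalog)
      push(e)
    }
  }
  edges <- if (k) do.call(rbind, all_edges[seq_len(k)]) else .empty_edges()
  # per-feature ranking of retained edges
  edges$rank <- NA_integer_
  if (nrow(edges)) {
    for (fid in unique(edges$feature_id[edges$retained])) {
      idx <- which(edges$feature_id == fid & edges$retained)
      o <- order(-edges$total[idx], is.na(edges$delta_ppm[idx]),
                 abs(edges$delta_ppm[idx]),
                 ifelse(is.na(edges$n_steps[idx]), 99L, edges$n_steps[idx]),
                 edges$prototype_id[idx])
      edges$rank[idx[o]] <- seq_along(idx)
    }
  }
  rownames(edges) <- NULL
  # per-feature category: top-ranked retained edge, else elusive
  features$category <- "elusive"
  if (nrow(edges)) {
    top <- edges[edges$retained & !is.na(edges$rank) & edges$rank == 1L, ]
    features$category[match(top$feature_id, features$feature_id)] <-
      top$category
  }
  build_network(edges, prototypes, features, params = params)
}

#' Candidate counts across MS1 mass-defect windows
#'
#' Counts the (feature, prototype) pairs passing the unpredictable-metabolite
#' MS1 screen (`ms1_window` amu proximity plus defect agreement) at each
#' defect tolerance. Widening the window can only add candidates, so the
#' counts are non-decreasing; the sweep makes the sensitivity/false-positive
#' trade-off behind the 25 mmu default visible on a user's own data.
#'
#' @param prototypes Prototype data.frame.
#' @param features Feature data.frame.
#' @param params An [mdrb_params()] object (for `ms1_window`).
#' @param tols Defect tolerances to sweep, mmu.
#' @return A data.frame with `defect_tol_mmu` and `n_candidates`.
#' @export
sweep_defect_window <- function(prototypes, features,
                                params = mdrb_params(),
                                tols = c(10, 25, 50, 75)) {
  prototypes <- as_prototypes(prototypes)
  features <- as_features(features)
  has_ad <- !is.na(features$adduct) & nzchar(features$adduct)
  fm <- ifelse(has_ad,
               features$mz - adduct_shift(ifelse(has_ad, features$adduct,
                                                 "M+H")),
               features$mz)
  pm_neutral <- prototypes$neutral_mass
  pm_raw <- prototypes$mz
  counts <- vapply(tols, function(tol) {
    n <- 0L
    for (i in seq_len(nrow(features))) {
      pm <- if (has_ad[i]) pm_neutral else pm_raw
      ok <- features$polarity[i] == prototypes$polarity &
        abs(fm[i] - pm) <= params$ms1_window &
        abs(mass_defect(fm[i], warn_half = FALSE) -
            mass_defect(pm, warn_half = FALSE)) <= tol
      n <- n + sum(ok)
    }
    n
  }, integer(1))
  data.frame(defect_tol_mmu = tols, n_candidates = counts)
}
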