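# Naive brute-force re-implementation of the stepwise matcher, written with
# plain scanning loops and no indexing or vectorisation. Used only as an
# independent oracle on small fixtures.

oracle_pair_fragments <- function(f, p, params) {
  nf <- nrow(f); np <- nrow(p)
  f_used <- logical(nf); p_used <- logical(np)
  n_exact <- 0L
  first_exact <- NA_real_
  repeat {
    best <- NULL
    for (i in seq_len(nf)) {
      if (f_used[i]) next
      for (j in seq_len(np)) {
        if (p_used[j]) next
        d <- abs(f$mz[i] - p$mz[j])
        if (d > params$ms2_frag_tol) next
        pri <- f$intensity[i] + p$intensity[j]
        if (is.null(best) || d < best$d || (d == best$d && pri > best$pri)) {
          best <- list(i = i, j = j, d = d, pri = pri)
        }
      }
    }
    if (is.null(best)) break
    f_used[best$i] <- TRUE; p_used[best$j] <- TRUE
    n_exact <- n_exact + 1L
    if (is.na(first_exact)) first_exact <- f$mz[best$i]
  }
  n_defect <- 0L
  repeat {
    best <- NULL
    for (i in seq_len(nf)) {
      if (f_used[i]) next
      for (j in seq_len(np)) {
        if (p_used[j]) next
        d <- abs(f$mz[i] - p$mz[j])
        if (d > params$ms2_window) next
        dd <- abs((f$mz[i] - round(f$mz[i])) - (p$mz[j] - round(p$mz[j]))) *
          1000
        if (dd > params$ms2_defect_tol) next
        if (is.null(best) || dd < best$dd || (dd == best$dd && d < best$d)) {
          best <- list(i = i, j = j, d = d, dd = dd)
        }
      }
    }
    if (is.null(best)) break
    f_used[best$i] <- TRUE; p_used[best$j] <- TRUE
    n_defect <- n_defect + 1L
  }
  list(n_exact = n_exact, n_defect = n_defect, first_exact = first_exact)
}

oracle_score <- function(f, p, precursor, params) {
  s <- oracle_pair_fragments(f, p, params)
  degree <- s$n_exact + s$n_defect
  sim <- if (s$n_exact >= 2L) 30 else if (s$n_exact == 1L) 20 else 0
  conf <- 0
  if (nrow(f) > 0L) {
    dd <- Inf
    for (i in seq_len(nrow(f))) {
      dd_i <- abs((precursor - round(precursor)) -
                    (f$mz[i] - round(f$mz[i]))) * 1000
      if (dd_i < dd) dd <- dd_i
    }
    if (dd <= params$ms1_ms2_defect_tol) conf <- 2
  }
  list(degree = degree, sim = sim, bonus = 5 * s$n_defect, conf = conf)
}

# Retained edge set (prototype, feature, pathway, category, total) by direct
# application of the stepwise screening rules.
oracle_mdrb <- function(prototypes, features, catalog, params) {
  pathways <- enumerate_pathways(catalog, max_delta_n = params$max_delta_n)
  shift_of <- function(ad) adducts()$mass_shift[match(ad, adducts()$name)]
  out <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    fms2 <- f$ms2[[1]]
    retained_here <- list()
    # step 1
    step1 <- FALSE
    for (j in seq_len(nrow(prototypes))) {
      p <- prototypes[j, ]
      if (f$polarity != p$polarity) next
      if (abs(f$mz - p$mz) / p$mz * 1e6 <= params$mz_tol) {
        step1 <- TRUE
        cat_ <- if (abs(f$rt - p$rt) * 60 <= params$rt_tol) "prototype"
                else "isomer"
        retained_here[[length(retained_here) + 1L]] <-
          data.frame(prototype_id = p$compound_id, feature_id = f$feature_id,
                     category = cat_, pathway = "", total = 100)
      }
    }
    if (step1) {
      out <- c(out, retained_here)
      next
    }
    # step 2
    ad <- if (!is.na(f$adduct) && nzchar(f$adduct)) f$adduct
          else if (f$polarity == "positive") "M+H" else "M-H"
    fn <- f$mz - shift_of(ad)
    seen <- character(0)
    any_retained <- FALSE
    for (j in seq_len(nrow(prototypes))) {
      p <- prototypes[j, ]
      if (f$polarity != p$polarity) next
      for (h in seq_len(nrow(pathways))) {
        pred <- p$neutral_mass + pathways$delta_mass[h]
        if (pred <= 0) next
        if (abs(fn - pred) / pred * 1e6 > params$mz_tol) next
        if (!is.na(p$n_count) && p$n_count + pathways$delta_n[h] < 0) next
        seen <- union(seen, p$compound_id)
        if (nrow(fms2) == 0L) {
          any_retained <- TRUE
          out[[length(out) + 1L]] <-
            data.frame(prototype_id = p$compound_id,
                       feature_id = f$feature_id, category = "predictable",
                       pathway = pathways$pathway[h], total = 70)
        } else {
          s <- oracle_score(fms2, p$ms2[[1]], f$mz, params)
          if (s$degree > 0L) {
            any_retained <- TRUE
            out[[length(out) + 1L]] <-
              data.frame(prototype_id = p$compound_id,
                         feature_id = f$feature_id, category = "predictable",
                         pathway = pathways$pathway[h],
                         total = 70 + s$sim + s$bonus)
          }
        }
      }
    }
    if (any_retained) next
    # step 3
    for (j in seq_len(nrow(prototypes))) {
      p <- prototypes[j, ]
      if (f$polarity != p$polarity) next
      if (p$compound_id %in% seen) next
      if (!is.na(f$adduct) && nzchar(f$adduct)) {
        fm <- f$mz - shift_of(f$adduct)
        pm <- p$neutral_mass
      } else {
        fm <- f$mz
        pm <- p$mz
      }
      if (abs(fm - pm) > params$ms1_window) next
      dd <- abs((fm - round(fm)) - (pm - round(pm))) * 1000
      if (dd > params$ms1_defect_tol) next
      total <- if (nrow(fms2) == 0L) 50 else {
        s <- oracle_score(fms2, p$ms2[[1]], f$mz, params)
        50 + s$sim + s$bonus
      }
      if (total >= params$retention_score) {
        delta <- fm - pm
        rules <- catalog$rules[abs(catalog$rules$delta_n) <=
                                 params$max_delta_n, ]
        pw <- sprintf("%+.4f Da", delta)
        hit <- which(abs(rules$delta_mass - delta) <= 0.005)
        if (length(hit)) {
          hit <- hit[which.min(abs(rules$delta_mass[hit] - delta))]
          pw <- paste0(pw, " (~", rules$label[hit], ")")
        }
        out[[length(out) + 1L]] <-
          data.frame(prototype_id = p$compound_id,
                     feature_id = f$feature_id, category = "unpredictable",
                     pathway = pw, total = total)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(prototype_id = character(0), feature_id = character(0),
                      category = character(0), pathway = character(0),
                      total = numeric(0)))
  }
  do.call(rbind, out)
}

edge_key <- function(edges) {
  sort(paste(edges$prototype_id, edges$feature_id, edges$category,
             edges$pathway, edges$total, sep = "|"))
}
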