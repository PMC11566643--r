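# Ground-truth simulator: an herb's prototype/metabolite universe with
# catalog-generated metabolites, ppm-level mass error, RT jitter and shared
# endogenous background, so that every pipeline stage is testable without
# instrument data.

#' Simulation configuration
#'
#' @param n_prototypes Number of herb prototype components.
#' @param n_families Number of structural families; prototypes in a family
#'   share two core MS2 fragments (conserved parent nucleus).
#' @param metabolites_per_prototype Poisson mean of metabolites per prototype.
#' @param p_two_step Probability a metabolite arises from a two-step pathway.
#' @param n_endogenous Endogenous background features added identically to
#'   blank and sample (PATBS must remove them).
#' @param mz_noise Mass accuracy bound in ppm; observed m/z is
#'   `true * (1 + e)` with `e ~ N(0, (mz_noise/3)^2)` ppm, so ~99.7% of
#'   errors fall inside the bound.
#' @param rt_jitter RT jitter standard deviation in seconds (applied to
#'   re-detections of a prototype in vivo).
#' @param fragment_count Range (length-2) of MS2 fragment counts per
#'   prototype.
#' @param p_fragment_shared Probability a prototype fragment survives in a
#'   metabolite's MS2.
#' @param p_prototype_absorbed Probability a prototype is itself absorbed and
#'   appears in vivo.
#' @param matrix_probs Named probabilities that a drug-related component is
#'   observed in each biological matrix.
#' @param p_endogenous_matrix Probability an endogenous feature occurs in a
#'   given matrix.
#' @param polarity Ionisation mode of the simulated stream.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_prototypes = 10L, n_families = 3L,
                       metabolites_per_prototype = 3,
                       p_two_step = 0.2, n_endogenous = 200L,
                       mz_noise = 5, rt_jitter = 10,
                       fragment_count = c(3L, 8L),
                       p_fragment_shared = 0.7,
                       p_prototype_absorbed = 0.5,
                       matrix_probs = c(plasma = 0.5, urine = 0.9,
                                        feces = 0.3, lung = 0.3),
                       p_endogenous_matrix = 0.8,
                       polarity = c("negative", "positive"),
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config requires an explicit seed", call. = FALSE)
  }
  polarity <- match.arg(polarity)
  probs <- c(p_two_step, p_fragment_shared, p_prototype_absorbed,
             p_endogenous_matrix, matrix_probs)
  stopifnot(all(probs >= 0 & probs <= 1), mz_noise >= 0, rt_jitter >= 0,
            length(fragment_count) == 2L, n_prototypes >= 1L)
  structure(list(
    n_prototypes = as.integer(n_prototypes),
    n_families = as.integer(n_families),
    metabolites_per_prototype = metabolites_per_prototype,
    p_two_step = p_two_step, n_endogenous = as.integer(n_endogenous),
    mz_noise = mz_noise, rt_jitter = rt_jitter,
    fragment_count = as.integer(fragment_count),
    p_fragment_shared = p_fragment_shared,
    p_prototype_absorbed = p_prototype_absorbed,
    matrix_probs = matrix_probs,
    p_endogenous_matrix = p_endogenous_matrix,
    polarity = polarity, seed = as.integer(seed)
  ), class = "sim_config")
}

# random CHNO(S) formula with monoisotopic mass in [150, 800] and 0-4 N
.random_formula <- function() {
  repeat {
    counts <- c(
      C = sample(8:30, 1L),
      N = sample(0:4, 1L, prob = c(0.45, 0.25, 0.15, 0.1, 0.05)),
      O = sample(2:14, 1L),
      S = stats::rbinom(1L, 1L, 0.1)
    )
    counts["H"] <- round(counts[["C"]] * stats::runif(1, 1.0, 1.9))
    counts <- counts[counts > 0]
    m <- formula_mass(counts)
    if (m >= 150 && m <= 800) {
      return(list(counts = counts, mass = m,
                  formula = paste0(names(counts), counts, collapse = "")))
    }
  }
}

.apply_delta <- function(counts, labels, rules) {
  out <- counts
  for (lab in labels) {
    f <- rules$delta_formula[rules$label == lab]
    if (is.na(f) || !nzchar(f)) return(NULL)
    d <- parse_formula(f)
    all_el <- union(names(out), names(d))
    v <- stats::setNames(numeric(length(all_el)), all_el)
    v[names(out)] <- v[names(out)] + out
    v[names(d)] <- v[names(d)] + d
    if (any(v < 0)) return(NULL)
    out <- v[v > 0]
  }
  out
}

#' Simulate an herb's prototype and in vivo feature universe
#'
#' Prototypes are drawn with realistic CHNO(S) formulas (150-800 Da, 0-4
#' nitrogens) and MS2 fragment sets; metabolites are generated by applying
#' catalog pathways (respecting the N-rule and elemental feasibility; a
#' pathway yielding negative atom counts is skipped and logged). A
#' metabolite's MS2 is a subset of its prototype's fragments: each survives
#' with probability `p_fragment_shared` and, when it survives, carries the
#' pathway mass shift with probability 0.5 (moiety-bearing fragment,
#' exercising the MS2 defect tier) or stays exact (conserved core, exercising
#' the 20/30 tier). Whenever any fragment survives, at least one stays exact:
#' the conserved parent nucleus assumption that the bridging score relies on.
#' Endogenous features are added identically to blank and sample tables.
#'
#' @param config A [sim_config()].
#' @param catalog A `pathway_catalog` (default [default_catalog()]).
#' @return A `herb_simulation`: list with `prototypes`, `samples` (named list
#'   of per-matrix feature tables), `blanks`, `features` (all drug-related
#'   features), `truth` (ground-truth edges), `log`, `config`.
#' @export
simulate_herb <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  rules <- catalog$rules
  pathways <- enumerate_pathways(catalog)
  pathways <- pathways[!pathways$near_null, , drop = FALSE]
  singles <- pathways[pathways$n_steps == 1L, , drop = FALSE]
  doubles <- pathways[pathways$n_steps == 2L, , drop = FALSE]
  pol <- config$polarity
  adduct <- default_adduct(pol)
  shift <- adduct_shift(adduct)
  sigma <- config$mz_noise / 3 * 1e-6
  noisy <- function(m) m * (1 + stats::rnorm(length(m), 0, sigma))
  log <- character(0)

  n <- config$n_prototypes
  families <- rep_len(seq_len(max(config$n_families, 1L)), n)
  core_frags <- lapply(seq_len(max(config$n_families, 1L)),
                       function(i) sort(stats::runif(2L, 80, 280)))
  protos <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .random_formula()
    true_mz <- mz_from_neutral(f$mass, adduct)
    k <- sample(config$fragment_count[1]:config$fragment_count[2], 1L)
    own <- sort(stats::runif(k, 0.15, 0.88)) * true_mz
    frag_mz <- c(core_frags[[families[i]]], own)
    frag_mz <- frag_mz[frag_mz < true_mz - 1]
    frags <- data.frame(mz = noisy(frag_mz),
                        intensity = stats::rlnorm(length(frag_mz), 10, 1))
    protos[[i]] <- list(
      compound_id = sprintf("H%02d", i),
      name = sprintf("prototype_%02d", i),
      family = families[i],
      rt = stats::runif(1, 1, 20),
      true_neutral = f$mass,
      true_mz = true_mz,
      mz = noisy(true_mz),
      formula = f$formula,
      counts = f$counts,
      true_frags = frag_mz,
      ms2 = frags[order(frags$mz), , drop = FALSE]
    )
  }
  prototypes <- data.frame(
    compound_id = vapply(protos, `[[`, character(1), "compound_id"),
    name = vapply(protos, `[[`, character(1), "name"),
    rt = vapply(protos, `[[`, numeric(1), "rt"),
    mz = vapply(protos, `[[`, numeric(1), "mz"),
    polarity = pol, adduct = adduct,
    formula = vapply(protos, `[[`, character(1), "formula"),
    stringsAsFactors = FALSE
  )
  prototypes$ms2 <- I(lapply(protos, `[[`, "ms2"))
  prototypes <- as_prototypes(prototypes)

  draw_matrices <- function() {
    mats <- names(config$matrix_probs)[
      stats::runif(length(config$matrix_probs)) < config$matrix_probs]
    if (!length(mats)) mats <- "urine"
    mats
  }

  feat_rows <- list()
  truth_rows <- list()
  met_i <- 0L
  for (i in seq_len(n)) {
    p <- protos[[i]]
    # the prototype itself, absorbed unchanged
    if (stats::runif(1) < config$p_prototype_absorbed) {
      met_i <- met_i + 1L
      fid <- sprintf("MET%03d", met_i)
      feat_rows[[length(feat_rows) + 1L]] <- list(
        feature_id = fid,
        rt = max(0, p$rt + stats::rnorm(1, 0, config$rt_jitter) / 60),
        mz = noisy(p$true_mz),
        intensity = stats::rlnorm(1, 13, 1),
        matrices = draw_matrices(),
        ms2 = data.frame(mz = noisy(p$true_frags),
                         intensity = stats::rlnorm(length(p$true_frags),
                                                   10, 1))
      )
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        prototype_id = p$compound_id, feature_id = fid,
        pathway = "", category = "prototype", delta_mass = 0,
        stringsAsFactors = FALSE
      )
    }
    n_met <- stats::rpois(1L, config$metabolites_per_prototype)
    for (m in seq_len(n_met)) {
      pw <- NULL
      for (attempt in 1:10) {
        pool <- if (stats::runif(1) < config$p_two_step && nrow(doubles))
          doubles else singles
        cand <- pool[sample.int(nrow(pool), 1L), ]
        if (!is.na(prototypes$n_count[i]) &&
            prototypes$n_count[i] + cand$delta_n < 0) next
        new_counts <- .apply_delta(p$counts, cand$labels[[1L]], rules)
        if (is.null(new_counts)) next
        new_mass <- p$true_neutral + cand$delta_mass
        if (new_mass < 60) next
        pw <- cand
        break
      }
      if (is.null(pw)) {
        log <- c(log, sprintf(
          "prototype %s: no feasible pathway for metabolite %d; skipped",
          p$compound_id, m))
        next
      }
      met_i <- met_i + 1L
      fid <- sprintf("MET%03d", met_i)
      met_neutral <- p$true_neutral + pw$delta_mass
      met_mz <- mz_from_neutral(met_neutral, adduct)
      keep <- stats::runif(length(p$true_frags)) < config$p_fragment_shared
      frag_true <- p$true_frags[keep]
      shifted <- stats::runif(length(frag_true)) < 0.5
      frag_true[shifted] <- frag_true[shifted] + pw$delta_mass
      ok <- frag_true > 20 & frag_true < met_mz - 1
      frag_true <- frag_true[ok]
      shifted <- shifted[ok]
      # conserved parent-nucleus fragment: force one unshifted survivor
      if (length(frag_true) && all(shifted)) {
        core_ok <- p$true_frags[p$true_frags < met_mz - 1]
        if (length(core_ok)) {
          frag_true[1L] <- core_ok[length(core_ok)]
        } else {
          frag_true <- numeric(0)
        }
      }
      ms2 <- if (length(frag_true)) {
        data.frame(mz = sort(noisy(frag_true)),
                   intensity = stats::rlnorm(length(frag_true), 10, 1))
      } else {
        data.frame(mz = numeric(0), intensity = numeric(0))
      }
      feat_rows[[length(feat_rows) + 1L]] <- list(
        feature_id = fid,
        rt = stats::runif(1, 1, 20),
        mz = noisy(met_mz),
        intensity = stats::rlnorm(1, 13, 1),
        matrices = draw_matrices(),
        ms2 = ms2
      )
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        prototype_id = p$compound_id, feature_id = fid,
        pathway = pw$pathway, category = "predictable",
        delta_mass = pw$delta_mass, stringsAsFactors = FALSE
      )
    }
  }
  features <- data.frame(
    feature_id = vapply(feat_rows, `[[`, character(1), "feature_id"),
    rt = vapply(feat_rows, `[[`, numeric(1), "rt"),
    mz = vapply(feat_rows, `[[`, numeric(1), "mz"),
    intensity = vapply(feat_rows, `[[`, numeric(1), "intensity"),
    polarity = pol, matrix = "other", adduct = adduct,
    stringsAsFactors = FALSE
  )
  features$ms2 <- I(lapply(feat_rows, `[[`, "ms2"))
  features <- as_features(features)
  feat_matrices <- lapply(feat_rows, `[[`, "matrices")

  # endogenous background, identical in blank and sample
  n_end <- config$n_endogenous
  if (n_end > 0L) {
    endo <- data.frame(
      feature_id = sprintf("END%03d", seq_len(n_end)),
      rt = stats::runif(n_end, 0.5, 22),
      mz = stats::runif(n_end, 100, 900),
      intensity = stats::rlnorm(n_end, 13, 1),
      polarity = pol, matrix = "other", adduct = NA_character_,
      stringsAsFactors = FALSE
    )
    endo$ms2 <- I(replicate(n_end,
                            data.frame(mz = numeric(0),
                                       intensity = numeric(0)),
                            simplify = FALSE))
    endo <- as_features(endo)
  } else {
    endo <- features[0, , drop = FALSE]
  }
  endo_in <- matrix(stats::runif(n_end * length(config$matrix_probs)) <
                      config$p_endogenous_matrix,
                    nrow = max(n_end, 1L))

  samples <- list()
  blanks <- list()
  mat_names <- names(config$matrix_probs)
  for (mi in seq_along(mat_names)) {
    m <- mat_names[mi]
    drug_idx <- which(vapply(feat_matrices, function(x) m %in% x, logical(1)))
    endo_idx <- if (n_end > 0L) which(endo_in[, mi]) else integer(0)
    blank <- endo[endo_idx, , drop = FALSE]
    if (nrow(blank)) blank$matrix <- m
    sample_tab <- rbind(features[drug_idx, , drop = FALSE], blank)
    if (nrow(sample_tab)) sample_tab$matrix <- m
    rownames(sample_tab) <- NULL
    rownames(blank) <- NULL
    samples[[m]] <- sample_tab
    blanks[[m]] <- blank
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(prototype_id = character(0),
                           feature_id = character(0), pathway = character(0),
                           category = character(0), delta_mass = numeric(0))
  structure(list(prototypes = prototypes, samples = samples, blanks = blanks,
                 features = features, truth = truth, log = log,
                 config = config),
            class = "herb_simulation")
}

#' Write a simulation to delimited fixture files
#'
#' Emits `prototypes.csv`, per-matrix `<matrix>_sample.csv` /
#' `<matrix>_blank.csv`, and `truth_edges.csv` in the formats the package
#' readers consume.
#'
#' @param sim A `herb_simulation`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "herb_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_prototype_table(sim$prototypes, file.path(dir, "prototypes.csv"))
  for (m in names(sim$samples)) {
    write_feature_table(sim$samples[[m]],
                        file.path(dir, paste0(m, "_sample.csv")))
    write_feature_table(sim$blanks[[m]],
                        file.path(dir, paste0(m, "_blank.csv")))
  }
  utils::write.csv(sim$truth, file.path(dir, "truth_edges.csv"),
                   row.names = FALSE)
  invisible(dir)
}
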