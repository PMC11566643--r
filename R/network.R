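# Component relationship network: prototypes and in vivo features joined by
# retained edges, with connected-component families, per-matrix summaries and
# exposure fractions.

#' Assemble the prototype-metabolite component network
#'
#' Nodes are prototypes plus features; retained edges connect them. Connected
#' components are computed on the retained graph and each component is
#' labeled by its highest-scoring prototype (the "parent nucleus" family);
#' features with no retained edge form singleton elusive components.
#'
#' @param edges Edge data.frame as produced by the matching passes.
#' @param prototypes Prototype data.frame.
#' @param features Feature data.frame.
#' @param params The `mdrb_params` used (stored for provenance).
#' @return A `component_network`: list with `graph` (igraph), `nodes`,
#'   `edges`, `features`, `prototypes`, `components`, `summary`.
#' @export
build_network <- function(edges, prototypes, features, params = NULL) {
  stopifnot(is.data.frame(edges))
  retained <- edges[edges$retained %in% TRUE, , drop = FALSE]
  bad <- !(retained$prototype_id %in% prototypes$compound_id) |
         !(retained$feature_id %in% features$feature_id)
  if (any(bad)) {
    stop("edge endpoint not found among nodes: ",
         paste(utils::head(unique(c(
           retained$prototype_id[bad], retained$feature_id[bad])), 5L),
           collapse = ", "), call. = FALSE)
  }
  key <- paste(edges$prototype_id, edges$feature_id, edges$pathway)
  if (anyDuplicated(key)) {
    stop("duplicate (prototype, feature, pathway) edges", call. = FALSE)
  }
  nodes <- rbind(
    data.frame(name = prototypes$compound_id, node_type = "prototype",
               label = prototypes$name, mz = prototypes$mz,
               rt = prototypes$rt, polarity = prototypes$polarity,
               matrix = "herb", intensity = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(name = features$feature_id, node_type = "feature",
               label = features$feature_id, mz = features$mz,
               rt = features$rt, polarity = features$polarity,
               matrix = features$matrix, intensity = features$intensity,
               stringsAsFactors = FALSE)
  )
  if (anyDuplicated(nodes$name)) {
    stop("prototype and feature identifiers must be disjoint and unique",
         call. = FALSE)
  }
  if ("category" %in% names(features)) {
    nodes$category <- c(rep("prototype_node", nrow(prototypes)),
                        features$category)
  }
  g_edges <- data.frame(
    from = retained$prototype_id, to = retained$feature_id,
    category = retained$category, pathway = retained$pathway,
    match_degree = ifelse(is.na(retained$match_degree), -1L,
                          retained$match_degree),
    base = retained$base, ms2_similarity = retained$ms2_similarity,
    ms2_defect_bonus = retained$ms2_defect_bonus,
    confidence = retained$confidence, total = retained$total,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(g_edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  membership <- comp$membership
  # family label per component: prototype with the highest-scoring edge
  family <- rep(NA_character_, comp$no)
  for (cid in seq_len(comp$no)) {
    members <- names(membership)[membership == cid]
    protos <- intersect(members, prototypes$compound_id)
    if (!length(protos)) next
    sub <- retained[retained$prototype_id %in% protos, , drop = FALSE]
    if (nrow(sub)) {
      best <- max(sub$total)
      cands <- sort(unique(sub$prototype_id[sub$total == best]))
      family[cid] <- cands[1L]
    } else {
      family[cid] <- sort(protos)[1L]
    }
  }
  components <- data.frame(
    name = names(membership),
    component = as.integer(membership),
    family = family[membership],
    stringsAsFactors = FALSE
  )
  n_cat <- if ("category" %in% names(features)) {
    as.list(table(features$category))
  } else NULL
  summary <- list(
    n_prototypes = nrow(prototypes),
    n_features = nrow(features),
    n_edges_retained = nrow(retained),
    n_components = comp$no,
    features_per_category = n_cat
  )
  structure(list(graph = g, nodes = nodes, edges = edges,
                 features = features, prototypes = prototypes,
                 components = components, summary = summary,
                 params = params),
            class = "component_network")
}

#' @export
print.component_network <- function(x, ...) {
  s <- x$summary
  cat("component_network:", s$n_prototypes, "prototypes,", s$n_features,
      "features,", s$n_edges_retained, "retained edges,", s$n_components,
      "connected components\n")
  if (!is.null(s$features_per_category)) {
    cat("features per category:\n")
    for (nm in names(s$features_per_category)) {
      cat(sprintf("  %-14s %d\n", nm, s$features_per_category[[nm]]))
    }
  }
  invisible(x)
}

# matrices a (possibly merged) feature row belongs to
.feature_matrices <- function(features) {
  strsplit(features$matrix, ",", fixed = TRUE)
}

#' Per-matrix exposure summary
#'
#' For every biological matrix: the number of drug-related features, the
#' number of retained edges touching them, and the characterized fraction
#' (features holding at least one retained edge over all features; elusive
#' features count in the denominator only).
#'
#' @param network A `component_network`.
#' @return A data.frame with one row per matrix.
#' @export
matrix_summary <- function(network) {
  stopifnot(inherits(network, "component_network"))
  feats <- network$features
  edges <- network$edges[network$edges$retained %in% TRUE, , drop = FALSE]
  mats <- .feature_matrices(feats)
  all_m <- sort(unique(unlist(mats)))
  characterized <- feats$feature_id %in% edges$feature_id
  rows <- lapply(all_m, function(m) {
    in_m <- vapply(mats, function(x) m %in% x, logical(1))
    n <- sum(in_m)
    data.frame(
      matrix = m,
      n_features = n,
      n_retained_edges = sum(edges$feature_id %in% feats$feature_id[in_m]),
      n_characterized = sum(characterized & in_m),
      characterized_fraction = if (n) sum(characterized & in_m) / n else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Peak-area exposure share of a component family
#'
#' The summed intensity of all features in the connected component(s) labeled
#' with `family`, divided by the summed intensity of every feature, per
#' polarity, as a percentage. With AUC-pooled samples the peak area stands in
#' for in vivo exposure, so this is the family's exposure share.
#'
#' @param network A `component_network`.
#' @param family A family label (prototype `compound_id` labeling the
#'   component, see [build_network()]).
#' @return A data.frame with `polarity`, `family_intensity`,
#'   `total_intensity`, `percent`.
#' @export
exposure_fraction <- function(network, family) {
  stopifnot(inherits(network, "component_network"))
  feats <- network$features
  comp <- network$components
  in_family <- feats$feature_id %in%
    comp$name[!is.na(comp$family) & comp$family == family]
  pols <- sort(unique(feats$polarity))
  rows <- lapply(pols, function(pol) {
    sel <- feats$polarity == pol
    tot <- sum(feats$intensity[sel])
    fam <- sum(feats$intensity[sel & in_family])
    data.frame(polarity = pol, family_intensity = fam,
               total_intensity = tot,
               percent = if (tot > 0) 100 * fam / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
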