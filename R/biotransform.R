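# Predictable-metabolism catalog: named biotransformations (mass/formula
# deltas with nitrogen bookkeeping) and one- or two-step pathway enumeration.

#' Read a biotransformation catalog from delimited text
#'
#' Expected columns: `label`, `delta_formula`, `delta_mass`, `delta_n`,
#' `phase` (and optionally `rule_id`). When `delta_formula` is present its
#' monoisotopic mass must agree with `delta_mass` to 1e-4 Da; when
#' `delta_mass` is blank it is computed from the formula.
#'
#' @param path Path to a tab- or comma-separated rule file.
#' @param delimiter Field delimiter (default tab).
#' @param max_steps Maximum pathway length stored on the catalog (1 or 2).
#' @return A `pathway_catalog` object.
#' @export
read_catalog <- function(path, delimiter = "\t", max_steps = 2L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "#")
  as_catalog(df, max_steps = max_steps)
}

#' Validate a biotransformation rule table
#'
#' @param df Rule data.frame (see [read_catalog()]).
#' @param max_steps Maximum pathway length (1 or 2).
#' @return A `pathway_catalog` object.
#' @export
as_catalog <- function(df, max_steps = 2L) {
  stopifnot(is.data.frame(df), max_steps %in% c(1L, 2L))
  if (!"label" %in% names(df)) {
    stop("catalog is missing required column 'label'", call. = FALSE)
  }
  if (anyDuplicated(df$label)) {
    stop("catalog rule labels must be unique", call. = FALSE)
  }
  n <- nrow(df)
  rules <- data.frame(
    rule_id = if ("rule_id" %in% names(df)) as.character(df$rule_id)
              else sprintf("r%02d", seq_len(n)),
    label = as.character(df$label),
    delta_formula = if ("delta_formula" %in% names(df))
                      as.character(df$delta_formula)
                    else rep(NA_character_, n),
    delta_mass = if ("delta_mass" %in% names(df))
                   .as_num_col(df$delta_mass, "delta_mass")
                 else rep(NA_real_, n),
    delta_n = if ("delta_n" %in% names(df))
                as.integer(.as_num_col(df$delta_n, "delta_n"))
              else rep(NA_integer_, n),
    phase = if ("phase" %in% names(df)) as.character(df$phase)
            else rep("I", n),
    stringsAsFactors = FALSE
  )
  has_f <- !is.na(rules$delta_formula) & nzchar(rules$delta_formula)
  fm <- rep(NA_real_, n)
  fm[has_f] <- vapply(rules$delta_formula[has_f], formula_mass, numeric(1))
  miss_mass <- is.na(rules$delta_mass)
  rules$delta_mass[miss_mass & has_f] <- fm[miss_mass & has_f]
  if (any(is.na(rules$delta_mass))) {
    stop("catalog rules without delta_formula must state delta_mass: ",
         paste(rules$label[is.na(rules$delta_mass)], collapse = ", "),
         call. = FALSE)
  }
  bad <- has_f & abs(fm - rules$delta_mass) > 1e-4
  if (any(bad)) {
    stop("catalog delta_formula mass disagrees with delta_mass (> 1e-4 Da): ",
         paste(rules$label[bad], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(rules$delta_n))) {
    dn <- rep(0L, n)
    dn[has_f] <- vapply(rules$delta_formula[has_f], function(f) {
      cnt <- parse_formula(f)
      as.integer(if ("N" %in% names(cnt)) cnt[["N"]] else 0L)
    }, integer(1))
    rules$delta_n[is.na(rules$delta_n)] <- dn[is.na(rules$delta_n)]
  }
  if (any(abs(rules$delta_n) > 3L)) {
    stop("catalog rules must satisfy |delta_n| <= 3 (N-rule): ",
         paste(rules$label[abs(rules$delta_n) > 3L], collapse = ", "),
         call. = FALSE)
  }
  structure(list(rules = rules, max_steps = as.integer(max_steps)),
            class = "pathway_catalog")
}

#' The default biotransformation catalog
#'
#' Twenty-three common reactions: phase I redox/hydrolysis steps, phase II
#' conjugations (glucuronide, sulfate, acetyl, glycine, taurine, cysteine,
#' glutathione, glucoside, methyl) and the glycoside losses (hexose, pentose,
#' deoxyhexose, glucuronide) that glycosylated herbal components readily
#' undergo in vivo. Shipped as an editable TSV
#' (`system.file("extdata", "biotransformations.tsv", package = "mdrb")`) so
#' a study-specific rule list can be substituted.
#'
#' @param max_steps Maximum pathway length (default 2).
#' @return A `pathway_catalog` object.
#' @export
default_catalog <- function(max_steps = 2L) {
  path <- system.file("extdata", "biotransformations.tsv", package = "mdrb")
  read_catalog(path, delimiter = "\t", max_steps = max_steps)
}

#' Enumerate one- and two-step metabolic pathways
#'
#' All single rules plus all unordered pairs with repetition whose net
#' nitrogen change respects the N-rule (|net delta_n| <= `max_delta_n`).
#' Composites with identical net elemental composition are deduplicated,
#' keeping the lexicographically smallest label sequence. Pathways whose net
#' mass change is below `near_null_da` (e.g. methylation + demethylation) are
#' retained but flagged `near_null`, since they would otherwise shadow isomer
#' matches.
#'
#' @param catalog A `pathway_catalog`.
#' @param max_steps 1 or 2 (default: the catalog's `max_steps`).
#' @param max_delta_n N-rule bound on the net nitrogen change (default 3).
#' @param near_null_da Absolute net-mass threshold for the near-null flag.
#' @return A data.frame with columns `pathway` (display label), `labels`
#'   (list-column of rule labels), `delta_mass`, `delta_n`, `n_steps`,
#'   `near_null`.
#' @export
enumerate_pathways <- function(catalog, max_steps = NULL, max_delta_n = 3L,
                               near_null_da = 0.0025) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  if (is.null(max_steps)) max_steps <- catalog$max_steps
  if (!max_steps %in% c(1L, 2L)) {
    stop("max_steps must be 1 or 2; longer pathways are unsupported",
         call. = FALSE)
  }
  rules <- catalog$rules
  n <- nrow(rules)
  counts <- lapply(seq_len(n), function(i) {
    f <- rules$delta_formula[i]
    if (!is.na(f) && nzchar(f)) parse_formula(f) else NULL
  })
  add_counts <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NULL)
    all_el <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(all_el)), all_el)
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] + b
    out[out != 0]
  }
  rows <- vector("list", n + n * (n + 1L) / 2L)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    rows[[k]] <- list(labels = rules$label[i],
                      delta_mass = rules$delta_mass[i],
                      delta_n = rules$delta_n[i],
                      n_steps = 1L,
                      key = if (!is.null(counts[[i]]))
                              formula_key(counts[[i]])
                            else sprintf("m:%.9f", rules$delta_mass[i]))
  }
  if (max_steps >= 2L) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        dn <- rules$delta_n[i] + rules$delta_n[j]
        if (abs(dn) > max_delta_n) next
        labs <- sort(c(rules$label[i], rules$label[j]))
        cc <- add_counts(counts[[i]], counts[[j]])
        dm <- rules$delta_mass[i] + rules$delta_mass[j]
        k <- k + 1L
        rows[[k]] <- list(labels = labs, delta_mass = dm, delta_n = dn,
                          n_steps = 2L,
                          key = if (!is.null(cc)) formula_key(cc)
                                else sprintf("m:%.9f", dm))
      }
    }
  }
  rows <- rows[seq_len(k)]
  keys <- vapply(rows, `[[`, character(1), "key")
  disp <- vapply(rows, function(r) paste(r$labels, collapse = " + "),
                 character(1))
  # dedup identical net compositions: prefer the shorter pathway, then the
  # lexicographically smallest label sequence; zero-net (near-null) pairs are
  # each kept since the flag, not the label, identifies them
  steps <- vapply(rows, `[[`, integer(1), "n_steps")
  keep <- rep(TRUE, k)
  for (key in unique(keys[duplicated(keys)])) {
    if (key == "") next
    idx <- which(keys == key)
    best <- idx[order(steps[idx], disp[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  rows <- rows[keep]
  disp <- disp[keep]
  out <- data.frame(
    pathway = disp,
    delta_mass = vapply(rows, `[[`, numeric(1), "delta_mass"),
    delta_n = vapply(rows, function(r) as.integer(r$delta_n), integer(1)),
    n_steps = vapply(rows, `[[`, integer(1), "n_steps"),
    stringsAsFactors = FALSE
  )
  out$labels <- I(lapply(rows, `[[`, "labels"))
  out$near_null <- abs(out$delta_mass) < near_null_da
  rownames(out) <- NULL
  out
}
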