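# Readers and writers for every artifact boundary: delimited feature tables
# and prototype lists (MS2 inline as "mz:intensity;mz:intensity"), MGF spectra,
# biotransformation catalogs, edge tables and GraphML networks.

#' Describe the layout of a delimited feature table
#'
#' @param delimiter Field delimiter (default ",").
#' @param columns Named list mapping canonical names (`feature_id`, `rt`,
#'   `mz`, `intensity`, `polarity`, `matrix`, `adduct`, `ms2`) to the column
#'   names used in the file. Unmapped canonical names default to themselves.
#' @param rt_unit `"min"` or `"sec"`; seconds are converted to minutes on read.
#' @param default_polarity Used when the file has no polarity column.
#' @param default_matrix Used when the file has no matrix column.
#' @return A `feature_dialect` object.
#' @export
feature_dialect <- function(delimiter = ",", columns = list(),
                            rt_unit = c("min", "sec"),
                            default_polarity = "negative",
                            default_matrix = "other") {
  rt_unit <- match.arg(rt_unit)
  canon <- c("feature_id", "rt", "mz", "intensity", "polarity", "matrix",
             "adduct", "ms2")
  map <- stats::setNames(as.list(canon), canon)
  for (nm in names(columns)) {
    if (!nm %in% canon) stop("unknown dialect column: ", nm, call. = FALSE)
    map[[nm]] <- columns[[nm]]
  }
  structure(
    list(delimiter = delimiter, columns = map, rt_unit = rt_unit,
         default_polarity = default_polarity,
         default_matrix = default_matrix),
    class = "feature_dialect"
  )
}

parse_ms2_inline <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  mz <- numeric(length(parts))
  int <- numeric(length(parts))
  for (i in seq_along(parts)) {
    kv <- strsplit(trimws(parts[i]), ":", fixed = TRUE)[[1]]
    mz[i] <- as.numeric(kv[1])
    int[i] <- if (length(kv) > 1L) as.numeric(kv[2]) else 1
  }
  if (any(is.na(mz)) || any(is.na(int))) {
    stop("unparsable MS2 string: '", s, "'", call. = FALSE)
  }
  o <- order(mz)
  data.frame(mz = mz[o], intensity = int[o])
}

format_ms2_inline <- function(frags) {
  if (is.null(frags) || nrow(frags) == 0L) return("")
  paste(sprintf("%.5f:%.6g", frags$mz, frags$intensity), collapse = ";")
}

# numeric coercion with row-located errors
.as_num_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad)) {
    stop("column '", col, "': unparsable numeric value at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate and normalise a feature table
#'
#' Ensures the canonical feature columns are present and well formed. `ms2`
#' may be a list-column of fragment data.frames (columns `mz`, `intensity`)
#' or an inline-string column; either is normalised to the list-column form.
#'
#' @param df A data.frame of aligned MS1 features.
#' @return A validated feature data.frame with an `ms2` list-column.
#' @export
as_features <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("rt", "mz", "intensity")) {
    if (!col %in% names(df)) {
      stop("feature table is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  n <- nrow(df)
  out <- data.frame(
    feature_id = if ("feature_id" %in% names(df)) as.character(df$feature_id)
                 else sprintf("F%04d", seq_len(n)),
    rt = .as_num_col(df$rt, "rt"),
    mz = .as_num_col(df$mz, "mz"),
    intensity = .as_num_col(df$intensity, "intensity"),
    polarity = if ("polarity" %in% names(df)) as.character(df$polarity)
               else rep("negative", n),
    matrix = if ("matrix" %in% names(df)) as.character(df$matrix)
             else rep("other", n),
    adduct = if ("adduct" %in% names(df)) as.character(df$adduct)
             else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if ("ms2" %in% names(df) && is.list(df$ms2) && !is.data.frame(df$ms2)) {
    out$ms2 <- I(lapply(df$ms2, function(x) {
      if (is.null(x)) data.frame(mz = numeric(0), intensity = numeric(0))
      else x[order(x$mz), , drop = FALSE]
    }))
  } else if ("ms2" %in% names(df)) {
    out$ms2 <- I(lapply(as.character(df$ms2), parse_ms2_inline))
  } else {
    out$ms2 <- I(replicate(n, data.frame(mz = numeric(0),
                                         intensity = numeric(0)),
                           simplify = FALSE))
  }
  if (any(out$mz <= 0)) stop("feature m/z must be > 0", call. = FALSE)
  if (any(out$rt < 0)) stop("feature rt must be >= 0", call. = FALSE)
  if (any(out$intensity < 0)) {
    stop("feature intensity must be >= 0", call. = FALSE)
  }
  for (i in seq_len(n)) {
    fr <- out$ms2[[i]]
    if (nrow(fr) && any(fr$mz >= out$mz[i] + 0.5)) {
      stop("feature ", out$feature_id[i],
           ": MS2 fragment m/z exceeds precursor m/z + 0.5", call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a delimited feature table
#'
#' @param path Path to a delimited text file.
#' @param dialect A [feature_dialect()] describing delimiter, column names and
#'   retention-time unit.
#' @return A feature data.frame (see [as_features()]).
#' @export
read_feature_table <- function(path, dialect = feature_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE,
                           colClasses = "character")
  cols <- dialect$columns
  for (col in c("rt", "mz", "intensity")) {
    if (!cols[[col]] %in% names(raw)) {
      stop("feature table ", path, " is missing required column '",
           cols[[col]], "' (", col, ")", call. = FALSE)
    }
  }
  df <- data.frame(
    rt = raw[[cols$rt]], mz = raw[[cols$mz]],
    intensity = raw[[cols$intensity]], stringsAsFactors = FALSE
  )
  opt <- function(col, default) {
    if (cols[[col]] %in% names(raw)) raw[[cols[[col]]]] else default
  }
  df$feature_id <- opt("feature_id", sprintf("F%04d", seq_len(nrow(raw))))
  df$polarity <- opt("polarity", dialect$default_polarity)
  df$matrix <- opt("matrix", dialect$default_matrix)
  df$adduct <- opt("adduct", NA_character_)
  df$ms2 <- opt("ms2", "")
  out <- as_features(df)
  if (dialect$rt_unit == "sec") out$rt <- out$rt / 60
  out
}

#' Write a feature table as delimited text
#'
#' MS2 list-columns are serialised inline as `mz:intensity;...` strings.
#'
#' @param features A feature data.frame.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_feature_table <- function(features, path, delimiter = ",") {
  df <- features
  if ("ms2" %in% names(df) && is.list(df$ms2)) {
    df$ms2 <- vapply(df$ms2, format_ms2_inline, character(1))
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Validate and normalise a prototype (herb component) list
#'
#' Requires `compound_id`, `rt`, `mz`, `polarity`; `adduct` defaults to the
#' polarity's primary adduct (M+H / M-H). Computes `neutral_mass` from the
#' adduct hypothesis and, when a molecular `formula` is given, checks it
#' against the neutral mass (10 ppm) and derives the nitrogen count used by
#' the N-rule.
#'
#' @param df A data.frame with one row per herb component.
#' @return A validated prototype data.frame with `neutral_mass`, `n_count`
#'   and an `ms2` list-column.
#' @export
as_prototypes <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("compound_id", "rt", "mz", "polarity")) {
    if (!col %in% names(df)) {
      stop("prototype table is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  n <- nrow(df)
  out <- data.frame(
    compound_id = as.character(df$compound_id),
    name = if ("name" %in% names(df)) as.character(df$name)
           else as.character(df$compound_id),
    rt = .as_num_col(df$rt, "rt"),
    mz = .as_num_col(df$mz, "mz"),
    polarity = as.character(df$polarity),
    adduct = if ("adduct" %in% names(df)) as.character(df$adduct)
             else default_adduct(as.character(df$polarity)),
    formula = if ("formula" %in% names(df)) as.character(df$formula)
              else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$compound_id)) {
    stop("duplicate compound_id in prototype table", call. = FALSE)
  }
  tab <- adducts()
  pol <- tab$polarity[match(out$adduct, tab$name)]
  if (any(is.na(pol))) {
    stop("unknown adduct in prototype table: ",
         paste(unique(out$adduct[is.na(pol)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(pol != out$polarity)) {
    stop("adduct/polarity mismatch in prototype table", call. = FALSE)
  }
  out$neutral_mass <- neutral_mass(out$mz, out$adduct)
  out$n_count <- vapply(out$formula, formula_n_count, numeric(1))
  has_f <- !is.na(out$formula) & nzchar(out$formula)
  if (any(has_f)) {
    fm <- vapply(out$formula[has_f], formula_mass, numeric(1))
    ppm <- abs(fm - out$neutral_mass[has_f]) / fm * 1e6
    if (any(ppm > 10)) {
      warning("prototype formula disagrees with neutral mass by > 10 ppm: ",
              paste(out$compound_id[has_f][ppm > 10], collapse = ", "),
              call. = FALSE)
    }
  }
  if ("ms2" %in% names(df) && is.list(df$ms2) && !is.data.frame(df$ms2)) {
    out$ms2 <- I(lapply(df$ms2, function(x) {
      if (is.null(x)) data.frame(mz = numeric(0), intensity = numeric(0))
      else x[order(x$mz), , drop = FALSE]
    }))
  } else if ("ms2" %in% names(df)) {
    out$ms2 <- I(lapply(as.character(df$ms2), parse_ms2_inline))
  } else {
    out$ms2 <- I(replicate(n, data.frame(mz = numeric(0),
                                         intensity = numeric(0)),
                           simplify = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Read a prototype list from delimited text
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter.
#' @return A prototype data.frame (see [as_prototypes()]).
#' @export
read_prototype_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE,
                           colClasses = "character")
  as_prototypes(raw)
}

#' Write a prototype table as delimited text
#'
#' @param prototypes A prototype data.frame.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_prototype_table <- function(prototypes, path, delimiter = ",") {
  df <- prototypes
  if ("ms2" %in% names(df) && is.list(df$ms2)) {
    df$ms2 <- vapply(df$ms2, format_ms2_inline, character(1))
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' Blocks are keyed by `FEATURE_ID=`, falling back to `TITLE=`. Blocks
#' without a `PEPMASS` line are skipped with a warning.
#'
#' @param path Path to an MGF file.
#' @return A named list of fragment data.frames (`mz`, `intensity`), sorted by
#'   m/z; each carries the precursor as attribute `pepmass`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      j <- i + 1L
      key <- NULL
      pepmass <- NA_real_
      mz <- numeric(0)
      int <- numeric(0)
      while (j <= n && trimws(lines[j]) != "END IONS") {
        ln <- trimws(lines[j])
        if (grepl("^FEATURE_ID=", ln)) {
          key <- sub("^FEATURE_ID=", "", ln)
        } else if (grepl("^TITLE=", ln) && is.null(key)) {
          key <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "[[:space:]]+")[[1]][1])
        } else if (grepl("^[0-9]", ln)) {
          kv <- strsplit(ln, "[[:space:]]+")[[1]]
          mz <- c(mz, as.numeric(kv[1]))
          int <- c(int, if (length(kv) > 1L) as.numeric(kv[2]) else 1)
        }
        j <- j + 1L
      }
      if (is.na(pepmass)) {
        warning("MGF block ", if (is.null(key)) "<untitled>" else key,
                " has no PEPMASS; skipped", call. = FALSE)
      } else {
        if (is.null(key)) key <- sprintf("spectrum_%03d", length(out) + 1L)
        o <- order(mz)
        frags <- data.frame(mz = mz[o], intensity = int[o])
        attr(frags, "pepmass") <- pepmass
        out[[key]] <- frags
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Attach MGF spectra to a feature table
#'
#' @param features A feature data.frame.
#' @param spectra A named list from [read_mgf()], keyed by feature_id.
#' @return The feature table with matching `ms2` entries replaced.
#' @export
attach_ms2 <- function(features, spectra) {
  idx <- match(features$feature_id, names(spectra))
  for (i in which(!is.na(idx))) {
    fr <- spectra[[idx[i]]]
    attr(fr, "pepmass") <- NULL
    features$ms2[[i]] <- fr
  }
  features
}

.EDGE_COLUMNS <- c("prototype_id", "feature_id", "category", "pathway",
                   "n_steps", "match_degree", "delta_ppm", "base",
                   "ms2_similarity", "ms2_defect_bonus", "confidence",
                   "total", "retained", "rank")

#' Write a scored edge table as CSV
#'
#' @param x A `component_network` (see [build_network()]) or an edge
#'   data.frame as produced by [run_mdrb()].
#' @param path Output path.
#' @export
write_edge_table <- function(x, path) {
  edges <- if (inherits(x, "component_network")) x$edges else x
  keep <- intersect(.EDGE_COLUMNS, names(edges))
  if (nrow(edges) == 0L) {
    edges <- edges[, keep, drop = FALSE]
  } else {
    edges <- edges[, keep, drop = FALSE]
  }
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Path to the CSV file.
#' @return An edge data.frame.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("retained" %in% names(df)) df$retained <- as.logical(df$retained)
  df
}

#' Write a component network as GraphML
#'
#' Node and edge attributes (matrix, category, scores) are carried so the
#' file can be laid out in external viewers such as Cytoscape.
#'
#' @param network A `component_network` from [build_network()].
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "component_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back into node and edge tables
#'
#' @param path Path to a GraphML file written by [write_graphml()].
#' @return A list with `nodes` and `edges` data.frames.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  list(nodes = nodes, edges = edges, graph = g)
}
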