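# Precise-and-thorough background subtraction (PATBS): non-targeted removal
# of endogenous signals by comparing post-dose sample feature lists against
# pre-dose blanks within narrow m/z and RT windows.

#' PATBS parameters
#'
#' @param mass_window m/z window in ppm (default 10).
#' @param time_window RT window in minutes (default 0.5).
#' @param subtraction_ratio A sample feature window-matched to a blank feature
#'   is removed when its intensity is at most `subtraction_ratio` times the
#'   blank intensity. `Inf` reduces to pure presence/absence subtraction.
#' @return A `patbs_params` object.
#' @export
patbs_params <- function(mass_window = 10, time_window = 0.5,
                         subtraction_ratio = 3.0) {
  stopifnot(mass_window > 0, time_window > 0, subtraction_ratio >= 0)
  structure(list(mass_window = mass_window, time_window = time_window,
                 subtraction_ratio = subtraction_ratio),
            class = "patbs_params")
}

#' Subtract blank (pre-dose) background from a sample feature list
#'
#' A sample feature is removed iff some blank feature lies within
#' `mass_window` ppm in m/z and `time_window` minutes in RT, and the sample
#' intensity does not exceed `subtraction_ratio` times the blank intensity.
#' When several blank features fall in the window (e.g. blank replicates),
#' the maximum blank intensity is used, which is the conservative choice.
#' Retained features are returned unchanged, in input order.
#'
#' @param sample Feature data.frame (post-dose).
#' @param blank Feature data.frame (pre-dose), or a list of them (replicates).
#' @param params A [patbs_params()] object.
#' @return The retained subset of `sample`.
#' @export
subtract_background <- function(sample, blank, params = patbs_params()) {
  sample <- as_features(sample)
  if (is.data.frame(blank)) blank <- list(blank)
  blank <- lapply(blank, as_features)
  blank_mz <- unlist(lapply(blank, `[[`, "mz"))
  blank_rt <- unlist(lapply(blank, `[[`, "rt"))
  blank_int <- unlist(lapply(blank, `[[`, "intensity"))
  blank_pol <- unlist(lapply(blank, `[[`, "polarity"))
  if (length(blank_mz) == 0L) return(sample)
  pols <- unique(c(sample$polarity, blank_pol))
  if (length(pols) > 1L) {
    stop("sample and blank must share a single polarity; got: ",
         paste(pols, collapse = ", "), call. = FALSE)
  }
  removed <- vapply(seq_len(nrow(sample)), function(i) {
    hit <- abs(blank_mz - sample$mz[i]) <=
             params$mass_window * 1e-6 * sample$mz[i] &
           abs(blank_rt - sample$rt[i]) <= params$time_window
    any(hit) &&
      sample$intensity[i] <= params$subtraction_ratio * max(blank_int[hit])
  }, logical(1))
  out <- sample[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool background-subtracted features across biological matrices
#'
#' Takes the per-matrix PATBS outputs and merges features that co-occur in
#' several matrices (same compound detected in, say, plasma and urine) into a
#' single drug-related component, using the prototype-matching tolerances.
#' The representative row of a merged group is its highest-intensity member;
#' per-matrix presence flags (`in_<matrix>`) record where the component was
#' seen.
#'
#' @param per_matrix Named list, matrix name -> background-subtracted feature
#'   data.frame.
#' @param mz_tol_ppm Merge tolerance in ppm (default 5).
#' @param rt_tol_s Merge tolerance in seconds (default 25).
#' @return A feature data.frame with one row per distinct component, plus
#'   per-matrix presence flags and a comma-separated `matrix` field.
#' @export
collect_related_components <- function(per_matrix, mz_tol_ppm = 5,
                                       rt_tol_s = 25) {
  stopifnot(is.list(per_matrix), length(per_matrix) > 0L,
            !is.null(names(per_matrix)))
  matrices <- names(per_matrix)
  stacked <- do.call(rbind, lapply(matrices, function(m) {
    f <- as_features(per_matrix[[m]])
    if (nrow(f)) f$matrix <- m
    f
  }))
  if (nrow(stacked) == 0L) {
    out <- stacked
    for (m in matrices) out[[paste0("in_", m)]] <- logical(0)
    return(out)
  }
  o <- order(-stacked$intensity)
  stacked <- stacked[o, , drop = FALSE]
  rt_tol <- rt_tol_s / 60
  group <- integer(nrow(stacked))
  rep_mz <- numeric(0)
  rep_rt <- numeric(0)
  rep_pol <- character(0)
  for (i in seq_len(nrow(stacked))) {
    hit <- which(
      rep_pol == stacked$polarity[i] &
      abs(rep_mz - stacked$mz[i]) <= mz_tol_ppm * 1e-6 * stacked$mz[i] &
      abs(rep_rt - stacked$rt[i]) <= rt_tol
    )
    if (length(hit)) {
      group[i] <- hit[1L]
    } else {
      rep_mz <- c(rep_mz, stacked$mz[i])
      rep_rt <- c(rep_rt, stacked$rt[i])
      rep_pol <- c(rep_pol, stacked$polarity[i])
      group[i] <- length(rep_mz)
    }
  }
  reps <- match(seq_along(rep_mz), group)  # first (= most intense) member
  out <- stacked[reps, , drop = FALSE]
  for (m in matrices) {
    out[[paste0("in_", m)]] <- vapply(seq_along(reps), function(g) {
      m %in% stacked$matrix[group == g]
    }, logical(1))
  }
  out$matrix <- vapply(seq_along(reps), function(g) {
    paste(matrices[matrices %in% stacked$matrix[group == g]], collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}
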