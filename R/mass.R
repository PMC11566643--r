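# Monoisotopic masses and small-molecule formula arithmetic.
#
# All masses in Da. Charge is fixed at 1 throughout the package; every adduct
# handled here is singly charged.

.ELEMENT_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322
)

.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula into signed atom counts
#'
#' Accepts plain formulas (`"C6H10O5"`), signed formulas (`"-C6H10O5"`,
#' `"+O"`), and signed compounds (`"+O-H2"`). Elements are restricted to the
#' CHNOPS set plus Na, K, Cl, F.
#'
#' @param formula A single formula string.
#' @return A named numeric vector of (possibly negative) atom counts.
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("-H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- gsub("[[:space:]]", "", formula)
  if (!nzchar(f)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  segs <- regmatches(f, gregexpr("[+-]?[A-Za-z0-9]+", f))[[1]]
  if (paste(segs, collapse = "") != f) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  counts <- c()
  for (seg in segs) {
    sgn <- 1
    if (startsWith(seg, "-")) {
      sgn <- -1
      seg <- substring(seg, 2L)
    } else if (startsWith(seg, "+")) {
      seg <- substring(seg, 2L)
    }
    toks <- regmatches(seg, gregexpr("([A-Z][a-z]?)([0-9]*)", seg))[[1]]
    toks <- toks[nzchar(toks)]
    if (paste(toks, collapse = "") != seg) {
      stop("cannot parse formula segment: '", seg, "'", call. = FALSE)
    }
    for (tok in toks) {
      el <- gsub("[0-9]+$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% names(.ELEMENT_MASS)) {
        stop("unknown element '", el, "' in formula '", formula, "'",
             call. = FALSE)
      }
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + sgn * n
    }
  }
  counts[counts != 0]
}

#' Monoisotopic mass of a formula
#'
#' @param formula A formula string (see [parse_formula()]) or a named numeric
#'   vector of atom counts.
#' @return Signed monoisotopic mass in Da.
#' @examples
#' formula_mass("C6H10O5")   # 162.0528
#' formula_mass("-H2O")      # -18.0106
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  sum(.ELEMENT_MASS[names(counts)] * counts)
}

# canonical key for net-composition deduplication
formula_key <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return("")
  counts <- counts[order(names(counts))]
  paste(names(counts), counts, sep = ":", collapse = ",")
}

# nitrogen count of a formula string, NA_real_ if missing/NA
formula_n_count <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  counts <- parse_formula(formula)
  if ("N" %in% names(counts)) counts[["N"]] else 0
}

#' Mass defect of an exact mass
#'
#' The signed deviation of a monoisotopic mass from its nearest integer mass,
#' in milli-mass units (mmu). This is the quantity bounded by the +/- 25 mmu
#' windows of the unpredictable-metabolite and MS2 screens. The
#' nearest-integer convention is unstable for masses close to a half-integer;
#' a warning is emitted there.
#'
#' @param m Exact mass(es) in Da, all > 0.
#' @param warn_half Warn when a mass lies within 30 mmu of a half-integer.
#' @return Signed defect(s) in mmu, in (-500, 500].
#' @examples
#' mass_defect(457.1478)  # 147.8
#' @export
mass_defect <- function(m, warn_half = TRUE) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    stop("mass must be a positive finite number", call. = FALSE)
  }
  frac <- m - round(m)
  if (warn_half && any(abs(abs(frac) - 0.5) < 0.030)) {
    warning("mass within 30 mmu of a half-integer: ",
            "nearest-integer mass defect is unstable there", call. = FALSE)
  }
  frac * 1000
}

#' Supported adduct hypotheses
#'
#' Singly charged adducts used to convert observed m/z to neutral mass:
#' \[M+H\]+, \[M+Na\]+, \[M+NH4\]+ in positive mode; \[M-H\]-, \[M+HCOO\]- in
#' negative mode. `mass_shift` is the signed Da difference between observed
#' m/z and the neutral monoisotopic mass.
#'
#' @return A data.frame with columns `name`, `polarity`, `mass_shift`,
#'   `charge`.
#' @export
adducts <- function() {
  data.frame(
    name = c("M+H", "M+Na", "M+NH4", "M-H", "M+HCOO"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    mass_shift = c(
      .PROTON_MASS,
      .ELEMENT_MASS[["Na"]] - .ELECTRON_MASS,
      .ELEMENT_MASS[["N"]] + 4 * .ELEMENT_MASS[["H"]] - .ELECTRON_MASS,
      -.PROTON_MASS,
      .ELEMENT_MASS[["C"]] + .ELEMENT_MASS[["H"]] +
        2 * .ELEMENT_MASS[["O"]] + .ELECTRON_MASS
    ),
    charge = 1L,
    stringsAsFactors = FALSE
  )
}

adduct_shift <- function(name) {
  tab <- adducts()
  idx <- match(name, tab$name)
  if (any(is.na(idx))) {
    stop("unknown adduct: ", paste(unique(name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tab$mass_shift[idx]
}

default_adduct <- function(polarity) {
  ifelse(polarity == "positive", "M+H",
         ifelse(polarity == "negative", "M-H", NA_character_))
}

#' Neutral monoisotopic mass from an observed m/z
#'
#' @param mz Observed m/z (Th), singly charged.
#' @param adduct Adduct name(s), see [adducts()].
#' @return Neutral mass(es) in Da.
#' @examples
#' neutral_mass(458.1551, "M+H")
#' @export
neutral_mass <- function(mz, adduct) {
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("m/z must be positive and finite", call. = FALSE)
  }
  mz - adduct_shift(adduct)
}

#' Observed m/z of a neutral mass under an adduct hypothesis
#'
#' Inverse of [neutral_mass()].
#'
#' @param m Neutral monoisotopic mass(es) in Da.
#' @param adduct Adduct name(s).
#' @return Observed m/z value(s).
#' @export
mz_from_neutral <- function(m, adduct) {
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("mass must be positive and finite", call. = FALSE)
  }
  m + adduct_shift(adduct)
}
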