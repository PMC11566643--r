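# In-code fixtures shared across the suite.

frags <- function(mz, intensity = rep(100, length(mz))) {
  data.frame(mz = mz, intensity = intensity)
}

make_features <- function(mz, rt, intensity = rep(1e5, length(mz)),
                          polarity = "negative", matrix = "plasma",
                          adduct = NA_character_, ms2 = NULL,
                          feature_id = sprintf("F%03d", seq_along(mz))) {
  df <- data.frame(feature_id = feature_id, rt = rt, mz = mz,
                   intensity = intensity, polarity = polarity,
                   matrix = matrix, adduct = adduct,
                   stringsAsFactors = FALSE)
  if (!is.null(ms2)) df$ms2 <- I(ms2)
  as_features(df)
}

make_prototypes <- function(mz, rt, polarity = "negative",
                            adduct = NULL, formula = NA_character_,
                            ms2 = NULL,
                            compound_id = sprintf("H%02d", seq_along(mz))) {
  if (is.null(adduct)) {
    adduct <- ifelse(polarity == "positive", "M+H", "M-H")
  }
  df <- data.frame(compound_id = compound_id, name = compound_id, rt = rt,
                   mz = mz, polarity = polarity, adduct = adduct,
                   formula = formula, stringsAsFactors = FALSE)
  if (!is.null(ms2)) df$ms2 <- I(ms2)
  as_prototypes(df)
}

# amygdalin-like prototype (C20H27NO11, [M-H]-) with three diagnostic
# fragments, and a deglycosylated (prunasin-like) metabolite feature sharing
# `n_shared` of them exactly; the worked scoring example of the bridging
# mechanism.
worked_example <- function(n_shared = 3) {
  amygdalin_neutral <- formula_mass("C20H27NO11")
  prunasin_neutral <- amygdalin_neutral + formula_mass("-C6H10O5")
  proto_frags <- frags(c(263.0925, 161.0455, 119.0350))
  proto <- make_prototypes(
    mz = mz_from_neutral(amygdalin_neutral, "M-H"), rt = 5.8,
    formula = "C20H27NO11", ms2 = list(proto_frags),
    compound_id = "AMY"
  )
  shared <- proto_frags[seq_len(n_shared), , drop = FALSE]
  feat <- make_features(
    mz = mz_from_neutral(prunasin_neutral, "M-H"), rt = 7.4,
    adduct = "M-H", ms2 = list(shared), feature_id = "MET1"
  )
  list(prototypes = proto, features = feat)
}
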