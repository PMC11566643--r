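---
title: "Bridging herbal prototypes to in vivo metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging herbal prototypes to in vivo metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrb)
```

## The problem

An orally dosed herbal extract contains tens to hundreds of chemical
constituents ("prototypes"). After dosing, a biological sample contains a
mixture of endogenous compounds, absorbed prototypes, and metabolites arising
from one or two metabolic transformations of the prototypes. Untargeted
LC-HRMS detects all of them as (RT, m/z, intensity) features; the analytical
problem is (i) removing the endogenous background, and (ii) deciding, for
each remaining feature, *which prototype it came from and by which
transformation* — including transformations that no catalog predicts.

`mdrb` implements the two post-processing stages of that workflow as a
library plus a command-line tool:

* **PATBS** (precise-and-thorough background subtraction): feature-list
  comparison of a post-dose sample against the pre-dose blank inside narrow
  m/z and RT windows.
* **MDRB** (mass dataset relevance bridging): stepwise matching of the
  background-subtracted in vivo component list against the prototype list,
  with a point-score expressing the strength of each candidate link.

## Background subtraction

A sample feature is removed when some blank feature lies within
`mass_window` ppm (default 10) and `time_window` min (default 0.5) **and**
the sample intensity is at most `subtraction_ratio` (default 3) times the
matched blank intensity. The ratio criterion keeps drug-related signals that
happen to coincide with a weak endogenous peak: only features that are *not
substantially more intense* than the blank are treated as background. The
ratio is deliberately configurable; `Inf` reduces the operation to pure
presence/absence subtraction. With several blank replicates the **maximum**
matched blank intensity is used — the conservative choice, removing a
feature if any replicate can explain it. Removal is monotone: raising the
ratio or widening either window can only shrink the retained set, and
subtracting a list from itself (ratio ≥ 1) empties it.

Per-matrix outputs (plasma, lung, urine, feces) are pooled by
`collect_related_components()`, which merges re-detections of the same
component across matrices at the prototype-matching tolerances (±5 ppm,
±25 s) and keeps per-matrix presence flags — the input to the ADME-style
per-matrix summaries.

## The stepwise bridging algorithm

All matching operates on one polarity stream at a time; observed m/z is
converted to neutral mass through the feature's adduct hypothesis
([M+H]⁺, [M+Na]⁺, [M+NH4]⁺, [M−H]⁻, [M+HCOO]⁻; charge fixed at 1).

**Step 1 — prototypes and isomers.** A feature matching a prototype within
±5 ppm (m/z) and ±25 s (RT) is that prototype, absorbed unchanged; matching
in m/z but not RT makes it an isomer. Both carry a sentinel full score of
100 and no pathway, and such features take no further part in matching.

**Step 2 — predictable metabolites.** The catalog of biotransformations is
expanded into all one- and two-step pathways. For every (prototype,
pathway), the predicted metabolite mass is the prototype neutral mass plus
the net pathway delta; a feature within ±5 ppm *of the predicted mass* is a
candidate with base score 70. The N-rule restricts pathways to a net
nitrogen change of at most ±3, and pathways that would drive a prototype's
known nitrogen count negative are skipped.

**Step 3 — unpredictable metabolites.** Features still lacking a retained
edge are screened against each prototype by MS1 proximity (±100 amu) plus
mass-defect agreement (±25 mmu): base score 50. The mass difference is
recorded as the pathway annotation, tagged with a catalog rule when one
matches it within 5 mmu. Candidates are retained when their total reaches
the retention score (50), so an MS1-only defect match sits exactly on the
threshold. Features that fail every step are *elusive*.

**MS2 scoring (steps 2 and 3).** Fragments are paired one-to-one:

1. *Exact tier*: pairs within `ms2_frag_tol` (0.01 Da), greedy
   nearest-first, ties toward the higher summed intensity. The exact-match
   count sets the similarity points — 20 at degree 1, 30 at degree ≥ 2.
2. *Defect tier*: remaining fragments pair when within ±50 amu and ±25 mmu
   of defect difference; each such pair raises the match degree by one and
   adds 5 points.

A separate 2-point *confidence* flag marks candidates that hold at least one
fragment whose mass defect agrees with the precursor's within ±50 mmu. It is
reported as its own column and **not** added to the total by default: with
it included, the canonical three-fragment predictable candidate would score
102 rather than the documented 100 (`include_confidence_in_total = TRUE`
restores the additive reading).

A feature may bridge to several prototypes — structurally similar parents
can yield identical metabolites — so ambiguity is resolved by *ranking*, not
pruning: per feature, retained edges are ordered by total score, then
smaller |Δppm| from the predicted mass, then fewer pathway steps, then
prototype id. The engine is fully deterministic.

### Why the 20/30 tier counts exact matches only

The published description of the defect tier ("the matching degree will be
increased by one") can be read two ways: the 20/30 similarity tier could be
computed from the exact-match count or from the pooled degree (exact +
defect). We default to *exact matches only*, because the worked example
(base 70 + three shared fragments = 100; one shared fragment = 90) is
reproduced by the exact tier and describes the 5-point mechanism as separate
per-match increments. Under the pooled reading a purely defect-matched
candidate would jump from 50 + 5k to 50 + 30 + 5k. Both readings are
implemented; `pooled_degree_scoring = TRUE` selects the alternative.

### Mass-defect convention

The sources never state a rounding convention. We use the dominant one:
defect(m) = (m − round(m)) × 1000 mmu, signed, so defects live in
(−500, 500] and defect differences are symmetric. Differences are taken
directly with no wraparound; a warning is emitted whenever a mass lies
within 30 mmu of a half-integer, where the nearest-integer convention is
unstable.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `mass_window` (PATBS) | 10 | ppm | blank-vs-sample m/z window |
| `time_window` (PATBS) | 0.5 | min | blank-vs-sample RT window |
| `subtraction_ratio` | 3 | — | max sample/blank intensity ratio for removal |
| `rt_tol` | 25 | s | prototype RT window |
| `mz_tol` | 5 | ppm | prototype / predicted-mass m/z window |
| `ms1_window` | 100 | amu | unpredictable MS1 proximity |
| `ms1_defect_tol` | 25 | mmu | unpredictable MS1 defect window |
| `ms2_window` | 50 | amu | MS2 defect-tier proximity |
| `ms2_defect_tol` | 25 | mmu | MS2 defect-tier window |
| `ms2_frag_tol` | 0.01 | Da | exact fragment match |
| `ms1_ms2_defect_tol` | 50 | mmu | precursor↔fragment confidence |
| `retention_score` | 50 | points | minimum retained total |
| `max_delta_n` | 3 | atoms | N-rule bound |

The ±25 mmu MS1/MS2 defect windows are the published optimum of a
10/25/50/75 mmu sweep balancing pathway coverage against false-positive
inclusion; `sweep_defect_window()` reproduces that sweep on any dataset, and
its candidate counts are non-decreasing in the window by construction.

## The biotransformation catalog

The catalog is data, not code: a TSV with `label`, `delta_formula`,
`delta_mass`, `delta_n`, `phase`, validated on load (formula mass must agree
with the stated delta within 1e-4 Da; |Δ nitrogen| ≤ 3). The shipped default
holds 23 canonical reactions — phase I redox and hydrolysis steps, phase II
conjugations, and the glycoside losses (hexose, pentose, deoxyhexose,
glucuronide) that glycosylated herbal constituents readily undergo — in the
spirit of the Metworks default transformation set extended with
deglycosylations. Users with a study-specific list substitute their own
file; the engine is catalog-parametric.

Pathway enumeration takes all singles and all unordered pairs *with
repetition* (di-oxidation via two oxidations is chemically routine), drops
composites breaking the N-rule, and deduplicates identical net elemental
compositions, preferring the shorter pathway and then the lexicographically
smallest label sequence — so "dehydrogenation + hydration" collapses onto
"oxidation". Exact zero-net pairs (e.g. methylation + demethylation) are
kept but flagged `near_null` (|net Δm| < 2.5 mmu), since at matching
tolerance they merely duplicate isomer candidates.

## The simulator and what passing tests mean

`simulate_herb()` generates the statistical structure the bridging algorithm
assumes, with complete ground truth:

* prototypes with realistic CHNO(S) formulas (150–800 Da, 0–4 nitrogens),
  random RT, and 3–8 MS2 fragments, two of which are family-shared cores;
* metabolites created by applying enumerated catalog pathways (N-rule and
  elemental feasibility respected; ~20% two-step), whose MS2 is a subset of
  the parent's fragments — each survivor is unshifted (conserved core) or
  shifted by the pathway delta (moiety-bearing) with probability 0.5, which
  exercises the exact and defect scoring tiers respectively by
  construction. Whenever any fragment survives, at least one stays
  unshifted: the conserved-parent-nucleus assumption that makes bridging
  identifiable at all;
* endogenous features written identically into blank and sample tables, so
  background subtraction must remove them;
* measurement error: observed m/z = true m/z × (1 + ε). The `mz_noise`
  parameter (default 5 ppm) is an instrument *accuracy bound*, implemented
  as ε ~ N(0, (mz_noise/3)²) so ~99.7% of errors fall inside it — matching
  how "5 ppm mass accuracy" is specified for Orbitrap-class instruments.
  RT jitter (default σ = 10 s) applies to in vivo re-detections of a
  prototype.

The simulator does **not** model chromatographic peak shape, isotope
envelopes, multiply charged species, in-source fragmentation, matrix-
dependent ionisation suppression, or MS2 fragments newly created in the
metabolite (only inherited ones). Passing recovery tests therefore shows
that the screening windows, scoring and bookkeeping are implemented
correctly under the stated noise model — not that the method's error rates
transfer to any particular instrument or matrix.

The test suite runs the pipeline at desk scale — 10 prototypes, ~3
metabolites per prototype (Poisson), 200 endogenous features, 4 matrices,
and 20 brute-force-verified fixtures of ≤ 50 features — chosen to exercise
every code path while keeping the default run near half a minute. Under the
noise-free setting the pipeline recovers 100% of catalog-pathway truth
edges; under the default 5 ppm / 10 s setting the suite asserts recall
≥ 0.9 and precision ≥ 0.8 against ground truth (these thresholds are
properties of the generator's conditions, verified by an independent
brute-force matcher on small fixtures).

## Numerical and degenerate-input choices

* Monoisotopic element masses are CODATA/NIST values; adduct shifts are
  derived from them including the electron mass. Neutral-mass round trips
  are exact to < 1e-9 Da.
* ppm tolerances in the predictable pass are computed on the *predicted*
  metabolite mass, not the prototype mass.
* Features without an annotated adduct are compared on raw m/z in the
  unpredictable pass and assumed to carry the polarity's primary adduct
  ([M+H]⁺ / [M−H]⁻) when a neutral mass is required.
* Candidates without any MS2 spectrum: predictable edges are kept at base 70
  with the match degree recorded as missing (MS1-only entries are routine in
  real lists); unpredictable edges sit at exactly the retention threshold.
* Greedy fragment pairing uses each fragment at most once; exact ties in
  both distance and intensity are resolved by scan order (measure-zero for
  continuous data).
* Empty blank lists are the identity for PATBS; an empty prototype list is a
  configuration error for the bridging engine.

## Known limitations

* Mass-only matching cannot distinguish isobaric transformations or site
  isomers; the score ranks plausibility, it does not prove structure.
* Two-step pathway enumeration is the hard ceiling (as published); chains of
  three or more reactions surface, at best, as unpredictable matches.
* Cross-polarity merging of the same compound is an annotation concern, not
  an I/O merge; each polarity is processed as its own stream.
* The nearest-integer defect convention is unstable within ~30 mmu of
  half-integer masses (warned, not corrected).
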