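---
title: "mhcbinder methods: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mhcbinder methods: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcbinder)
```

## The model and its assumptions

Peptides presented by one HLA class I allele share a sequence motif
imposed by the binding groove, concentrated at a small number of anchor
positions. `mhcbinder` summarizes that motif, per allele and per peptide
length *N*, as a 20 × *N* position-specific scoring matrix of log-odds

$$P_{ai} = \log\frac{F_{ai} + \omega}{BG_a},$$

with $F_{ai}$ the training-set proportion of residue $a$ at position $i$,
$BG_a$ a background residue frequency, and $\omega$ a pseudocount. The
assumptions this encodes: positions contribute independently (no pairwise
coupling), binding is determined by the motif alone, and the training
binders are an unbiased sample of the allele's ligands. A peptide's
binding score is the mean matrix lookup $\sum_i P_{a(i),i}/N$, and scores
map to IC50 nM through

$$\mathrm{IC50} = b^{\,(\mathrm{Max}-s)/(\mathrm{Max}-\mathrm{Min})},
\qquad b = 50000,\ \mathrm{Max} = 0.8,\ \mathrm{Min} = -0.8.$$

Pan-specific prediction rests on a second assumption: alleles with
similar protein sequences bind similar peptides. An allele with no
trained model is predicted as the weighted mean
$\mathrm{IC50}_{un} = \sum_i w_i\,\mathrm{IC50}_i / \sum_i w_i$ over its
characterized neighbors, weighted by BLOSUM62 local-alignment scores of
the HLA protein sequences.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `omega` (fixed) | 0.02 | proportion | keeps unobserved residues finite; deterministic default. A seeded per-column symmetric Dirichlet(1) mode mirrors the stochastic description of the pseudocount; both are labeled interpretations since its dimension/concentration are not standardized. |
| `log_base` | e | — | the base behind Max/Min is unrecoverable; it is stored inside every model file so models are self-describing, and configurable. |
| `score_max`, `score_min` | 0.8, −0.8 | score | the published transform constants; with them the transform spans exactly [1, 50000] nM. |
| `binder_cutoff`, `strong_cutoff` | 500, 50 | nM | the standard IEDB-recommended class thresholds; comparisons are strict (`<`), so exactly 500 nM is a nonbinder. |
| `min_binders` (training) | 10 | peptides | minimum binder count per (allele, length) group to train a PSSM. |
| `min_binders` (CV) | 12 | peptides | minimum group size to evaluate in cross-validation. |
| gap penalties | open 11, extend 1 | score | protein-BLAST local-alignment convention used for the similarity weights. |
| `constant_weight` | median alignment weight | score | puts nearest-distance pairs (a consumed input list, not re-derived) on the same scale as alignment pairs. |
| `top_k` | all | neighbors | the weighted mean runs over every usable neighbor by default; a cap is exposed for control. |
| CV `k` | 10 | folds | fold sizes differ by at most one; validation adds an equal-count nonbinder set per fold. |
| neoantigen `lengths` | 8–13 | residues | the class I presentation window range used for enumeration. |

## Numerical choices

* **Clamping.** Scores outside [Min, Max] are clamped before
  exponentiation, keeping IC50 in [1, 50000] nM; the transform is then
  strictly decreasing and analytically invertible on the interior
  (round-trip verified to 1e−9).
* **Ties and boundaries.** All IC50 class cutoffs use strict `<`.
  Pan-specific neighbor ranking breaks weight ties by allele name, so
  `top_k` selection is deterministic.
* **Exactness.** A single-neighbor weighted mean is special-cased to
  return the neighbor's IC50 bit-exactly rather than via `×w/Σw`, so the
  consistency limit (an uncharacterized allele whose sequence equals a
  characterized one predicts identically with `top_k = 1`) holds with
  `identical()`, not a tolerance.
* **AUC.** Computed by average ranks, algebraically equal to exhaustive
  (binder, nonbinder) pair counting with ties worth one half; the test
  suite checks equality against a brute-force pair-counting oracle.
* **Degenerate inputs.** An empty library directory loads as an empty
  library with a warning; peptides whose length has no model (or no
  usable neighbor) get a row-level status rather than failing the batch;
  mixed-length binder sets, non-canonical residues, and ref-residue
  mismatches in mutations are hard errors naming the offending input.
* **Reproducibility.** Fixed-ω construction is a pure function; every
  stochastic path (Dirichlet ω, fold splits, nonbinder generation,
  fixtures) takes a seed, and `seed = NULL` consumes the ambient RNG
  stream so composite procedures are reproducible from one outer seed.

## What the synthetic generator emulates — and what it does not

`make_motif_profile()`/`sample_binders()` produce fixed-length binder
sets with 2 anchor positions carrying 0.7 probability on one residue and
background-distributed remaining positions — the anchor-enrichment
structure class I motifs show. `make_synthetic_hla_set()` mutates one
~365-residue ancestor at 2% per site, emulating the high pairwise
similarity of class I heavy chains, and can plant an uncharacterized
allele whose sequence exactly copies a characterized one.

What the generator does **not** emulate: real motifs with more than one
tolerated anchor residue or position-coupled preferences, the skewed
length and affinity distributions of curated epitope databases,
experimental nonbinders (negatives here are background-random), or
genuinely divergent allele families. A green motif-recovery test
therefore establishes that the estimator recovers a planted
independent-position motif and ranks its peptides above background — not
that any particular accuracy holds on real epitope data. Likewise the
pan-specific correlation fixture trains every neighbor on the *same*
motif (the hypothesis-true regime in which similar alleles bind
similarly); it validates the weighted-mean machinery, not the biological
hypothesis.

## Known limitations

* **Score inflation at the 500 nM scale.** With natural log and
  ω = 0.02, a background peptide scored against a background-trained
  column contributes ≈ $\sum_a BG_a\log(1+\omega/BG_a) > 0$, so even
  random peptides tend to land below 500 nM. Ranking (AUC) is unaffected
  — it is the desk-scale metric used throughout — but the absolute
  accuracy at the 500 nM cutoff is poor under these defaults, and
  cross-validation output shows it honestly (specificity near zero).
  Published accuracy at that cutoff depended on a large curated training
  database and externally screened nonbinders, neither reproducible
  here. Users who need a calibrated 500 nM scale should reduce ω or
  recalibrate Max/Min for their data.
* **Nonbinder screening.** For the same reason, screening generated
  nonbinders with the model itself rejects nearly everything; the
  default is unscreened background sampling, with `screen` exposed as a
  function argument.
* **Indel windows** are an interpretation: mutant windows must overlap
  inserted residues or the deletion junction, and no wild-type
  comparison is made because no positionally corresponding wild-type
  peptide exists; the wild-type filter applies to substitutions only.
* **Consensus across predictors.** The ≥2-predictors-plus-median rule is
  implemented over user-supplied IC50 columns (`consensus_ic50()`);
  external predictors are never wrapped or called.
* Two-field allele resolution only; HLA class II is out of scope.

## A small worked run

```{r example}
set.seed(7)
prof <- make_motif_profile(9, anchors = c(2, 9), dominance = 0.7)
binders <- sample_binders(prof, 120)
lib <- pssm_library(list(build_pssm(binders, allele = "A*0201")))
predict_binding(sample_binders(prof, 3), "A*0201", lib)[
  , c("peptide", "binding_score", "ic50_nM", "class")]
```
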