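---
title: "Semantic depth of narrative speech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic depth of narrative speech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdepth)
```

This vignette is the package's own account of its science: the Semantic
Depth Index and its conventions, the feature-profile definitions, the
statistical kernel, the synthetic-cohort model, and the design choices made
where the design was genuinely open.

## The Semantic Depth Index

A hypernym taxonomy is a directed acyclic graph over synsets — sets of
synonymous lemmas — whose edges encode the "is-a-kind-of" relation, from
hyponym (specific) to hypernym (general). Synsets without a hypernym are
roots; every word class (noun, verb, adjective, adverb) has its own
root(s). For a produced word, the SDI is the number of nodes separating its
synset from the root of its word class, **excluding the root**, i.e. the
number of is-a edges on the hypernym path. On the canonical noun hierarchy
rooted at "entity" this puts "thing" at 1, "animal" at 3 and "cat" at 10;
on the verb side, roots are per-tree, so "close" can score 1 in its own
tree while "come out" scores 3 in another. This edge-count convention is
the only one consistent with all of those anchor values simultaneously;
counting nodes inclusively of the root would shift every value by one and
break the "thing = 1" anchor.

Three further conventions close the gaps a bare definition leaves open:

* **Multiple hypernym paths.** In a DAG a synset may reach a root along
  several paths; `synset_depth()` takes the minimum edge count. This is
  deterministic and reads "separation" as shortest separation. Sensitivity
  to the choice is available at the word level via the `max_depth` policy.
* **Polysemy.** A lemma may name several synsets. The default policy is
  `first_sense` — the synset of sense rank 1, which in WordNet-style
  databases is the most frequent sense and is reproducible without context.
  `min_depth`, `max_depth` and `mean_depth` are exposed for sensitivity
  analyses; `mean_depth` may be fractional. For monosemous lemmas all four
  agree (a property the tests enforce).
* **Missing words.** A lemma absent from the taxonomy yields
  `found = FALSE` — never an error, never an imputed depth. Missingness is
  surfaced by `coverage_report()` and by the `sdi_coverage` column of every
  feature profile. Adjective and adverb hypernymy is typically absent from
  WordNet-format resources; such words are scored only if the taxonomy file
  supplies is-a links for them, and otherwise excluded from mean SDI and
  counted in coverage.

Sense rank is file order: S-record order in the edge-list dialect, index
order in the WordNet-database adapter. The canonical writer sorts synsets
by id, so round-tripping a non-canonical file can renumber senses of
polysemous lemmas; canonical files round-trip bit-exactly.

## Feature profiles

The per-speaker profile follows a types-versus-tokens reading that makes
the reported quantities mutually consistent: noun/verb/adjective counts are
**distinct-lemma (type) counts**, open- and closed-class counts are **token
counts**, and the two are linked by the mean number of occurrences,

> mean_occurrences = open-class tokens / open-class types,

an identity that holds exactly per speaker (and only approximately for
group means of ratios, which is why the tests assert it per speaker).
Adverbs count toward open-class tokens and types but have no dedicated type
counter. Fillers and false starts arrive annotated and are excluded from
all lexical counts; phonemic/semantic paraphasias are token tags; anomic
pauses and conduites d'approche are utterance-level events; well-formed
sentences are counted from a per-utterance flag. All annotation is input,
not inference: the package deliberately performs no POS tagging or error
detection, which keeps it language-agnostic and testable.

Mean SDI is type-weighted by default — each distinct word counts once,
matching a database organised by word with an occurrence count — with
token weighting available (`sdi_weighting = "token"`). Mean lexical
frequency (per-million counts from a user-supplied lexicon) is likewise
averaged over types, skipping absent words rather than imputing zero.
Whether the original feature tables were type- or token-weighted is not
stated anywhere authoritative; exposing both is the honest option.

## Statistical kernel

Group comparisons use the Mann-Whitney U test. U is computed from midranks,
so `u1 + u2 = n1 * n2` holds with ties; the reported statistic is
`min(u1, u2)`, the convention of the common statistical packages, with both
values returned. The two-sided p-value is the tail mass of the exact null
distribution of U whenever the pooled sample is tie-free and
`n1 + n2 <= 25` (small clinical groups land here), and a tie- and
continuity-corrected normal approximation otherwise; the method used is
always labelled in the result. Correlations are Pearson's r with the t
transform on n − 2 degrees of freedom. Multiplicity is handled by
Benjamini-Hochberg adjustment with two pre-registered families mirroring
the analysis structure: the 28 semantic-network correlations (14 regions x
2 hemispheres), and — per clinical group — the 68 Desikan parcels of the
thickness contrast. Significance is declared at adjusted p < 0.05,
two-sided.

Two entries of the conceptual ROI list have no single Desikan label and are
mapped once, visibly (`semantic_network_rois()$listed_as`): the anterior
temporal lobe to `temporalpole`, and the inferior frontal gyrus to
`parsopercularis`, its opercular subdivision — the IFG part that showed
group-level atrophy in both clinical variants, and the least arbitrary
single-label choice.

## The synthetic cohort

Clinical speech corpora rarely travel, so the generator produces complete
synthetic inputs with the statistical structure the analysis assumes. Its
defaults are the study conditions of the motivating clinical design and are
not tuning knobs:

* **Cohort**: 6 svPPA-like and 16 lvPPA-like speakers plus 30 controls;
  controls contribute thickness only (they undergo no speech assessment).
* **Taxonomy**: a complete binary noun tree of depth 8 (511 synsets) plus a
  verb tree of depth 5 — deep enough for mean depths near 4 and cheap
  enough to regenerate thousands of times in tests.
* **Lexical choice**: open-class lemmas are sampled with probability
  proportional to `exp(theta * depth)`. This one-parameter family is the
  minimal model of the "generic terms" phenomenon: more negative theta
  shifts mass toward shallow words. Group defaults `theta_sv = -1.07`,
  `theta_lv = -0.815` were fixed once, by matching the expected
  type-weighted mean SDI to the reported group means (about 3.99 and 4.42)
  at the reported open-token scales (about 286 and 162); per-speaker
  heterogeneity `theta_i ~ N(theta_g, 0.10)` brings the between-speaker SD
  of mean SDI to the reported 0.32-0.37 range.
* **Counts**: open/closed token totals are negative binomial at the
  reported group means (size 12 reproduces the reported SDs); paraphasias,
  anomic pauses and conduites d'approche are independent Poisson at the
  reported group means (no within-speaker correlation is modelled);
  sentence well-formedness is Bernoulli per utterance.
* **Thickness**: per-region baselines are the reported group means/SDs for
  all 68 parcels (`inst/extdata/cohort-thickness-params.tsv`). With no
  planted association every value is an independent Gaussian draw from its
  group's baseline. With a planted association, the designated ROIs of
  clinical subjects are drawn as `pooled_baseline + beta * (mean_sdi -
  cohort mean) + noise` with `beta = r * sd_pool / sd_sdi` and noise SD
  `sd_pool * sqrt(1 - r^2)`, where `sd_pool` is the pooled clinical SD of
  the ROI: the ROI keeps its configured scale and the planted pooled
  correlation equals `r` exactly. The default plants r = 0.66 in the eight
  ROIs reported significant in the motivating analysis.
* **Determinism**: one master seed; each stage derives a fixed substream
  seed, so equal seeds give byte-identical files. Bit-exactness is
  guaranteed within this implementation (substream derivation is
  documented in `stage_seed()`), not across independent reimplementations.

What the generator does **not** emulate: real lexical semantics (lemmas are
synthetic strings), discourse structure, within-speaker correlation of
error types, non-Gaussian thickness distributions, scanner or segmentation
artefacts, and any covariate structure (age, education) — so passing tests
show that the pipeline recovers the structure it assumes, not that real
svPPA data satisfy those assumptions.

## Calibration experiments and problem sizes

The test suite runs the full pipeline at sizes chosen to balance
Monte-Carlo error against runtime, stated here as the package's own
choices: parameter recovery uses 500 replicates of a 21-subject clinical
cohort (6 + 15 — mirroring one logopenic patient without usable MRI in the
motivating design) and requires the mean estimated r at a planted ROI to
fall within ±0.05 of the planted 0.66; null calibration uses 200 thickness
replicates over a fixed cohort (under a zero slope, thickness is
independent of the profile draw) and requires the mean FDR-significant
fraction of the 28-ROI family to stay at or below 0.05; group-separation
power draws 200 cohorts of 6 svPPA-like subjects against 30 controls at the
reported left-entorhinal parameters (1.77 ± 0.27 vs 3.20 ± 0.42 mm) and
requires an FDR-adjusted hit in at least 95% of replicates. Statistical
kernel oracles (brute-force pair counting, full permutation enumeration,
the classical step-up rule) run on 500 random cases each.

## Numerical and degenerate-input choices

Midranks everywhere; exact Mann-Whitney only in tie-free samples (the exact
null assumes continuity). `mean_occurrences` and `mean_sdi` are `NA`, not
zero, for speakers without open-class types — downstream group tests drop
`NA`s explicitly. Thickness values outside (0, 6) mm trigger a QC warning
but are not altered. Cycle detection names one offending synset
deterministically (the lexicographically first survivor of the elimination
order). File writers emit fixed-format, LF-terminated UTF-8 bytes so that
determinism can be asserted at the byte level.

## Known limitations

The SDI inherits every bias of its taxonomy: depth is not comparable across
word classes or across taxonomy versions, and the per-word values of a
given text depend on the sense policy where lemmas are polysemous. The
planted-association generator plants a single common slope across both
clinical groups; it cannot express group-specific brain-behaviour
coupling. Correlations are unadjusted bivariate Pearson — no covariates,
no partial correlation, no voxel-wise analysis — matching the scope of the
motivating design.
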