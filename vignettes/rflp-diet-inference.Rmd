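---
title: "RFLP-based diet inference: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RFLP-based diet inference: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpdiet)
```

## The problem

Restriction fragment length polymorphism (RFLP) identifies taxa by the
fragment sizes produced when restriction enzymes cut an amplified barcode
region. It is crude next to sequencing, but in a *closed* setting — an
experimental enclosure holding at most eight candidate host plants of known
identity — it is cheap, fast, and sufficient: with up to three enzymes the
fragment-size combinations can be made unique to each community member.
This package implements that workflow computationally: virtual PCR and
digestion of reference ITS2 sequences, selection of a discriminating enzyme
panel, identification of single- and multi-species samples from observed
gel bands, and the summary statistics used to compare sample types (faeces
vs regurgitate), sexes, and species-level detection biases.

## The model, stage by stage

### Primer matching and amplicon extraction

Primer sites are located by exact-length, zero-mismatch scanning where a
primer base matches a template base when their IUPAC base sets intersect.
The model deliberately has **no mismatch tolerance**: no annealing
thermodynamics are modelled, and a conservative exact rule is testable
against a brute-force window oracle. The amplicon spans from the first base
of the forward primer match to the last base of the reverse primer's
annealing site — primers are incorporated into the product, so this is the
length a gel sees. Templates with zero or multiple candidate sites raise
errors rather than guessing ("ambiguous priming"). Amplicon lengths are
reported but *not* filtered to the nominal 400–600 bp product range: the
range is treated as a description of the assay, not a hard gate, since
nothing in the workflow depends on it.

### Virtual digestion

An enzyme is a recognition sequence plus a cut offset from the site's 5'
end (TaqI = T^CGA, offset 1; HaeIII = GG^CC, offset 2; MluCI = ^AATT,
offset 0; incubation temperatures are carried as metadata only). Cut
positions are `site + offset`; fragments are gaps between consecutive cuts
including both molecule ends, so fragment lengths always sum to the
amplicon length and fragment count = site count + 1. All three built-in
sites are palindromic, so single-strand scanning finds every cut. Two
boundary conventions worth stating:

* a cut falling exactly at position 0 or at the amplicon end would create a
  zero-length fragment; it is dropped with a message;
* digesting the reverse complement reproduces the fragment multiset exactly
  only for a central cutter (HaeIII). For off-centre cutters the
  single-strand cut coordinate shifts by the overhang (2 bases for TaqI, 4
  for MluCI). On a real gel the duplex fragments are identical; the
  discrepancy is bookkeeping, is bounded by the overhang, and is asserted
  at that bound in the tests.

Degenerate template bases (N, R, Y, ...) are retained verbatim, and a
recognition site is called wherever every site base is IUPAC-*compatible*
with the template. This mirrors the primer rule, but it means a run of Ns
would cut optimistically; each profile therefore carries a
`degenerate_sites` count per enzyme so uncertain cuts can be flagged or
excluded downstream. How the original assay handled degenerate Sanger
calls is not documented anywhere we could rely on; compatible-match is our
explicit choice, not a transcription.

### The gel model

All pattern comparison runs through a three-parameter gel model:

| parameter | default | meaning |
|-----------|---------|---------|
| `min_size`, `max_size` | 25, 766 bp | detection window of the sizing ladder |
| `rel_tol` | 0.05 | relative sizing tolerance |

Two bands comigrate when `|a − b| <= rel_tol * max(a, b)`. The assay's
source material never quantifies sizing error, so 5% — a conventional
accuracy figure for agarose sizing against a ladder — is the default and is
surfaced as a parameter everywhere, never hard-coded. Visible bands are
produced by window-filtering a fragment list and merging comigrating
fragments walked in descending size order; a fragment joins the current
band only if it comigrates with **every** member (complete linkage), which
is deterministic and cannot chain 100 with 120 through 110. A
single-linkage (`transitive = TRUE`) variant exists for sensitivity
analysis. A merged band's apparent size is the rounded mean of its members:
one band on a gel has one apparent size.

### Panel selection

Two species are distinguishable when, for at least one enzyme, their
visible band lists differ — different counts, or some positional pair
(after descending sort) failing to comigrate. `select_panel()` searches
enzyme subsets exhaustively, size 1 up to `max_enzymes = 3` (three
reactions is the practical per-sample budget), ordered by size then enzyme
name, returning the first fully discriminating subset; if none exists it
returns the subset maximising distinguishable pairs and lists the residual
pairs. The fixed ordering makes results reproducible; at ≤ 3 candidate
enzymes and ≤ 8 species exhaustive search is trivially affordable.

### Identification with mixtures

A sample may contain several hosts, so identification is subset
enumeration: for every community subset of size 1..`max_mixture` (default
4, the largest mixture the method is credited with resolving), the
*expected mixture pattern* is the union of member fragment lists passed
through the gel model. An observed pattern is explained exactly when, for
every enzyme present, greedy largest-first one-to-one matching pairs off
all observed and all expected bands within comigration tolerance.

Among exact explanations the **minimal cardinality** ones win — a
parsimony rule: a single species that explains all bands is preferred to a
pair that also would. One minimal explanation gives status `unique`;
several give `ambiguous`, flagged `requires_sequencing` (the practical
escalation for, e.g., congeners with near-identical ITS); none gives
`no_match`, with the best partial explanation reported (maximise explained
observed bands, then smaller subset, then fewer unmatched expected bands,
then lexicographic order). Bands flagged faint can be excluded via
`include_faint = FALSE`. Species absent from the community — contaminants,
self-introduced weeds — surface as `no_match` with unexplained bands; the
package never invents out-of-community taxa, though a caller can re-query
such samples against an extended database.

One tolerance subtlety: widening `rel_tol` never shrinks the set of exact
explanations *for fixed expected band lists* (greedy matching is monotone
in the tolerance). It can, however, change the expected lists themselves,
because merging is tolerance-dependent — two 102/107 fragments separate at
3% and merge at 8%. The monotonicity property is therefore stated, and
tested, in the fixed-pattern form.

## Statistics

* **Proportions** use exact integer counts with Wilson score 95% intervals
  — chosen over Wald because per-species counts sit near the
  minimum-sample filter where Wald misbehaves. Rounding (half away from
  zero) happens only at presentation.
* **Relative difference** between group probabilities is
  `100 (p_a − p_b) / p_b`, the "X% higher in relative terms" convention;
  the unrounded value is always returned alongside.
* **Paired agreement**: a faecal/regurgitate pair (same animal, same
  occasion, both with at least one identified host) matches exactly when
  the species sets are equal and at least partially when they intersect —
  so exact matches count among partial matches, which is what "at least
  partial" means and what makes the printed counts (56 exact ≤ 100
  partial) coherent.
* **Deviance from expected frequency**: one identification event per
  (sample, species); for each species with ≥ `min_samples` (default 5)
  events, deviance = faecal share of its events minus `expected_prop`. The
  expected frequency is a **supplied constant** (study-wide value 0.66),
  not derived internally: its event base (samples vs identifications) is
  ambiguous in the source material, and both are computable by the caller,
  so the package refuses to guess.
* **Chi-squared** is the classical Pearson statistic on margin-product
  expecteds, no continuity correction; **trait regression** is ordinary
  least squares of deviance on a numeric trait or two-level factor, with
  the slope t-test on n − 2 df. Both are cross-checked in the tests
  against independent implementations. The original study's mixed models
  (grasshopper and mesocosm random effects) are intentionally out of
  scope; this package reproduces the raw-proportion summaries and the
  relative-difference arithmetic on printed group means only.

## The synthetic world

`sim_config()` states the emulated experiment; the defaults *are* the
stated world, chosen once and not tuned:

* 39-species pool (19 native, 20 exotic), 20 communities of 8, replicated
  4×, 4 sampling occasions; one female and one male grasshopper per
  mesocosm each contribute one faecal and one regurgitate sample per
  occasion (4 × 20 × 4 × 2 × 2 = 1280 scheduled samples).
* Sequences: one random ancestral insert sized so amplicons fall in
  400–600 bp, each species derived by independent per-base substitution at
  10%, flanked by the real primer sites; one designated near-identical
  pair at 0.5% divergence emulates the congener pair RFLP cannot separate.
  Expected pairwise identity under this model is
  `(1 − d)² + d²/3 ≈ 0.813`, which the tests verify.
* Amplification success: Bernoulli per sample with the study's group
  means — faecal/female 0.773, regurgitate/female 0.630, faecal/male
  0.801, regurgitate/male 0.431.
* Diet sets: sizes drawn with weights 335:133:31:1 (the study's observed
  1/2/3/4-species sample counts), members uniform within the community.
  Faecal and regurgitate truths are drawn independently by default —
  consistent with the finding that the two sample types carry
  complementary information — with `shared_diet_prob` interpolating to
  fully shared. This weights-based draw is a modelling device for testing,
  not a claim about grasshopper behaviour.
* Observations: the true set's expected pattern perturbed by multiplicative
  Gaussian noise (sd 2%, a realistic sizing repeatability inside the 5%
  comigration tolerance) and window-filtered.
* `sla_bias` optionally reweights *faecal* diet draws towards
  low-specific-leaf-area species by `exp(−bias · z(SLA))`; the acceptance
  suite uses it to confirm the qualitative detection-bias structure: a
  negative slope of deviance on SLA.

What the generator does **not** emulate: PCR chimeras or partial
digestion, band intensities, grasshopper mortality and replacement (a
`thinning` option drops scheduled samples at random instead), plant
phenology, or any phylogenetic structure beyond independent substitution.
A green round-trip test therefore establishes internal consistency of the
pipeline under the stated noise model — not field performance.

## Numerical conventions

* Coordinates are 0-based half-open throughout; lengths in bases.
* Reported percentages are rounded half away from zero, at presentation
  only; all internal arithmetic keeps full precision.
* Band merging returns the half-up-rounded mean of merged fragments.
* `select_panel()` and `identify_sample()` break all ties by fixed
  lexicographic orderings, so equal inputs give identical outputs.
* Seeds: every generator is deterministic given `sim_config(seed = ...)`;
  sub-generators offset the seed by small constants so they are
  individually reproducible.

## Known limitations

* Exact-match priming will miss templates with real primer-site mutations;
  there is no mismatch budget.
* The subset-enumeration identification formalises what was a manual
  deconvolution in practice; with very noisy bands the greedy matcher can
  differ from a human reading a gel.
* Comigration is pairwise after sorting, not a global assignment; at ≤ 8
  species and ≤ a dozen bands this is adequate, and the exhaustive oracle
  tests bound its behaviour, but it is not a claim of optimality.
* Statistics assume one record per collected sample and species-set
  semantics (a species counts once per sample, however many bands support
  it).
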