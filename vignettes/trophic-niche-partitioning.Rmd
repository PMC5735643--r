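---
title: "Trophic niche partitioning from stomach-content surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic niche partitioning from stomach-content surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophon)
```

## The data model

`trophon` analyses paired tables from a nycthemeral gillnet survey of
sympatric fish populations. A *specimen* record carries taxon, sex, total
length (mm), total/gutted/stomach weight (g), capture date, the 3-h
net-check interval at which it was taken, and a visual stomach repletion
class (void; partly full, 25–75%; full, > 75%). A *stomach item* is one
(specimen, food category, volume) observation, with categories fixed to the
broad scheme fish / crustacean / microcrustacean / insect / plant / other.
Void stomachs carry no items by definition, and all readers enforce that
along with referential integrity and the weight inequalities.

Two conventions deserve explanation because the raw field protocol leaves
them open:

* **Interval semantics.** Nets are checked every three hours at 18:00,
  21:00, 24:00, 03:00, 06:00, 09:00, 12:00 and 15:00; a check label denotes
  the *end* of its window, so the 06:00 check (window 03:00–06:00) is
  nocturnal and the 18:00 check (15:00–18:00) closes the day at dusk. With
  the nocturnal period defined as 18:00–06:00 this yields 5 nocturnal and 3
  diurnal checks — the split every day/night test in the package uses.
  "24:00" is kept verbatim as a label rather than normalised to 00:00.
* **Seasons.** The flood (rainy) season is January–June and the dry season
  July–December, at month granularity; a supplied season column must agree
  with the one derived from the capture date.

## Diet composition

For a group (species × season, optionally × interval) with `N`
content-bearing stomachs — non-void stomachs with at least one item row —
the three standard indices are

$$FO_i = \frac{100\,n_i}{N}, \qquad
  VF_i = \frac{100 \sum \text{vol}_i}{\sum_j \sum \text{vol}_j}, \qquad
  IF_i = \frac{FO_i \, VF_i}{\sum_j FO_j \, VF_j},$$

where occurrence is counted once per stomach (duplicate item rows of a
category do not inflate `n_i`) and volumes are pooled across all stomachs
of the group before normalisation. The pooled-volume convention was chosen
over the per-stomach mean of percentages because it is the standard reading
of "relative volume" and because `IF_i`, the index the downstream analyses
rest on, is invariant to any common rescaling of volumes — the two
conventions give identical feeding-importance values. All computation is
done in full precision; the print methods round FO/VF to 3 decimals and
`IF_i` to 4, the customary reporting style.

## Niche breadth, overlap and classification

Utilization matrices (rows = species, columns = the six categories) default
to the volumetric measure, with frequency-of-occurrence and
feeding-importance available as sensitivity switches; volume is the
conventional basis for diet-overlap work and nothing in the indices depends
on the percent scaling. Levin's standardized breadth uses the *fixed*
category scheme for `n` (six states) rather than the count of nonzero
entries, keeping `Bi` comparable across groups; `n` is an explicit argument
for users who prefer otherwise. Band boundaries 0.4 and 0.6 are assigned to
"moderate" (closed middle interval), resolving the ambiguity between the
strict and inclusive notations in common use.

## The RA3 null model

To ask whether an observed mean pairwise Pianka overlap could arise by
chance, each species' utilization row is randomly permuted among the
resource states — zeros included, which is precisely what distinguishes RA3
from RA4 and what makes the algorithm *breadth-retaining*: the multiset of
utilization values is conserved, so Levin's `Bi` of every row is unchanged
in every iteration (a property the test suite checks directly). Each of the
5000 default iterations shuffles every row independently and recomputes the
mean pairwise overlap; with only two species this is the single pair's
overlap.

Both one-tailed Monte-Carlo probabilities are plain proportions of
iterations with ties counted in both tails, so
`p_obs_le_exp + p_obs_ge_exp >= 1` and either tail may legitimately be 0
when no simulated value reaches the observed one; no +1 continuity
correction is applied. A small `p(observed <= expected)` — simulated
overlaps rarely as low as the observed — is the competition-consistent
signal; a small `p(observed >= expected)` marks overlap higher than chance.
Floating-point ties are detected with a 1e-12 tolerance. A single seed set
at the start of the call drives one sequential RNG stream, so a seed +
matrix + iteration count triple reproduces results bit-identically.

One subtlety is worth recording for users designing power studies: with two
species over six categories the attainable null distribution is a finite
set of relative arrangements (720), and the tie-inclusive
`p(observed <= expected)` can only be small when the observed pairing sits
in the extreme lower tail of those arrangements *and* carries little tie
mass. Utilization rows with one dominant state and shared zeros reproduce
their own minimum under shuffling with probability ~0.2–0.4, so such data
can never reach p ≤ 0.05 here; graded utilization vectors with opposite
preference orders can (the observed pairing is then the
rearrangement-inequality minimum, p ≈ 1/720). The divergence-recovery tests
use the latter structure.

## Activity and seasonal statistics

Per-interval capture counts are tested for heterogeneity with a chi-square
goodness-of-fit against uniformity (df = 7). The day/night test compares
the nocturnal and diurnal capture counts with an **exposure-weighted**
expectation of 5/8 vs 3/8 by default, because the design samples the night
with five checks and the day with three — a 50/50 expectation would mistake
sampling effort for activity. Since survey reports do not always state
which expectation they used, `expectation = "equal"` reproduces the naive
test. The Yates continuity correction (subtract 0.5 from each |O − E|,
floored at zero) is offered for the two-class case only; it is implemented
directly because the base goodness-of-fit test does not expose it, and is
cross-checked against `chisq.test(correct = FALSE)` and a loop oracle in
the tests.

Seasonal variation in the occurrence of a food item uses the G-test
(log-likelihood ratio, `G = 2 Σ O ln(O/E)` with margin-based expectations)
on the per-item 2 × 2 (present/absent) × (flood/dry) table of
content-bearing stomachs; an optional Williams correction divides G by the
usual `q`. p-values come from the asymptotic chi-square distribution
throughout — the counts these tests see are large, and no exact tests are
attempted.

Size-structure comparisons follow the conventional battery: per-sample
Kolmogorov–Smirnov checks against a normal with the sample's own moments,
Bartlett's homoscedasticity test, then Student's equal-variance t-test.
Pre-check failures are *flagged, not blocking*, mirroring how such
batteries are reported; the returned `ks` entry summarises the worse of the
two samples, with per-sample results alongside.

## The synthetic survey generator

The generator emulates the statistical structure the analysis assumes: two
(or more) populations with Poisson abundances split evenly over the
simulated seasons, Bernoulli sex, positive truncated-normal lengths and
weights (resampling, not clipping; rounded to 1 mm and 0.01 g, the usual
instrument precisions), categorical repletion per season, capture intervals
multinomial over the eight checks with per-species activity weights, and
1 + Binomial(3, 0.3) items per non-void stomach — few distinguishable items,
as in carnivore stomachs. Item categories follow the season's diet vector;
item volumes are i.i.d. lognormal about a unit scale (σ = 0.4 by default),
so the pooled volumetric composition converges to the generating diet
vector as the sample grows — the property the parameter-recovery tests
verify (L1 error < 0.05 by ~2000 stomachs). Making volumes *proportional*
to the diet share instead would square the dominance structure
(VF → p²/Σp²) and break that recovery, which is why the noise is
category-independent.

`preset_paper_like()` fixes the study conditions used across the end-to-end
tests: abundances 341 vs 61, sex ratios 0.48 vs 0.64 female, fish-dominated
diets taken from normalised per-season volumetric columns (the rarer
species eating only fish in the dry season, so its dry-season `Bi` is
exactly 0; the commoner one gaining plant matter seasonally), uniform vs
nocturnal-bimodal activity, and high void-stomach rates. The
nocturnal-bimodal weight vector (0.15, 0.24, 0.12, 0.20, 0.14, 0.05, 0.05,
0.05) puts peaks at 21:00 and 03:00 — dusk and early morning — with 85% of
captures in the five nocturnal checks; at the preset's abundance of ~61 the
exposure-weighted day/night chi-square has noncentrality ≈ 13, so the test
is significant in well over 95% of replicates. What the generator does
*not* emulate: prey-size selectivity, length–weight allometry (lengths and
weights are drawn independently), date-level catch correlation, and
regurgitation in the net. Passing tests therefore demonstrate the
pipeline's correctness and statistical behaviour under the assumed
structure, not the field fidelity of any particular dataset.

## Numerical choices and degenerate inputs

* Pianka overlap is clamped to [0, 1] after evaluation to absorb
  floating-point spill at proportional rows.
* Zero utilization rows, empty groups, all-zero volumes, structural-zero
  G-test margins, zero-variance samples and Yates requests at k > 2 all
  raise immediate domain errors rather than returning NaN.
* Histogram classes are half-open `[lo, lo + w)` with the origin snapped to
  a multiple of the class width at or below the minimum, so counts always
  conserve the sample size.
* Simulation sizes in the test suite (5000 null iterations where a
  published default exists; 50 000 for the enumeration cross-check; 500
  replicates for p-value calibration; 100 generator replicates for power
  properties; 2000 multinomial draws for type-I calibration) were chosen as
  the smallest sizes at which the Monte-Carlo error bounds in the
  corresponding assertions are meaningful.

## Known limitations

Only Pianka's overlap is implemented (Czekanowski/Schoener and Morisita
variants are deliberate non-goals), only RA3 among the randomization
algorithms, and no circular statistics for the activity data — the binned
chi-square approach is what the survey design supports. The G-test input
for multi-category seasonal comparisons is exposed as a plain contingency
matrix; the package takes no position on which pooling of categories a
given report used. Null-model randomization is per utilization matrix;
whether seasons are randomized jointly or separately is the caller's choice
of which matrix to pass.
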