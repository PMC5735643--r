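# trophon

Trophic niche partitioning analysis for stomach-content surveys of
sympatric fish populations.

When two closely related carnivores — say, two piranha species sharing an
Amazonian reservoir — coexist on the same prey base, the classical questions
are: what does each species eat, how wide is each trophic niche, how much do
the niches overlap, and is the observed overlap distinguishable from what
chance alone would produce? `trophon` implements the full analysis chain
used to answer them from paired specimen and stomach-content tables, plus a
synthetic survey generator so every stage can be exercised and tested
without field data.

## The indices and models

For a group of specimens (one species in one season), with `N` the number of
content-bearing stomachs and `n_i` the number of them containing food
category `i`:

- **Frequency of occurrence** `FO_i = 100 n_i / N`.
- **Volumetric frequency** `VF_i`: category `i`'s share of the pooled food
  volume of the group, in percent.
- **Index of feeding importance**
  `IF_i = FO_i VF_i / Σ_j FO_j VF_j`, a proportion ranking each category's
  dietary importance (invariant to any common rescaling of the volumes).
- **Levin's standardized niche breadth** `Bi = (1/Σ_j p_j² − 1)/(n − 1)`
  over the utilization proportions `p_j` of `n` resource states: 0 when a
  single resource is used, 1 when use is uniform.
- **Pianka's niche overlap**
  `O_jk = Σ_i p_ij p_ik / √(Σ_i p_ij² Σ_i p_ik²)` between two species'
  utilization vectors, 0 (disjoint) to 1 (proportional identity). Both
  indices use the conventional bands low (< 0.4), moderate (0.4–0.6),
  high (> 0.6).
- **RA3 randomization null model**: each species' utilization values —
  zeros included — are reshuffled among resource states (conserving niche
  breadth), the mean pairwise overlap is recomputed over many iterations
  (default 5000), and both one-tailed Monte-Carlo probabilities
  `p(observed ≤ expected)` and `p(observed ≥ expected)` are reported with
  ties counted in both tails. Overlap significantly *lower* than chance is
  consistent with competition-driven niche divergence.
- **Activity statistics**: capture profiles over eight 3-h net checks
  (18:00 … 15:00, five of them nocturnal), chi-square tests among intervals
  and between night and day (exposure-weighted by the 5:3 check split, with
  optional Yates correction), sex-ratio chi-squares, G-tests for seasonal
  variation in diet occurrence, and Kolmogorov–Smirnov/Bartlett/Student-t
  size-structure comparisons.

## Worked example

```r
library(trophon)

sim  <- generate(preset_paper_like(seed = 4202))   # two-species survey
diet <- diet_by(sim$items, sim$specimens)          # FO / VF / IF per group

u  <- utilization_matrix(diet[diet$season == "flood", ])  # volume-based
ns <- niche_summary(u)
ns$breadth
#>       species         bi band
#> 1   S. gibbus 0.06046699  low
#> 2 S. rhombeus 0.07299794  low
ns$overlap
#>   species_a   species_b       ojk band
#> 1 S. gibbus S. rhombeus 0.9956016 high

null_overlap_test(u, n_iterations = 5000, seed = 4202)
#> Niche-overlap null model (RA3, 5000 randomizations, seed 4202)
#>   observed mean overlap : 0.9956
#>   simulated mean        : 0.2160
#>   simulated variance    : 0.117
#>   p (observed <= expected): 1.0000
#>   p (observed >= expected): 0.0354

ap <- activity_profile(sim$specimens, group_key("S. rhombeus"))
day_night_test(ap, yates = TRUE)
#> chisq_gof: statistic = 10.691, df = 1, p = 0.00108
#>   corrected (Yates/Williams): 9.697, p = 0.00185
#>   note: night vs day, exposure-weighted expectation
```

Both simulated species are fish-dominated, so each trophic niche is narrow
(`Bi` ≈ 0.06–0.07, "low") while the *pairwise* overlap is nearly complete
(`O_jk` ≈ 0.996, "high") — far above what the RA3 null produces
(simulated mean ≈ 0.216, `p(observed ≥ expected)` ≈ 0.035). The rarer
species' nocturnal-bimodal rhythm is picked up by the day/night test even
against the exposure-weighted expectation (5 of 8 checks fall at night).

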