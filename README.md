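# svchromatin

Structural variants (SVs) of different mechanistic origin — deletions
from non-allelic homologous recombination (NAHR), non-homologous end
joining (NHEJ), replication errors (NHrepl), retrotransposon insertions
and polymorphic ancestral copies, tandem duplications, VNTRs — are not
scattered uniformly across the genome. Their breakpoints track chromatin
organization: compartments, DNase accessibility, double-strand-break
(DSB) hotspots, replication timing, nucleosome positioning and 3D
contact structure. `svchromatin` is an R package, for genomicists
analyzing SV call sets alongside epigenomic annotations, that implements
the statistical machinery for these questions end to end:

- **Circular-permutation enrichment.** The genome is circularized with
  chromosomes laid end to end; each null replicate shifts the whole SV
  set by one shared uniform offset, preserving SV lengths and spacing.
  Per mechanism and annotation label,
  `Z = (obs − μ_bg) / σ_bg`
  with two-sided normal p-values and Bonferroni correction, for
  compartment/chromHMM segmentations and for SVs encompassing TAD
  boundaries or loop anchors; mechanisms cluster by Z-profile.
- **Simulated NAHR breakpoints.** 100-bp seeds searched for homologous
  partners (same orientation, alignment length > 50 bp, identity > 85%,
  separation 100 bp–1 Mb) with an internal k-mer seed-and-extend
  aligner; rejection sampling to the real NAHR length distribution;
  compartment-proportion matching by largest-remainder rounding.
- **Aggregation profiles.** Peak-fraction profiles in 100-bp bins over
  ±2.5 kb around breakpoints (10-bp bins around regulatory-site
  midpoints), signal profiles normalized so a flat track reads 1.0,
  element-boundary anchoring for length-conserved elements, mean
  replication time over ±500 bp, and KS-based mechanism clustering.
- **Hi-C breakpoint interaction.** Knight–Ruiz balancing, obs/exp
  transform, compartment- and distance-specific average normalization,
  and interaction comparison of the two end bins of each SV > 5 kb.
- **Regression and the meiotic fraction.** Per-bin OLS of NAHR
  breakpoint density on homology/DSB predictors with 3-SD discordant
  bins, and the closed-form estimator
  `x = (S_obs − b·f_s) / (f_m − b·f_s)`
  for the fraction of NAHR deletions of meiotic origin
  (`S_obs = 0.08`, `b = 0.04` at the breakpoint-centered aggregation
  coordinate; `f_m`, `f_s` are experimental capture fractions).
- **A synthetic world.** `generateWorld()` produces a multi-chromosome
  genome with labeled compartments, DNase/TFBS/DSB peak sets, Alu-like
  homologous repeat pairs, per-mechanism SV sets with planted biases
  (including a planted meiotic NAHR fraction), contact matrices with
  distance decay plus compartment/NAHR boosts, and signal tracks — all
  with a ground-truth record, so every statistic can be validated by
  parameter recovery.

See the methods vignette (`vignettes/svchromatin-methods.Rmd`) for the
models, conventions and design choices.

## Worked example

Plant a 3× A1-compartment bias in one SV class and recover it:

```r
library(svchromatin)

w <- generateWorld(worldConfig(nChrom = 2, chromLength = 3e6,
                               svCounts = c(TDUP = 300, NHEJ = 300),
                               svEnrichment = list(TDUP = c(A1 = 3)),
                               repeatPairCount = 0, withContacts = FALSE,
                               withTracks = FALSE, seed = 42))
res <- enrichmentZscores(w@svs, w@compartments, w@layout,
                         nPerm = 1000, seed = 7)
res[, c("mechanism", "label", "observed", "bg_mean", "z", "p_adj")]
#>    mechanism label observed bg_mean      z    p_adj
#> 1       NHEJ    A1    0.242   0.234  0.287 1.00e+00
#> ...
#> 6       TDUP    A1    0.442   0.233  5.011 5.40e-06
#> 8       TDUP    B1    0.138   0.200 -1.979 4.78e-01
```

The planted class (TDUP) shows 44% of breakpoints in A1 against a
23% circular-permutation background — Z = 5.0, Bonferroni-adjusted
p = 5×10⁻⁶ — while the unbiased class (NHEJ) stays within noise of its
background everywhere.

The meiotic-fraction estimator, evaluated over capture fractions
`f_m, f_s ∈ [0.5, 1]`:

```r
meioticFractionRange()[c("x_min", "x_max")]
#> $x_min
#> [1] 0.04166667
#> $x_max
#> [1] 0.125
```

i.e. under the mixture model only ~4–12% of NAHR deletions are of
meiotic origin, whatever the capture fractions in that range.

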