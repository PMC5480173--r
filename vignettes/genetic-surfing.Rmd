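---
title: "Detecting range expansion and genetic surfing: models, conventions, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting range expansion and genetic surfing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A species that colonized its present range by a chain of founder events
leaves a characteristic pattern in neutral markers: diversity decays with
distance from the origin, differentiation is stronger in the newly
occupied range, and some alleles that are rare near the origin ride the
expansion front to high frequency far from it — *genetic surfing*.
`volesurf` implements the statistics needed to read that pattern out of a
typical field design: diploid microsatellite genotypes from a few dozen
sampling sites grouped into regional clusters, plus an mtDNA
control-region alignment, as collected for steppe rodents such as Brandt's
vole.  This vignette records the models, the numerical conventions, the
simulator the package validates itself against, and the design choices
that were genuinely open.

```{r setup}
library(volesurf)
```

## Microsatellite statistics

**Heterozygosity.** `diversity_summary()` reports the plain
`He = 1 - sum(p^2)` alongside the unbiased `uHe = 2n/(2n-1) He`.  The
downstream surfing regressions use the plain form, matching the
GENALEX-style workflow such surveys usually follow.  Per-site means over
loci are unweighted; sample-size weighting is a defensible alternative,
but the unweighted mean is what the common toolchain reports, and the
choice is documented rather than hidden.

**Rarefied allelic richness.** Allele counts are not comparable across
unequal samples, so `allelic_richness()` standardizes to `g` gene copies
by hypergeometric rarefaction,
`Ar = sum_i (1 - choose(N - N_i, g)/choose(N, g))`.  The default
`g = 14` (seven diploids) accommodates the small end of realistic site
samples; `Ar` is left undefined — never extrapolated — where a site has
fewer than `g` copies.  "Minimum sample size 14" is interpreted in *gene
copies*, the unit gene-based rarefaction software counts in.

**F_ST.** `pairwise_fst()` implements the Weir–Cockerham (1984)
variance-component estimator: per locus and allele the among-population
(`a`), among-individual (`b`) and within-individual (`c`) components, with
`theta = sum(a) / sum(a+b+c)` over alleles and loci, two populations per
pair.  Negative estimates are retained; clamping would bias downstream
averages.  The test suite checks the implementation against a literal
nested-ANOVA mean-squares computation to 1e-12 on random tables — two
independent routes to the same moments estimator.

**AMOVA.** `amova()` partitions variance over cluster / site / individual
using the number-of-different-alleles distance between diploid multilocus
genotypes (the F_ST-like choice, and the common default for such tables;
a sum-of-squared-size-differences variant would weight large repeat jumps
and is out of scope).  Components use the standard unequal-sample-size
coefficients; p-values permute the unit the tested component varies over
(sites among clusters for Phi_CT, individuals among sites within clusters
for Phi_SC, individuals among all sites for Phi_ST).  Percentages can be
negative for single components — they still sum to 100.

**Hardy–Weinberg screening.** Rather than the score test of classic
software, `hwe_test()` permutes the observed gene copies into random
diploid pairings and compares heterozygote counts two-sidedly (+1
continuity on both numerator and denominator).  This is assumption-free
and exact in the limit of permutations; HWE here is a data-quality
diagnostic, not an inference target.  `hwe_table()` applies Bonferroni
across site-by-locus tests and skips cells with fewer than five
genotyped individuals.

## Sequence statistics

**Counting conventions.** Segregating sites `S` may include indel events
("including insertions and deletions" is how such surveys usually report
`S`): each maximal run of contiguous alignment columns containing a gap
counts as one event.  Everything metric — `pi`, mean pairwise differences
`k`, the mismatch distribution, and all neutrality tests — uses gap-free,
`N`-free columns only.  All statistics operate on (haplotype, count)
pairs and are exactly equal to their expanded per-individual versions;
the tests assert this identity.

**Neutrality tests.** Tajima's D uses the standard constants; Fu & Li's
D* and F* use the corrected outgroup-free variance constants in standard
use, with the singleton count `eta_s` defined in the folded sense (a site
where exactly one sampled individual carries the minority base).  Fu's Fs
computes `S' = P(K >= K_obs | theta = k)` under the Ewens sampling
distribution with unsigned Stirling numbers of the first kind evaluated
in log space — stable to the `n = 746`-scale samples these surveys reach.
Expansion produces strongly negative D and Fs.

**Mismatch and the sudden-expansion model.** The expected mismatch under
an instantaneous growth from mutation-scaled size `theta0` to `theta1` at
time `tau` (units of 1/(2u) generations) mixes the equilibrium geometric
at `theta1` with a Poisson(`tau`)-shifted geometric at `theta0`; the
implementation evaluates it in log space so `theta1 = 40`, `d = 400`
class tails do not overflow.  `fit_sudden_expansion()` minimizes the sum
of squared deviations by Nelder–Mead from a coarse multi-start grid
(`tau` in 0–50, `theta` in 0–100) because the SSD surface is multimodal
in `tau`.  P-values are parametric bootstrap: coalescent samples of the
same size under the *fitted* expansion, each refit (warm-started) before
its SSD enters the null distribution.

**Raggedness.** Software disagrees on boundary terms, so the convention
is fixed explicitly: `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over
difference classes, where `d` is the largest observed difference and
`x_{d+1} = 0` is the first empty class past it.  For the two-point
distribution (0.5, 0.5) this gives `r = 0.25`.

## The surfing inference

**Isolation by distance** regresses `theta/(1-theta)` on the log of
great-circle distance (haversine, Earth radius 6371.0088 km) over site
pairs; pairs with `theta >= 1` or zero distance are excluded with a
warning, negative `theta` is kept (the transform is monotone below 1).
A Mantel permutation test (via `vegan`) is available alongside the
parametric F-test for readers who distrust pair non-independence.

**Start and arrival sites.** For an ordered cluster route, the site of a
cluster with the lowest mean pairwise F_ST to a neighbouring cluster is
the candidate colonization start (read source-to-target) or arrival
point.  Significance is assessed by one-way ANOVA across source sites on
their F_ST vectors followed by all-pairs Tukey HSD at 0.05 — the standard
all-pairs follow-up, chosen because the field convention reports only
"significantly lowest".  The F_ST values entering the ANOVA are not
independent observations (they share sites); the p-values are therefore
heuristic ranking aids, a known approximation that the output flags
rather than hides.  A starting site is annotated with whether it also
carries its cluster's highest allelic richness; when it does not, the
designation is kept with a warning flag — the diversity criterion can
legitimately fail at a bridge cluster that is both a receiver and a
source.

**Cline regressions.** `diversity_cline()` regresses He and Ar on
`theta` to the focal site.  F_ST stands in for geographic distance
deliberately: within clusters IBD is typically absent, and F_ST better
reflects effective dispersal along the route.  The focal site is excluded
from its own regression by default — its `theta` to itself is 0 by
construction, not an observation; `exclude_focal = FALSE` restores it.
With `cluster = NULL` the regression spans every site in the matrix,
which is the form of the serial-founder prediction (diversity decays
along the whole transect) and the form the package's acceptance battery
tests; per-cluster regressions have only a handful of points and
correspondingly little power.  `allele_cline_scan()` does the same per
locus-allele with Pearson correlations, stars at 0.05/0.01 with no
multiple-testing correction (matching the reporting convention of the
surveys this mirrors) plus an honest Benjamini–Hochberg column.

**Rare-to-common scan.** "Rare" is a pooled source-cluster frequency
below 0.05 (the conventional rare-allele threshold).  "Common in the
derived range" has no printed convention, so the default is explicit and
configurable: maximum per-site derived frequency at least 0.25, or a
pooled derived frequency at least twice the rarity threshold; both
evidence columns are always reported so any other threshold can be
applied by the reader.

## The simulator and what passing tests mean

`simulate_expansion()` is a forward-time, individual-based
stepping-stone model: logistic growth to carrying capacity `K` within
demes, colonization of an empty neighbour by `F` founders (removed from
the frontier deme) once it passes `trigger * K`, symmetric
nearest-neighbour migration at rate `m`, stepwise microsatellite mutation
(±1 repeat, reflecting bounds), and a maternally inherited mtDNA sequence
carried through explicitly sexed individuals.

Defaults: 12 demes 100 km apart in three clusters of four, `K = 200`,
`F = 8`, `m = 0.01`, 12 loci at `mu = 5e-4`, 50 sampled per deme.  The
origin sits at the edge of the source cluster adjacent to the route — the
geometry in which a "starting site" in the survey sense exists.  Two
calibration decisions matter and were made once, against the field
picture the generator is meant to emulate:

- *Ancestral standing variation is modeled explicitly.*  A realistic
  survey shows He around 0.55–0.75 with 4–10 alleles per locus, far above
  the stepwise mutation–drift equilibrium for `theta = 4K mu = 0.4`
  (He about 0.26).  Demes therefore start from an ancestral pool (10
  alleles per locus, exponential-weighted frequencies) and mtDNA from a
  neutral coalescent sample at `theta = 2`, rather than from a
  monomorphic state that could never reach the target diversity on a
  colonization timescale.  The drift property the tests check instead is
  dynamic: under pure drift, pairwise F_ST tracks `1 - (1 - 1/2K)^t`.
- *mtDNA mutation supply is low.*  At `mu = 5e-6` per site per
  generation a 600-individual sample carries 10–34 haplotypes with a
  modal haplotype above 0.3 and Tajima's D reliably negative — the
  star-like structure with one or two dominant central haplotypes that
  real control-region surveys of expanding rodents show.  An order of
  magnitude higher and nearly every matriline mutates during the run,
  shattering the sample into ~100 near-private haplotypes.

The `paper_like` profile (23 demes, bent SE→NE→W route, `K = 500`,
`F = 40`, `m = 0.03`, site samples thinned to 15–60) reproduces the
survey scale: He 0.55–0.78 and pairwise F_ST mostly 0.03–0.11.  The
`surf_heavy` profile (`F = 4`, `m = 0.002`) maximizes surfing.

What the simulator does *not* emulate: genotyping error, null alleles
and allelic dropout; mutation-rate heterogeneity among loci or sites;
selection; two-dimensional landscapes and barriers (the route is a
possibly bent chain); overlapping generations and seasonal demography.
Passing the validation battery therefore shows the *inference machinery*
is sound under the idealized serial-founder model — it does not show that
any particular real dataset satisfies that model.

## Numerical choices and degenerate inputs

- Rarefaction uses `lchoose`, exact for `N - N_i < g` (the term is 0).
- `theta` with an all-monomorphic denominator returns 0 rather than NaN;
  monomorphic loci contribute nothing to either sum.
- Ties in the focal-site minimum (within 1e-12) are reported as ties,
  never silently broken.
- Zero-variance allele-frequency vectors are excluded from cline scans
  with an explicit reason, as are alleles observed in fewer than
  `min_sites` sites.
- `S = 0` makes every neutrality statistic undefined (flagged), not 0.
- The mismatch bootstrap and every permutation test take explicit seeds;
  the pipeline derives per-stage seeds from one master seed, and repeated
  runs are byte-identical (`write_surfing_report()` serializes
  deterministically).
- Single-sex founder groups (probability `2^{1-F}` per event) simply
  fail to grow until migration rescues them, as a real colonization
  attempt would; sampling then caps at deme size with a warning.

## Problem sizes

The bundled validation batteries use 20 replicates of the default
12-deme design (about a minute), 20 surf-heavy replicates, 100 random
tables for the estimator-vs-oracle identity, exhaustive rarefaction
enumeration up to 12 gene copies, and mismatch bootstraps of 60–200
replicates — sizes at which every stochastic acceptance band in the test
suite is stable across seeds while the whole suite stays comfortably
inside a coffee break.

## Known limitations

- The cross-cluster ANOVA treats pairwise F_ST values as exchangeable
  replicates; their correlation structure makes the Tukey significance
  flags conservative rankings, not calibrated tests.
- Fu's Fs at very large `n` with tiny `k` can hit `S'` numerically equal
  to 0 or 1; the result is flagged ±Inf rather than clipped.
- The GenePop reader accepts the common dialect (2- or 3-digit,
  POP-delimited, trailing-label site names) and deliberately rejects
  rather than repairs structural inconsistencies.
- Haplogroup membership is always an input; the package never infers
  clades (tree-based haplogroup calling is a different problem).
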