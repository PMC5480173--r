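# volesurf

Population-genetic analysis of range expansions and **genetic surfing** —
the stochastic rise of (possibly rare) alleles to high frequency on the
front of a spatial expansion, driven by serial founder effects rather than
selection.  The package was built around the kind of range-wide rodent
survey that combines diploid microsatellite genotypes from a few dozen
sampling sites with an mtDNA control-region alignment, and it bundles a
forward-time stepping-stone simulator so that every inference step can be
validated against known ground truth.

It is aimed at population geneticists and phylogeographers who want a
scripted, reproducible version of a workflow usually spread across
GENALEX, Arlequin, DnaSP, HP-Rare and SPSS.

## What it computes

**Classical summaries (microsatellites).**  Per site and locus: allele
counts N_a, allele frequencies, observed and expected heterozygosity
(H_o, H_e = 1 − Σp², and the unbiased 2n/(2n−1) variant), private and
rare (< 0.05) alleles, and allelic richness A_r standardized by
hypergeometric rarefaction to g gene copies (default g = 14):

    A_r = Σ_i [ 1 − C(N − N_i, g) / C(N, g) ]

Pairwise F_ST is the Weir–Cockerham (1984) variance-component estimator θ,
summed over alleles and loci; Nei's D_a feeds a neighbor-joining tree;
hierarchical AMOVA (cluster / site / individual, number-of-different-
alleles distance) with permutation tests; Monte-Carlo exact
Hardy–Weinberg screening with Bonferroni correction.

**Sequence statistics (mtDNA).**  Haplotype diversity
Hd = n/(n−1)(1 − Σp²), nucleotide diversity π, segregating sites with a
contiguous gap counted as one indel event, Tajima's D, Fu & Li's D* and
F*, Fu's Fs (Ewens distribution via log-space Stirling numbers), the
mismatch distribution, Harpending's raggedness r, and a least-squares fit
of the Rogers–Harpending sudden-expansion model F_i(τ, θ0, θ1) with
parametric-bootstrap p-values for SSD and r.

**Surfing inference.**  Isolation by distance as the regression of
θ/(1−θ) on ln(great-circle km); start/arrival-site identification: for an
ordered cluster route (e.g. SE → NE → W), the site of a cluster with the
lowest mean pairwise F_ST to the neighbouring cluster (one-way ANOVA +
Tukey HSD on the per-site F_ST vectors) is the putative colonization
start or arrival point; regressions of H_e, A_r and individual allele
frequencies on F_ST to those focal sites; and a rare-to-common scan
listing alleles rare (< 0.05) in the source cluster but common
(per-site frequency ≥ 0.25) in the derived one — the surfing signature.

**Simulator.**  Forward-time, individual-based: a 1-D (optionally bent)
chain of demes, diploid Wright–Fisher reproduction with logistic
regulation to K, colonization of empty neighbours by F founders once a
frontier deme passes a trigger size, nearest-neighbour migration,
stepwise-mutating microsatellites, and a maternally inherited 734-bp
mtDNA locus seeded with coalescent standing variation.  Ground truth
(origin, colonization times, surfed alleles) is returned alongside the
GenePop/FASTA/TSV outputs.

## Worked example

```r
library(volesurf)

cfg <- sim_config(seed = 7)          # 12 demes, 3 clusters, origin D04
sim <- simulate_expansion(cfg)
div <- diversity_summary(sim$gt, sim$meta, g = 14)
fst <- pairwise_fst(sim$gt)

head(div$per_site[, c("site", "Na", "He", "Ar")], 6)
#>   site       Na        He       Ar
#> 1  D01 4.083333 0.4521333 2.905887
#> 2  D02 4.916667 0.5530667 3.402970
#> 3  D03 5.083333 0.6200333 3.724083
#> 4  D04 5.583333 0.6327667 3.547034
#> 5  D05 5.000000 0.6052167 3.465821
#> 6  D06 5.333333 0.5574667 3.504440
```

Heterozygosity and allelic richness peak at the origin deme D04 and decay
along the expansion route — the serial founder-effect gradient.  The
focal-site criterion recovers the origin from the genotypes alone:

```r
cross_cluster_mean_fst(fst, sim$meta, "SE", "NE")$focal
#> [1] "D04"
```

The numbered scripts under `analysis/` run the same workflow at survey
scale (23 sites, bent SE → NE → W route) and write CSV tables and a JSON
report under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_genetic_diversity.R
Rscript analysis/03_dloop_expansion.R
Rscript analysis/04_surfing.R
```

## Layout

- `R/` — the implementation; `tests/testthat/` — unit, property and
  acceptance tests (oracles live in `tests/testthat/helper-oracles.R`)
- `analysis/` — numbered narrative drivers over the package functions
- `vignettes/genetic-surfing.Rmd` — models, conventions, calibration and
  limitations
- `inst/extdata/deposited/` — where the deposited study data goes if you
  fetch it (not redistributed)
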