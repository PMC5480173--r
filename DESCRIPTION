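Package: volesurf
Title: Range-Expansion and Genetic-Surfing Analysis for Microsatellite and
    mtDNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis of range expansions and genetic
    surfing in spatially structured samples, built around diploid
    microsatellite genotypes (GenePop format) and aligned mtDNA control-region
    sequences.  Implements classical summary statistics (allele counts,
    observed and expected heterozygosity, rarefied allelic richness, private
    and rare alleles), Weir-Cockerham pairwise F_ST, Nei's D_a distance and
    neighbor-joining trees, hierarchical AMOVA with permutation tests,
    sequence diversity and neutrality statistics (Tajima's D, Fu and Li's D*
    and F*, Fu's Fs), mismatch distributions with the Rogers-Harpending
    sudden-expansion model, isolation-by-distance regression, and an
    F_ST-based inference of colonization start and arrival sites with
    diversity and allele-frequency cline regressions and a rare-to-common
    allele scan.  A forward-time stepping-stone simulator with serial founder
    events provides ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
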