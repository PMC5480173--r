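#!/usr/bin/env Rscript
# Step 1: generate the simulated range-expansion surveys that the rest of
# the analysis runs on.  Three designs: the paper-scale survey (23 sites in
# three clusters on a bent SE -> NE -> W route), the default 12-deme
# transect, and a surf-heavy variant (small founder groups, weak
# migration).  All outputs are plain text under results/data/.

suppressMessages(library(volesurf))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("== simulating the paper-scale survey (23 sites, 3 clusters) ==\n")
paths <- make_fixture("paper_like", file.path(out, "survey"))
gt <- read_genepop(paths["genotypes"])
meta <- read_site_metadata(paths["meta"])
truth <- jsonlite::fromJSON(paths["truth"])
cat("  ", length(gt$individuals), "individuals,", length(gt$loci),
    "loci,", length(site_ids(gt)), "sites\n")
cat("   origin deme:", truth$origin, "| colonization spanned",
    max(unlist(truth$colonized_gen)), "generations\n")
cat("   surfed alleles in the full populations:",
    nrow(as.data.frame(truth$surfed_alleles)), "\n")

cat("== simulating the surf-heavy variant ==\n")
paths2 <- make_fixture("surf_heavy", file.path(out, "surf_heavy"))
truth2 <- jsonlite::fromJSON(paths2["truth"])
cat("   surfed alleles:", nrow(as.data.frame(truth2$surfed_alleles)), "\n")

cat("== simulating the tiny check fixture ==\n")
make_fixture("tiny", file.path(out, "tiny"))
cat("done; data under", out, "\n")
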