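#' Named simulation presets
#'
#' Three reproducible study designs for [simulate_expansion()]:
#' `tiny` (4 demes, a few individuals; completes in seconds, for quick
#' checks), `paper_like` (23 demes in three clusters, SE -> NE -> W with a
#' bent route, 12 loci, site samples of 15-60 diploids, matching the scale
#' of a range-wide microsatellite survey), and `surf_heavy` (small founder
#' groups and weak migration, maximizing allele surfing).  Each profile
#' embeds a fixed seed, so a profile always regenerates the same dataset;
#' pass `seed` to override it.
#'
#' @param profile one of `"tiny"`, `"paper_like"`, `"surf_heavy"`.
#' @param seed optional seed overriding the profile's embedded one.
#' @return a [sim_config()].
#' @export
fixture_config <- function(profile = c("tiny", "paper_like", "surf_heavy"),
                           seed = NULL) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = sim_config(n_demes = 4, origin = 2, K = 30, founder_size = 4,
                      n_loci = 3, n_founder_alleles = 4, mt_len = 120,
                      theta_mt = 1.5, burn_in = 20, settle_gens = 5,
                      sample_n = 8, cluster_sizes = c(2, 2),
                      cluster_labels = c("A", "B"), seed = 424242L),
    paper_like = sim_config(n_demes = 23, origin = 8, K = 500,
                            founder_size = 40, m = 0.03,
                            cluster_sizes = c(8, 7, 8),
                            cluster_labels = c("SE", "NE", "W"),
                            bend_at = 15, sample_n = 60, seed = 171717L),
    surf_heavy = sim_config(founder_size = 4, m = 0.002, seed = 272727L))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Write a simulated fixture to disk
#'
#' Runs the chosen profile and writes the four artefacts of a field study:
#' GenePop genotypes, FASTA mtDNA alignment with a haplotype count TSV,
#' site metadata TSV, and the simulator ground truth as JSON.
#'
#' @param profile passed to [fixture_config()].
#' @param dir output directory (created if needed).
#' @param seed optional seed override.
#' @return named character vector of the paths written, invisibly.
#' @export
make_fixture <- function(profile = c("tiny", "paper_like", "surf_heavy"),
                         dir, seed = NULL) {
  cfg <- fixture_config(profile, seed)
  profile <- match.arg(profile)
  sim <- simulate_expansion(cfg)
  if (profile == "paper_like") {
    # emulate uneven field trapping success: site samples of 15-60
    sim <- thin_samples(sim, min_n = 15, max_n = 60, seed = cfg$seed + 1L)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.gen"),
             fasta = file.path(dir, "dloop.fasta"),
             hap_counts = file.path(dir, "hap_counts.tsv"),
             meta = file.path(dir, "sites.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genepop(sim$gt, paths["genotypes"],
                title = paste("volesurf fixture:", profile))
  write_fasta_alignment(sim$hd, paths["fasta"], paths["hap_counts"])
  utils::write.table(as.data.frame(sim$meta), paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$surfed_alleles <- as.data.frame(truth$surfed_alleles)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              na = "null"), paths["truth"])
  invisible(paths)
}

# subsample each site to a seeded draw from [min_n, max_n] individuals
thin_samples <- function(sim, min_n, max_n, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- character(0)
  for (s in site_ids(sim$gt)) {
    ids <- sim$gt$individuals[sim$gt$site == s]
    ns <- min(length(ids), sample(seq(min_n, max_n), 1L))
    keep_s <- sample(ids, ns)
    keep <- c(keep, sort(keep_s))
  }
  gt <- subset_genotypes(sim$gt, individuals = keep)
  # haplotype counts must track the genotype subsample 1:1 is not possible
  # (haplotype assignment of unsampled individuals is unknown to the data
  # model), so per-site counts are rescaled proportionally instead
  counts <- sim$hd$counts
  for (s in colnames(counts)) {
    n_new <- sum(gt$site == s)
    col <- counts[, s]
    tot <- sum(col)
    if (tot == 0 || n_new >= tot) next
    scaled <- floor(col * n_new / tot)
    short <- n_new - sum(scaled)
    if (short > 0) {
      frac <- col * n_new / tot - scaled
      add <- order(frac, decreasing = TRUE)[seq_len(short)]
      scaled[add] <- scaled[add] + 1L
    }
    counts[, s] <- scaled
  }
  keep_h <- rowSums(counts) > 0
  hd <- haplotype_data(sim$hd$seqs[keep_h, , drop = FALSE],
                       counts[keep_h, , drop = FALSE])
  meta <- sim$meta
  meta$n_sampled <- as.integer(table(gt$site)[meta$site])
  list(gt = gt, hd = hd, meta = meta, truth = sim$truth)
}
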