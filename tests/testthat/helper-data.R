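# small in-code fixtures and a lazily computed, cached batch of default
# simulator replicates shared by the simulator property tests and the
# acceptance tests (the batch is the expensive part of the suite)

toy_gt <- function() {
  # 2 sites x 2 loci x 2 diploids each
  genotype_table(
    individuals = c("A_1", "A_2", "B_1", "B_2"),
    loci = c("L1", "L2"),
    a1 = rbind(c(150L, 200L), c(150L, 202L), c(152L, 200L), c(150L, 204L)),
    a2 = rbind(c(150L, 202L), c(152L, 202L), c(152L, 204L), c(154L, 202L)),
    site = c("A", "A", "B", "B"))
}

toy_meta <- function() {
  site_meta(data.frame(site = c("A", "B", "C"),
                       lat = c(44, 45, 46), lon = c(104, 106, 109),
                       cluster = c("SE", "SE", "NE")))
}

# random genotype table: npop sites x nloci loci x n diploids per site
random_gt <- function(npop = 2, nloci = 2, n = 4, nalleles = 3, seed = 1) {
  set.seed(seed)
  N <- npop * n
  a1 <- matrix(sample.int(nalleles, N * nloci, TRUE) + 100L, N, nloci)
  a2 <- matrix(sample.int(nalleles, N * nloci, TRUE) + 100L, N, nloci)
  genotype_table(paste0("i", seq_len(N)), paste0("L", seq_len(nloci)),
                 a1, a2, rep(paste0("p", seq_len(npop)), each = n))
}

# haplotype data from explicit sequences and counts
make_hd <- function(seqs, counts, sites = NULL, hap_group = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("H", seq_along(seqs))
  cm <- if (is.matrix(counts)) counts else {
    m <- cbind(all = as.integer(counts)); rownames(m) <- names(seqs); m
  }
  haplotype_data(seqs, cm, hap_group)
}

# cached batch of default-configuration expansion replicates with the
# derived statistics the property and acceptance tests share
.sim_cache <- new.env(parent = emptyenv())
default_sim_batch <- function(n_reps = 20, base_seed = 1000L) {
  key <- paste0("batch_", n_reps, "_", base_seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  out <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_expansion(sim_config(seed = base_seed + r))
    div <- diversity_summary(sim$gt, sim$meta)
    fst <- pairwise_fst(sim$gt)
    list(sim = sim, div = div, fst = fst)
  })
  .sim_cache[[key]] <- out
  out
}

surf_heavy_batch <- function(n_reps = 20, base_seed = 2000L) {
  key <- paste0("surf_", n_reps, "_", base_seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- fixture_config("surf_heavy", seed = base_seed + r)
    sim <- simulate_expansion(cfg)
    freqs <- allele_frequencies(sim$gt)
    list(sim = sim, freqs = freqs)
  })
  .sim_cache[[key]] <- out
  out
}
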