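#' Configuration for the forward-time range-expansion simulator
#'
#' Builds and validates the parameter list for [simulate_expansion()].  The
#' defaults describe a one-dimensional stepping-stone expansion with serial
#' founder events: 12 demes 100 km apart in three contiguous clusters of
#' four (labels SE, NE, W), the origin at the SE deme adjacent to the SE-NE
#' boundary (colonization therefore proceeds both outward along the route
#' and backward into the rest of the source cluster, as in a species
#' spreading from the edge of its ancestral area), carrying capacity 200
#' diploids per deme, logistic growth, founder groups of 8, nearest-
#' neighbour migration at 0.01 per generation, 12 microsatellite loci under
#' stepwise mutation, and a maternally inherited 734-bp mtDNA locus whose
#' ancestral standing variation is drawn from a neutral coalescent.
#'
#' @param n_demes number of demes on the line.
#' @param origin index of the origin deme.
#' @param spacing_km distance between neighbouring demes (km).
#' @param K carrying capacity (diploids per deme).
#' @param growth_rate logistic growth rate per generation.
#' @param founder_size F, diploids seeding a new deme.
#' @param trigger fraction of K a frontier deme must reach before it sends
#'   founders.
#' @param m per-generation migration rate between occupied neighbours.
#' @param n_loci number of microsatellite loci.
#' @param mu_ms stepwise mutation rate per locus per generation.
#' @param allele_range reflecting bounds for repeat counts.
#' @param n_founder_alleles ancestral alleles per locus.
#' @param mt_len mtDNA sequence length (bp).
#' @param mu_mt mtDNA mutation rate per site per generation.
#' @param theta_mt mutation-scaled size of the ancestral coalescent that
#'   seeds mtDNA standing variation.
#' @param burn_in generations at the origin before colonization starts.
#' @param settle_gens extra generations after the last deme is colonized.
#' @param max_gens hard cap on total generations.
#' @param sample_n individuals sampled per deme at the end.
#' @param cluster_sizes contiguous cluster sizes summing to `n_demes`.
#' @param cluster_labels one label per cluster.
#' @param bend_at optional deme index at which the route turns 90 degrees
#'   (coordinates only), `NA` for a straight line.
#' @param seed mandatory integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 12, origin = 4, spacing_km = 100,
                       K = 200, growth_rate = 0.5, founder_size = 8,
                       trigger = 0.8, m = 0.01,
                       n_loci = 12, mu_ms = 5e-4, allele_range = c(5, 60),
                       n_founder_alleles = 10,
                       mt_len = 734, mu_mt = 5e-6, theta_mt = 2,
                       burn_in = 100, settle_gens = 20, max_gens = 2000,
                       sample_n = 50,
                       cluster_sizes = c(4, 4, 4),
                       cluster_labels = c("SE", "NE", "W"),
                       bend_at = NA, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(origin >= 1, origin <= n_demes,
            founder_size <= K, m >= 0, m <= 1, mu_ms >= 0, mu_ms <= 1,
            mu_mt >= 0, mu_mt <= 1, trigger > 0, trigger <= 1,
            sum(cluster_sizes) == n_demes,
            length(cluster_labels) == length(cluster_sizes))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a stepping-stone range expansion with serial founder events
#'
#' Forward-time individual-based simulation.  Discrete generations; within
#' each occupied deme diploid Wright-Fisher reproduction with logistic
#' regulation toward `K`; once a frontier deme exceeds `trigger * K`, an
#' empty neighbour is colonized by `founder_size` individuals drawn (and
#' removed) from it; occupied neighbours exchange migrants at rate `m`.
#' Microsatellites mutate stepwise (+/- 1 repeat, reflecting at
#' `allele_range`); every individual carries one maternally inherited mtDNA
#' sequence mutating at `mu_mt` per site.  After `settle_gens` generations
#' beyond full colonization, `sample_n` individuals per deme are sampled
#' without replacement.
#'
#' @param cfg a [sim_config()].
#' @return list with `gt` ([genotype_table()]), `hd` ([haplotype_data()]),
#'   `meta` ([site_meta()]) and `truth` (origin site, per-deme colonization
#'   generation, surfed-allele table, config echo).
#' @export
simulate_expansion <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  nd <- cfg$n_demes; L <- cfg$n_loci
  site_names <- sprintf("D%02d", seq_len(nd))
  cluster_of <- rep(cfg$cluster_labels, cfg$cluster_sizes)

  # ancestral microsatellite pool: n_founder_alleles per locus, broken-stick
  # frequencies
  pool <- lapply(seq_len(L), function(l) {
    lo <- cfg$allele_range[1]; hi <- cfg$allele_range[2]
    mid <- (lo + hi) %/% 2
    ks <- cfg$n_founder_alleles
    alleles <- seq(mid - ks + 1, mid + ks - 1, by = 2)[seq_len(ks)]
    w <- stats::rexp(ks)
    list(alleles = as.integer(alleles), p = w / sum(w))
  })

  # mtDNA registry: root sequence + (parent, site, base) mutation records
  reg <- new.env(parent = emptyenv())
  reg$root <- sample(c("A", "C", "G", "T"), cfg$mt_len, replace = TRUE)
  reg$parent <- integer(0); reg$site <- integer(0); reg$base <- character(0)
  new_hap <- function(parent) {
    s <- sample.int(cfg$mt_len, 1L)
    cur <- hap_base_at(reg, parent, s)
    reg$parent <- c(reg$parent, parent)
    reg$site <- c(reg$site, s)
    reg$base <- c(reg$base, sample(setdiff(c("A", "C", "G", "T"), cur), 1L))
    length(reg$parent)
  }

  # ancestral mtDNA variation: coalescent sample of K haplotype indices
  init_mt <- sim_init_mt(cfg$K, cfg$theta_mt, reg)

  demes <- vector("list", nd)
  colonized_gen <- rep(NA_integer_, nd)
  new_deme <- function(g, mt, sex) list(g = g, mt = mt, sex = sex)
  g0 <- matrix(0L, cfg$K, 2L * L)
  for (l in seq_len(L)) {
    g0[, 2 * l - 1] <- sample(pool[[l]]$alleles, cfg$K, TRUE, pool[[l]]$p)
    g0[, 2 * l] <- sample(pool[[l]]$alleles, cfg$K, TRUE, pool[[l]]$p)
  }
  demes[[cfg$origin]] <- new_deme(g0, init_mt,
                                  stats::rbinom(cfg$K, 1L, 0.5))
  colonized_gen[cfg$origin] <- 0L

  reproduce <- function(d) {
    N <- nrow(d$g)
    females <- which(d$sex == 0L); males <- which(d$sex == 1L)
    if (!length(females) || !length(males)) return(d)   # single-sex: hold
    Nn <- max(2L, round(N + cfg$growth_rate * N * (1 - N / cfg$K)))
    mothers <- females[sample.int(length(females), Nn, TRUE)]
    fathers <- males[sample.int(length(males), Nn, TRUE)]
    g <- matrix(0L, Nn, 2L * L)
    for (l in seq_len(L)) {
      g[, 2 * l - 1] <- d$g[cbind(mothers, 2L * l - 1L +
                                    (stats::runif(Nn) < 0.5))]
      g[, 2 * l] <- d$g[cbind(fathers, 2L * l - 1L +
                                (stats::runif(Nn) < 0.5))]
    }
    nmut <- stats::rbinom(1L, Nn * 2L * L, cfg$mu_ms)
    if (nmut > 0L) {
      ri <- sample.int(Nn, nmut, TRUE)
      ci <- sample.int(2L * L, nmut, TRUE)
      step <- sample(c(-1L, 1L), nmut, TRUE)
      v <- g[cbind(ri, ci)] + step
      v[v < cfg$allele_range[1]] <- cfg$allele_range[1] + 1L
      v[v > cfg$allele_range[2]] <- cfg$allele_range[2] - 1L
      g[cbind(ri, ci)] <- v
    }
    mt <- d$mt[mothers]
    p_mt <- 1 - (1 - cfg$mu_mt)^cfg$mt_len
    hit <- which(stats::runif(Nn) < p_mt)
    for (i in hit) mt[i] <- new_hap(mt[i])
    new_deme(g, mt, stats::rbinom(Nn, 1L, 0.5))
  }

  take <- function(d, idx) new_deme(d$g[idx, , drop = FALSE], d$mt[idx],
                                    d$sex[idx])
  gen <- 0L; done_gen <- NA_integer_
  repeat {
    gen <- gen + 1L
    occ <- which(!vapply(demes, is.null, logical(1)))
    for (i in occ) demes[[i]] <- reproduce(demes[[i]])
    expanding <- gen > cfg$burn_in
    if (expanding) {
      for (i in occ) {
        if (nrow(demes[[i]]$g) < cfg$trigger * cfg$K) next
        for (nb in c(i - 1L, i + 1L)) {
          if (nb < 1L || nb > nd || !is.null(demes[[nb]])) next
          if (nrow(demes[[i]]$g) < cfg$founder_size + 2L) next
          idx <- sample.int(nrow(demes[[i]]$g), cfg$founder_size)
          demes[[nb]] <- take(demes[[i]], idx)
          demes[[i]] <- take(demes[[i]],
                             setdiff(seq_len(nrow(demes[[i]]$g)), idx))
          colonized_gen[nb] <- gen
        }
      }
      occ <- which(!vapply(demes, is.null, logical(1)))
      if (cfg$m > 0) for (i in occ[-length(occ)]) {
        j <- i + 1L
        if (is.null(demes[[i]]) || is.null(demes[[j]])) next
        nmin <- min(nrow(demes[[i]]$g), nrow(demes[[j]]$g))
        k <- stats::rbinom(1L, nmin, cfg$m)
        if (k > 0L) {
          ai <- sample.int(nrow(demes[[i]]$g), k)
          aj <- sample.int(nrow(demes[[j]]$g), k)
          tmp <- take(demes[[i]], ai)
          demes[[i]]$g[ai, ] <- demes[[j]]$g[aj, , drop = FALSE]
          demes[[i]]$mt[ai] <- demes[[j]]$mt[aj]
          demes[[i]]$sex[ai] <- demes[[j]]$sex[aj]
          demes[[j]]$g[aj, ] <- tmp$g
          demes[[j]]$mt[aj] <- tmp$mt
          demes[[j]]$sex[aj] <- tmp$sex
        }
      }
    }
    if (is.na(done_gen) && all(!is.na(colonized_gen))) done_gen <- gen
    if (!is.na(done_gen) && gen >= done_gen + cfg$settle_gens) break
    if (gen >= cfg$max_gens)
      stop("simulation hit max_gens before full colonization; ",
           sum(is.na(colonized_gen)), " deme(s) never colonized")
  }

  # final sampling
  meta <- site_meta(data.frame(site = site_names,
                               lat = deme_coords(cfg)$lat,
                               lon = deme_coords(cfg)$lon,
                               cluster = cluster_of,
                               n_sampled = NA_integer_))
  ids <- character(0); a1 <- list(); a2 <- list(); site <- character(0)
  mt_seq <- character(0)
  for (i in seq_len(nd)) {
    N <- nrow(demes[[i]]$g)
    ns <- min(cfg$sample_n, N)
    if (ns < N || ns < cfg$sample_n)
      if (ns < cfg$sample_n)
        warning("deme ", site_names[i], " smaller than sample_n; sampled ", ns)
    idx <- sample.int(N, ns)
    meta$n_sampled[i] <- ns
    ids <- c(ids, sprintf("%s_%02d", site_names[i], seq_len(ns)))
    a1[[i]] <- demes[[i]]$g[idx, 2L * seq_len(L) - 1L, drop = FALSE]
    a2[[i]] <- demes[[i]]$g[idx, 2L * seq_len(L), drop = FALSE]
    site <- c(site, rep(site_names[i], ns))
    mt_seq <- c(mt_seq, vapply(demes[[i]]$mt[idx], function(h)
      paste(hap_sequence(reg, h), collapse = ""), character(1)))
  }
  gt <- genotype_table(ids, sprintf("L%02d", seq_len(L)),
                       do.call(rbind, a1), do.call(rbind, a2), site)
  hd <- collapse_haplotypes(mt_seq, site)

  truth <- list(origin = site_names[cfg$origin],
                colonized_gen = stats::setNames(colonized_gen, site_names),
                surfed_alleles = surfed_allele_truth(demes, cfg, site_names,
                                                     cluster_of),
                generations = gen, seed = cfg$seed)
  list(gt = gt, hd = hd, meta = meta, truth = truth)
}

# deme coordinates on a (possibly bent) 1-D route, centred near 45N 105E
deme_coords <- function(cfg) {
  km_per_deg_lat <- 111.195
  lat0 <- 45; lon0 <- 105
  dx <- dy <- numeric(cfg$n_demes)
  bend <- if (is.na(cfg$bend_at)) cfg$n_demes + 1L else cfg$bend_at
  for (i in seq_len(cfg$n_demes)) {
    if (i <= bend) { dx[i] <- (i - 1) * cfg$spacing_km; dy[i] <- 0 }
    else { dx[i] <- (bend - 1) * cfg$spacing_km
           dy[i] <- (i - bend) * cfg$spacing_km }
  }
  lat <- lat0 + dy / km_per_deg_lat
  lon <- lon0 + dx / (km_per_deg_lat * cos(lat0 * pi / 180))
  list(lat = lat, lon = lon)
}

# coalescent standing variation for the origin deme's mtDNA:
# returns one registry haplotype index per individual
sim_init_mt <- function(n, theta, reg) {
  lineages <- as.list(seq_len(n))
  muts <- vector("list", n)            # mutation ids per tip, tipward order
  kk <- n
  while (kk > 1L) {
    rate <- choose(kk, 2) / theta
    dt <- stats::rexp(1, rate)
    nm <- stats::rpois(kk, dt / 2)
    for (li in which(nm > 0)) for (tip in lineages[[li]])
      muts[[tip]] <- c(muts[[tip]], rep(-1L, nm[li]))  # placeholder count
    # materialize each event once with a fresh site
    for (li in which(nm > 0)) {
      for (e in seq_len(nm[li])) {
        s <- sample.int(length(reg$root), 1L)
        b <- sample(setdiff(c("A", "C", "G", "T"), reg$root[s]), 1L)
        id <- length(reg$site) + 1L
        reg$parent <- c(reg$parent, NA_integer_)  # resolved below
        reg$site <- c(reg$site, s)
        reg$base <- c(reg$base, b)
        for (tip in lineages[[li]]) {
          holes <- which(muts[[tip]] == -1L)
          muts[[tip]][holes[1]] <- id
        }
      }
    }
    pair <- sample.int(kk, 2L)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    kk <- kk - 1L
  }
  # chain each tip's mutations root->tip into registry parent links
  out <- integer(n)
  for (tip in seq_len(n)) {
    chain <- rev(muts[[tip]])          # collected tipward; reverse to rootward
    parent <- 0L
    for (id in chain) {
      reg$parent[id] <- parent
      parent <- id
    }
    out[tip] <- parent
  }
  out
}

# base at `site` for haplotype `h` (0 = root) given the mutation chain
hap_base_at <- function(reg, h, site) {
  while (h != 0L) {
    if (reg$site[h] == site) return(reg$base[h])
    h <- reg$parent[h]
  }
  reg$root[site]
}

# full sequence of haplotype `h`
hap_sequence <- function(reg, h) {
  seqv <- reg$root
  chain <- integer(0)
  while (h != 0L) { chain <- c(chain, h); h <- reg$parent[h] }
  for (id in rev(chain)) seqv[reg$site[id]] <- reg$base[id]
  seqv
}

# collapse per-individual sequences into haplotype_data
collapse_haplotypes <- function(seqs, sites) {
  u <- unique(seqs)
  hap_id <- sprintf("H%02d", seq_along(u))
  idx <- match(seqs, u)
  usites <- unique(sites)
  counts <- matrix(0L, length(u), length(usites),
                   dimnames = list(hap_id, usites))
  for (i in seq_along(seqs))
    counts[idx[i], sites[i]] <- counts[idx[i], sites[i]] + 1L
  haplotype_data(stats::setNames(u, hap_id), counts)
}

# ground truth: alleles rare in the origin cluster but common in some
# derived deme (computed from the full final populations, not the sample)
surfed_allele_truth <- function(demes, cfg, site_names, cluster_of,
                                rare = 0.05, common = 0.25) {
  L <- cfg$n_loci
  origin_cluster <- cluster_of[cfg$origin]
  src <- which(cluster_of == origin_cluster)
  der <- which(cluster_of != origin_cluster)
  out <- list()
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    src_copies <- unlist(lapply(src, function(i) demes[[i]]$g[, cols]))
    src_tab <- table(src_copies) / length(src_copies)
    for (i in der) {
      copies <- as.vector(demes[[i]]$g[, cols])
      tab <- table(copies) / length(copies)
      hits <- names(tab)[tab >= common]
      for (al in hits) {
        f_src <- if (al %in% names(src_tab)) as.numeric(src_tab[al]) else 0
        if (f_src < rare)
          out[[length(out) + 1L]] <- data.frame(
            locus = sprintf("L%02d", l), allele = as.integer(al),
            deme = site_names[i], deme_freq = as.numeric(tab[al]),
            origin_cluster_freq = f_src)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(locus = character(), allele = integer(), deme = character(),
               deme_freq = numeric(), origin_cluster_freq = numeric())
}
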