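#' Hierarchical AMOVA on microsatellite genotypes
#'
#' Distance-based analysis of molecular variance on the number-of-different-
#' alleles distance between diploid multilocus genotypes (for each locus the
#' two unordered allele pairs are compared and 0, 1 or 2 differences are
#' counted; loci missing in either individual are skipped).  With a cluster
#' column in `meta` a three-level design is fitted (among clusters, among
#' sites within clusters, within sites); without clusters, or with
#' `levels = 2`, a two-level design (among sites, within sites).  Variance
#' components follow the standard nested moments estimators with
#' unequal-sample-size coefficients; significance is assessed by
#' permutation: whole sites among clusters for Phi_CT, individuals among
#' sites within their cluster for Phi_SC, and individuals among all sites
#' for Phi_ST.
#'
#' @param gt a [genotype_table()].
#' @param meta a [site_meta()] table (needed for the three-level design).
#' @param reps number of permutations (default 1000).
#' @param seed integer seed.
#' @param levels 2 or 3 (default: 3 when `meta` has >= 2 clusters).
#' @return a list of class `amova_result`: `components` (data.frame with
#'   sigma2, percent per level), `phi` (named vector), `p_values`,
#'   `ss_table`, `reps`, `seed`.
#' @export
amova <- function(gt, meta = NULL, reps = 1000, seed = 1L, levels = NULL) {
  site <- unname(gt$site)
  if (!is.null(meta)) check_sites(gt, meta)
  cluster <- if (!is.null(meta)) meta$cluster[match(site, meta$site)] else NULL
  if (is.null(levels))
    levels <- if (!is.null(cluster) && length(unique(cluster)) >= 2L) 3L else 2L
  if (levels == 3L) {
    if (is.null(cluster)) stop("three-level design needs cluster metadata")
    sizes <- table(unique(data.frame(site, cluster))$cluster)
    if (any(sizes < 2L))
      stop("cluster(s) with a single site: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "),
           "; use levels = 2")
  }
  D <- genotype_distance_matrix(gt)
  obs <- amova_decompose(D, site, cluster, levels)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(site)
  p_st <- p_sc <- p_ct <- NA_real_
  # Phi_ST: individuals among all sites
  stat <- vapply(seq_len(reps), function(i) {
    amova_decompose(D, sample(site), cluster, levels)$phi["phi_st"]
  }, numeric(1))
  p_st <- (1 + sum(stat >= obs$phi["phi_st"])) / (reps + 1)
  if (levels == 3L) {
    # Phi_SC: individuals among sites within their cluster
    stat <- vapply(seq_len(reps), function(i) {
      s2 <- site
      for (cl in unique(cluster)) {
        idx <- which(cluster == cl)
        s2[idx] <- sample(s2[idx])
      }
      amova_decompose(D, s2, cluster, 3L)$phi["phi_sc"]
    }, numeric(1))
    p_sc <- (1 + sum(stat >= obs$phi["phi_sc"])) / (reps + 1)
    # Phi_CT: whole sites among clusters
    usite <- unique(site)
    ucl <- cluster[match(usite, site)]
    stat <- vapply(seq_len(reps), function(i) {
      perm_cl <- sample(ucl)
      amova_decompose(D, site, perm_cl[match(site, usite)], 3L)$phi["phi_ct"]
    }, numeric(1))
    p_ct <- (1 + sum(stat >= obs$phi["phi_ct"])) / (reps + 1)
  }
  structure(c(obs, list(
    p_values = c(phi_st = p_st, phi_sc = p_sc, phi_ct = p_ct),
    reps = reps, seed = seed)), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$components, digits = 4)
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), collapse = "  "), "\n")
  cat("p:  ", paste(names(x$p_values), signif(x$p_values, 3), collapse = "  "), "\n")
  invisible(x)
}

# squared-distance matrix: number of different alleles between individuals
genotype_distance_matrix <- function(gt) {
  n <- length(gt$individuals)
  D <- matrix(0, n, n)
  for (l in seq_along(gt$loci)) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    for (i in seq_len(n - 1L)) {
      if (is.na(a1[i])) next
      j <- (i + 1L):n
      ok <- !is.na(a1[j])
      jj <- j[ok]
      if (!length(jj)) next
      # shared alleles = size of the best matching between the two
      # unordered pairs; either pairing order, whichever matches more
      m11 <- (a1[i] == a1[jj]) + (a2[i] == a2[jj])
      m12 <- (a1[i] == a2[jj]) + (a2[i] == a1[jj])
      d <- 2L - pmax(m11, m12)
      D[i, jj] <- D[i, jj] + d
      D[jj, i] <- D[i, jj]
    }
  }
  D
}

# sums of squares from a squared-distance matrix: SS(group) = sum_{i<j} d2/n
ss_of <- function(D, idx) {
  if (length(idx) < 2L) return(0)
  sum(D[idx, idx]) / 2 / length(idx)
}

amova_decompose <- function(D, site, cluster, levels) {
  n <- length(site)
  usite <- unique(site)
  S <- length(usite)
  ss_total <- ss_of(D, seq_len(n))
  ss_wp <- sum(vapply(usite, function(s) ss_of(D, which(site == s)), numeric(1)))
  n_s <- as.numeric(table(site)[usite])
  if (levels == 2L) {
    df_wp <- n - S; df_ap <- S - 1L
    ms_wp <- ss_wp / df_wp
    ms_ap <- (ss_total - ss_wp) / df_ap
    n0 <- (n - sum(n_s^2) / n) / (S - 1L)
    s2_c <- ms_wp
    s2_b <- (ms_ap - ms_wp) / n0
    tot <- s2_b + s2_c
    comp <- data.frame(
      level = c("among_sites", "within_sites"),
      df = c(df_ap, df_wp), SS = c(ss_total - ss_wp, ss_wp),
      sigma2 = c(s2_b, s2_c), percent = 100 * c(s2_b, s2_c) / tot)
    phi <- c(phi_st = s2_b / tot)
    return(list(components = comp, phi = phi))
  }
  ucl <- unique(cluster)
  G <- length(ucl)
  cl_of_site <- cluster[match(usite, site)]
  ss_groups <- sum(vapply(ucl, function(g) ss_of(D, which(cluster == g)),
                          numeric(1)))
  ss_ap_wg <- ss_groups - ss_wp
  ss_ag <- ss_total - ss_groups
  df_wp <- n - S; df_ap <- S - G; df_ag <- G - 1L
  ms_wp <- ss_wp / df_wp
  ms_ap <- ss_ap_wg / df_ap
  ms_ag <- ss_ag / df_ag
  N_g <- vapply(ucl, function(g) sum(cluster == g), numeric(1))
  sum_ns2_by_g <- vapply(ucl, function(g) {
    s_in_g <- usite[cl_of_site == g]
    sum(as.numeric(table(site)[s_in_g])^2)
  }, numeric(1))
  n1 <- (n - sum(sum_ns2_by_g / N_g)) / df_ap
  n2 <- (sum(sum_ns2_by_g / N_g) - sum(n_s^2) / n) / df_ag
  n3 <- (n - sum(N_g^2) / n) / df_ag
  s2_c <- ms_wp
  s2_b <- (ms_ap - ms_wp) / n1
  s2_a <- (ms_ag - ms_wp - n2 * s2_b) / n3
  tot <- s2_a + s2_b + s2_c
  comp <- data.frame(
    level = c("among_clusters", "among_sites_within_clusters", "within_sites"),
    df = c(df_ag, df_ap, df_wp), SS = c(ss_ag, ss_ap_wg, ss_wp),
    sigma2 = c(s2_a, s2_b, s2_c),
    percent = 100 * c(s2_a, s2_b, s2_c) / tot)
  phi <- c(phi_st = (s2_a + s2_b) / tot,
           phi_sc = s2_b / (s2_b + s2_c),
           phi_ct = s2_a / tot)
  list(components = comp, phi = phi)
}
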