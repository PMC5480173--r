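#' Rarefied allelic richness for one allele-count vector
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from `N = sum(counts)` observed copies:
#' `sum_i (1 - choose(N - N_i, g) / choose(N, g))` (hypergeometric
#' rarefaction, as in gene-based rarefaction software).
#'
#' @param counts integer vector of allele copy counts at one site x locus.
#' @param g rarefaction size in gene copies; must satisfy `g <= sum(counts)`.
#' @return the rarefied allelic richness (numeric scalar).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction size g = ", g, " exceeds N = ", N)
  if (g < 1) stop("g must be >= 1")
  # lchoose handles choose(N - Ni, g) = 0 when N - Ni < g
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-site diversity summary for microsatellite data
#'
#' Computes, per site x locus and as unweighted per-site means over loci:
#' number of alleles `Na`, observed heterozygosity `Ho`, expected
#' heterozygosity `He = 1 - sum(p^2)` and its unbiased version
#' `uHe = 2n/(2n-1) * He`, and rarefied allelic richness `Ar` at `g` gene
#' copies.  Sites with fewer than `g` non-missing gene copies at a locus get
#' `Ar = NA` there (never extrapolated), with a warning.  Private alleles
#' (observed in exactly one site) and rare alleles (frequency below
#' `rare_thresh` in a site, and separately in a cluster when `meta` is
#' given) are listed.
#'
#' @param gt a [genotype_table()].
#' @param meta optional [site_meta()] table (enables the per-cluster rare
#'   allele list).
#' @param g rarefaction size in gene copies (default 14, i.e. 7 diploids).
#' @param rare_thresh frequency threshold defining a rare allele
#'   (default 0.05).
#' @return a list of class `diversity_summary`: `per_locus` (site x locus
#'   table), `per_site` (site means), `private_alleles`, `rare_alleles`
#'   (per site) and `rare_alleles_cluster` (per cluster, or `NULL`), plus
#'   the `g` used.
#' @export
diversity_summary <- function(gt, meta = NULL, g = 14, rare_thresh = 0.05) {
  freqs <- allele_frequencies(gt, "site")
  sites <- site_ids(gt)
  per_locus <- list()
  rarefaction_skipped <- 0L
  for (s in sites) {
    rows <- which(gt$site == s)
    for (l in seq_along(gt$loci)) {
      a1 <- gt$a1[rows, l]; a2 <- gt$a2[rows, l]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n == 0L) {
        per_locus[[length(per_locus) + 1L]] <- data.frame(
          site = s, locus = gt$loci[l], n = 0L, Na = NA_integer_,
          Ho = NA_real_, He = NA_real_, uHe = NA_real_, Ar = NA_real_)
        next
      }
      copies <- c(a1[ok], a2[ok])
      tab <- table(copies)
      p <- as.numeric(tab) / (2 * n)
      he <- 1 - sum(p^2)
      ar <- if (2 * n >= g) allelic_richness(as.integer(tab), g) else {
        rarefaction_skipped <- rarefaction_skipped + 1L
        NA_real_
      }
      per_locus[[length(per_locus) + 1L]] <- data.frame(
        site = s, locus = gt$loci[l], n = n, Na = length(tab),
        Ho = mean(a1[ok] != a2[ok]),
        He = he, uHe = 2 * n / (2 * n - 1) * he, Ar = ar)
    }
  }
  per_locus <- do.call(rbind, per_locus)
  rownames(per_locus) <- NULL
  if (rarefaction_skipped > 0L)
    warning(rarefaction_skipped, " site x locus cell(s) have fewer than g = ",
            g, " gene copies; Ar left undefined there")

  agg <- function(v) {
    m <- tapply(v, per_locus$site, mean, na.rm = TRUE)
    as.numeric(m[sites])
  }
  per_site <- data.frame(site = sites, n = agg(per_locus$n),
                         Na = agg(per_locus$Na), Ho = agg(per_locus$Ho),
                         He = agg(per_locus$He), uHe = agg(per_locus$uHe),
                         Ar = agg(per_locus$Ar))
  rownames(per_site) <- NULL

  # private alleles: allele at a locus observed in exactly one site
  key <- paste(freqs$locus, freqs$allele)
  nsites_of_allele <- table(key)
  priv <- freqs[nsites_of_allele[key] == 1L, c("group", "locus", "allele", "freq")]
  names(priv)[1] <- "site"
  rownames(priv) <- NULL

  rare <- freqs[freqs$freq < rare_thresh, c("group", "locus", "allele", "freq")]
  names(rare)[1] <- "site"
  rownames(rare) <- NULL

  rare_cl <- NULL
  if (!is.null(meta)) {
    fc <- allele_frequencies(gt, "cluster", meta)
    rare_cl <- fc[fc$freq < rare_thresh, c("group", "locus", "allele", "freq")]
    names(rare_cl)[1] <- "cluster"
    rownames(rare_cl) <- NULL
  }
  structure(list(per_locus = per_locus, per_site = per_site,
                 private_alleles = priv, rare_alleles = rare,
                 rare_alleles_cluster = rare_cl,
                 g = g, rare_thresh = rare_thresh),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("diversity_summary over", nrow(x$per_site), "sites (Ar at g =",
      x$g, "gene copies)\n")
  print(x$per_site, digits = 3)
  invisible(x)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Permutes the observed gene copies into random diploid pairings and
#' compares the heterozygote count of each pairing with the observed one.
#' The two-sided statistic is the absolute deviation of the heterozygote
#' count from its permutation mean; the p-value carries +1 continuity on
#' numerator and denominator.
#'
#' @param gt a [genotype_table()].
#' @param site,locus the site and locus to test.
#' @param reps number of random pairings (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return a list with `p_value`, `het_obs`, `het_expected` (permutation
#'   mean), `n`, `monomorphic` flag, `reps` and `seed`.
#' @export
hwe_test <- function(gt, site, locus, reps = 10000, seed = 1L) {
  l <- match(locus, gt$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  rows <- which(gt$site == site)
  if (!length(rows)) stop("unknown site: ", site)
  a1 <- gt$a1[rows, l]; a2 <- gt$a2[rows, l]
  ok <- !is.na(a1)
  if (sum(ok) < 3L) stop("need >= 3 genotyped individuals for the HWE test")
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  copies <- c(a1, a2)
  if (length(unique(copies)) == 1L)
    return(list(p_value = 1.0, het_obs = 0L, het_expected = 0,
                n = n, monomorphic = TRUE, reps = reps, seed = seed))
  het_obs <- sum(a1 != a2)
  het_perm <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      x <- sample(copies)
      sum(x[seq_len(n)] != x[n + seq_len(n)])
    }, integer(1))
  })
  mu <- mean(het_perm)
  p <- (1 + sum(abs(het_perm - mu) >= abs(het_obs - mu))) / (reps + 1)
  list(p_value = p, het_obs = het_obs, het_expected = mu,
       n = n, monomorphic = FALSE, reps = reps, seed = seed)
}

#' Hardy-Weinberg tests across all sites and loci
#'
#' Runs [hwe_test()] for every site x locus with at least 5 genotyped
#' individuals and applies a Bonferroni correction across the tests
#' performed.
#'
#' @param gt a [genotype_table()].
#' @param reps permutations per test.
#' @param seed integer seed; each test uses an offset derived from it.
#' @return data.frame with columns `site`, `locus`, `n`, `het_obs`,
#'   `p_value`, `p_bonferroni`, `monomorphic`.
#' @export
hwe_table <- function(gt, reps = 10000, seed = 1L) {
  out <- list()
  k <- 0L
  for (s in site_ids(gt)) for (l in gt$loci) {
    rows <- which(gt$site == s)
    n_ok <- sum(!is.na(gt$a1[rows, l]))
    if (n_ok < 5L) next
    k <- k + 1L
    r <- hwe_test(gt, s, l, reps = reps, seed = seed + k)
    out[[k]] <- data.frame(site = s, locus = l, n = r$n, het_obs = r$het_obs,
                           p_value = r$p_value, monomorphic = r$monomorphic)
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  rownames(res) <- NULL
  res
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
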