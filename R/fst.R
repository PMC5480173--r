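#' Weir-Cockerham theta for a set of populations
#'
#' Method-of-moments estimator of F_ST from the 1984 variance-component
#' framework.  For every locus and allele, the among-population (`a`),
#' among-individual-within-population (`b`) and within-individual (`c`)
#' components are computed from sample sizes, allele frequencies and
#' observed heterozygote frequencies, and theta is the ratio
#' `sum(a) / sum(a + b + c)` over all alleles and loci.  Negative estimates
#' are retained.
#'
#' @param gt a [genotype_table()] restricted to the populations of interest
#'   (every site in `gt` is treated as one population).
#' @return a list with `theta`, the per-locus component sums
#'   (`a`, `b`, `c` per locus), and `loci_used`.
#' @export
wc_theta <- function(gt) {
  pops <- site_ids(gt)
  r <- length(pops)
  if (r < 2L) stop("need at least two populations")
  rows_of <- lapply(pops, function(s) which(gt$site == s))
  A <- B <- C <- numeric(length(gt$loci))
  used <- logical(length(gt$loci))
  for (l in seq_along(gt$loci)) {
    ni <- hbar_i <- numeric(r)
    pmat <- NULL
    freqs <- list(); hets <- list()
    ok_all <- TRUE
    for (i in seq_len(r)) {
      a1 <- gt$a1[rows_of[[i]], l]; a2 <- gt$a2[rows_of[[i]], l]
      ok <- !is.na(a1)
      ni[i] <- sum(ok)
      if (ni[i] < 1L) { ok_all <- FALSE; break }
      freqs[[i]] <- c(a1[ok], a2[ok])
      hets[[i]] <- cbind(a1[ok], a2[ok])[a1[ok] != a2[ok], , drop = FALSE]
    }
    if (!ok_all) next   # locus absent in one population: dropped
    alleles <- sort(unique(unlist(freqs)))
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(seq_len(r), function(i) mean(freqs[[i]] == al), numeric(1))
      h_i <- vapply(seq_len(r), function(i)
        sum(hets[[i]] == al) / ni[i], numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A[l] <- A[l] + a; B[l] <- B[l] + b; C[l] <- C[l] + cc
    }
    used[l] <- TRUE
  }
  if (!any(used)) stop("no locus usable across all populations")
  denom <- sum(A[used] + B[used] + C[used])
  theta <- if (denom == 0) 0 else sum(A[used]) / denom
  list(theta = theta,
       components = data.frame(locus = gt$loci, a = A, b = B, c = C,
                               used = used),
       loci_used = gt$loci[used])
}

#' Pairwise Weir-Cockerham F_ST matrix between sites
#'
#' @param gt a [genotype_table()] with at least two sites.
#' @return symmetric numeric matrix of pairwise theta estimates with zero
#'   diagonal, classed `fst_matrix`.  Loci entirely missing in one member of
#'   a pair are dropped for that pair.
#' @export
pairwise_fst <- function(gt) {
  sites <- site_ids(gt)
  if (length(sites) < 2L) stop("need at least two sites")
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)[-length(sites)]) for (j in (i + 1):length(sites)) {
    sub <- subset_genotypes(gt, sites = sites[c(i, j)])
    th <- wc_theta(sub)$theta
    m[i, j] <- m[j, i] <- th
  }
  class(m) <- c("fst_matrix", class(m))
  m
}

#' Nei's D_a genetic distance between sites
#'
#' `D_a(x, y) = 1 - (1/L) * sum over loci of sum over alleles of
#' sqrt(p_x * p_y)`; zero iff the two sites share identical frequency
#' profiles at every locus used, one when allele sets are disjoint at every
#' locus.
#'
#' @param gt a [genotype_table()] with at least two sites.
#' @return symmetric distance matrix (zero diagonal).
#' @export
nei_da <- function(gt) {
  sites <- site_ids(gt)
  if (length(sites) < 2L) stop("need at least two sites")
  freqs <- allele_frequencies(gt, "site")
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)[-length(sites)]) for (j in (i + 1):length(sites)) {
    tot <- 0; L_used <- 0L
    for (l in gt$loci) {
      px <- freq_vector(freqs, sites[i], l)
      py <- freq_vector(freqs, sites[j], l)
      if (!length(px) || !length(py)) next
      shared <- intersect(names(px), names(py))
      tot <- tot + sum(sqrt(px[shared] * py[shared]))
      L_used <- L_used + 1L
    }
    if (L_used == 0L) stop("no locus shared between ", sites[i], " and ", sites[j])
    m[i, j] <- m[j, i] <- 1 - tot / L_used
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a warning.  Returns an unrooted tree in Newick form.
#'
#' @param d symmetric numeric matrix with zero diagonal, >= 3 taxa.
#' @return a single Newick string (also carries the `phylo` object as
#'   attribute `tree`).
#' @export
nj_tree <- function(d) {
  d <- unclass(d)
  if (!isSymmetric(unname(d), tol = 1e-10)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative branch length(s) clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  structure(ape::write.tree(tr), tree = tr)
}
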