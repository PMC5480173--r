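#' Sequence diversity summary for haplotype data
#'
#' Computes sample size `n`, number of haplotypes `N_hap`, segregating sites
#' `S`, haplotype diversity `Hd`, mean pairwise differences `k` and
#' nucleotide diversity `pi`.  Haplotype counts are expanded implicitly:
#' every statistic equals the one computed on the per-individual sequence
#' list.  `Hd = n/(n-1) * (1 - sum(p_i^2))`.  `S` is counted over columns
#' polymorphic among the present haplotypes; when `include_indels` each
#' maximal run of contiguous alignment columns containing a gap counts as a
#' single indel event, otherwise gapped columns are excluded.  `pi` and `k`
#' always use gap-free, N-free columns only, weighting each haplotype pair
#' by the product of counts.
#'
#' @param hd a [haplotype_data()].
#' @param sites,haplotypes,group optional subset (see [subset_haplotypes()]).
#' @param include_indels count indel events in `S` (default `TRUE`).
#' @return a list with `n`, `N_hap`, `S`, `S_substitutions`, `S_indel_events`,
#'   `Hd`, `k`, `pi`, `n_sites_used`.
#' @export
seq_diversity <- function(hd, sites = NULL, haplotypes = NULL, group = NULL,
                          include_indels = TRUE) {
  sub <- subset_haplotypes(hd, sites = sites, haplotypes = haplotypes,
                           group = group)
  cnt <- rowSums(sub$counts)
  n <- sum(cnt)
  if (n < 2L) stop("need at least 2 sampled individuals in the subset")
  p <- cnt / n
  hd_div <- if (nrow(sub$seqs) == 1L) 0 else n / (n - 1) * (1 - sum(p^2))

  poly <- polymorphic_columns(sub$seqs)
  S_sub <- length(poly$substitution)
  S_ind <- poly$n_indel_events
  S <- if (include_indels) S_sub + S_ind else S_sub

  dmat <- hap_diff_matrix(sub$seqs)
  L <- attr(dmat, "n_sites")
  npairs <- n * (n - 1) / 2
  w <- outer(cnt, cnt)
  diag(w) <- cnt * (cnt - 1) / 2
  w[lower.tri(w)] <- 0
  k <- sum(w * dmat) / npairs
  list(n = n, N_hap = nrow(sub$seqs), S = S, S_substitutions = S_sub,
       S_indel_events = S_ind, Hd = hd_div, k = k,
       pi = if (L > 0) k / L else NA_real_, n_sites_used = L)
}

# classify alignment columns of a haplotype matrix:
#  - clean: no gap/N anywhere; substitution-polymorphic clean columns
#  - indel events: maximal runs of contiguous columns containing '-'
#    in some but not all rows
polymorphic_columns <- function(seqs) {
  has_gap <- apply(seqs == "-", 2L, any)
  has_n <- apply(seqs == "N", 2L, any)
  clean <- !has_gap & !has_n
  nall <- apply(seqs, 2L, function(col) length(unique(col)))
  substitution <- which(clean & nall > 1L)
  informative_gap <- has_gap & apply(seqs == "-", 2L, function(z) !all(z))
  r <- rle(as.vector(informative_gap))
  n_events <- sum(r$values)
  list(substitution = substitution, clean = which(clean),
       n_indel_events = n_events)
}

# pairwise hamming distances between haplotypes over clean columns
hap_diff_matrix <- function(seqs) {
  clean <- polymorphic_columns(seqs)$clean
  m <- seqs[, clean, drop = FALSE]
  H <- nrow(seqs)
  d <- matrix(0L, H, H, dimnames = list(rownames(seqs), rownames(seqs)))
  if (H > 1L) for (i in seq_len(H - 1L)) for (j in (i + 1L):H)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  attr(d, "n_sites") <- length(clean)
  d
}

# weighted base counts per clean column; returns S, k, eta_s on the
# expanded sample (used by the neutrality tests)
neutrality_inputs <- function(hd, sites = NULL, haplotypes = NULL,
                              group = NULL) {
  sub <- subset_haplotypes(hd, sites = sites, haplotypes = haplotypes,
                           group = group)
  cnt <- rowSums(sub$counts)
  n <- sum(cnt)
  clean <- polymorphic_columns(sub$seqs)$clean
  m <- sub$seqs[, clean, drop = FALSE]
  S <- 0L; eta_s <- 0L
  if (ncol(m)) for (col in seq_len(ncol(m))) {
    tab <- tapply(cnt, m[, col], sum)
    if (length(tab) > 1L) {
      S <- S + 1L
      eta_s <- eta_s + sum(tab == 1L)
    }
  }
  dmat <- hap_diff_matrix(sub$seqs)
  w <- outer(cnt, cnt); diag(w) <- cnt * (cnt - 1) / 2
  w[lower.tri(w)] <- 0
  k <- sum(w * dmat) / (n * (n - 1) / 2)
  list(n = n, S = S, eta_s = eta_s, k = k)
}

#' Tajima's D
#'
#' Contrasts the pairwise-difference estimator of theta with the
#' segregating-sites estimator using the standard normalizing constants for
#' sample size `n`.  Computed on gap-free substitution sites with haplotype
#' counts expanded.
#'
#' @inheritParams seq_diversity
#' @return list with `D`, `S`, `k`, `n`; `D` is `NA` (with a `defined`
#'   flag) when `S = 0`.
#' @export
tajimas_d <- function(hd, sites = NULL, haplotypes = NULL, group = NULL) {
  x <- neutrality_inputs(hd, sites, haplotypes, group)
  if (x$n < 4L) stop("Tajima's D needs n >= 4")
  if (x$S == 0L)
    return(list(D = NA_real_, S = 0L, k = x$k, n = x$n, defined = FALSE))
  ct <- tajima_constants(x$n)
  D <- (x$k - x$S / ct$a1) /
    sqrt(ct$e1 * x$S + ct$e2 * x$S * (x$S - 1))
  list(D = D, S = x$S, k = x$k, n = x$n, defined = TRUE)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Outgroup-free versions built from the total number of segregating sites
#' `S`, the singleton count `eta_s` (sites at which exactly one sampled
#' individual carries the minority base) and, for F*, the mean pairwise
#' difference `k`, with the corrected variance constants in standard use.
#'
#' @inheritParams seq_diversity
#' @return list with `D_star`, `F_star`, `S`, `eta_s`, `k`, `n`.
#' @export
fu_li_tests <- function(hd, sites = NULL, haplotypes = NULL, group = NULL) {
  x <- neutrality_inputs(hd, sites, haplotypes, group)
  n <- x$n; S <- x$S
  if (n < 4L) stop("Fu & Li tests need n >= 4")
  if (S == 0L)
    return(list(D_star = NA_real_, F_star = NA_real_, S = 0L,
                eta_s = 0L, k = x$k, n = n, defined = FALSE))
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2); an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  D_star <- (n / (n - 1) * S - an * x$eta_s) / sqrt(uD * S + vD * S^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  F_star <- (x$k - (n - 1) / n * x$eta_s) / sqrt(uF * S + vF * S^2)
  list(D_star = D_star, F_star = F_star, S = S, eta_s = x$eta_s,
       k = x$k, n = n, defined = TRUE)
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` where `S'` is the probability of observing at
#' least the sampled number of distinct haplotypes under the Ewens sampling
#' distribution with theta set to the mean pairwise difference `k`.
#' Probabilities use unsigned Stirling numbers of the first kind computed in
#' log space.  Strongly negative values indicate an excess of haplotypes
#' relative to `k`, the signature of recent expansion.
#'
#' @inheritParams seq_diversity
#' @return list with `Fs`, `S_prime`, `k`, `K_obs` (haplotype count), `n`.
#' @export
fu_fs <- function(hd, sites = NULL, haplotypes = NULL, group = NULL) {
  sub <- subset_haplotypes(hd, sites = sites, haplotypes = haplotypes,
                           group = group)
  cnt <- rowSums(sub$counts)
  n <- sum(cnt)
  x <- neutrality_inputs(hd, sites, haplotypes, group)
  if (x$k <= 0)
    return(list(Fs = NA_real_, S_prime = NA_real_, k = x$k,
                K_obs = nrow(sub$seqs), n = n, defined = FALSE))
  K_obs <- nrow(sub$seqs)
  lp <- ewens_log_probs(n, x$k)
  S_prime <- sum(exp(lp[K_obs:n]))
  S_prime <- min(max(S_prime, 0), 1)
  Fs <- if (S_prime <= 0) -Inf else if (S_prime >= 1) Inf else
    log(S_prime / (1 - S_prime))
  list(Fs = Fs, S_prime = S_prime, k = x$k, K_obs = K_obs, n = n,
       defined = is.finite(Fs))
}

# log P(K = k | theta, n) for k = 1..n under the Ewens sampling formula,
# via unsigned Stirling numbers of the first kind in log space
ewens_log_probs <- function(n, theta) {
  ls <- log_stirling_first(n)
  lrf <- sum(log(theta + 0:(n - 1)))        # log rising factorial
  k <- seq_len(n)
  ls + k * log(theta) - lrf
}

# log |s(n, k)| for k = 1..n by the recurrence
# |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|
log_stirling_first <- function(n) {
  cur <- c(0)                                # n = 1: |s(1,1)| = 1
  if (n == 1L) return(cur)
  for (m in seq_len(n - 1L)) {
    nxt <- numeric(m + 1L)
    prev <- c(cur, -Inf)                     # k = 1..m (+ pad)
    shifted <- c(-Inf, cur)                  # k-1 term
    grown <- log(m) + prev
    nxt <- pmax(grown, shifted) +
      log1p(exp(pmin(grown, shifted) - pmax(grown, shifted)))
    nxt[is.nan(nxt)] <- -Inf
    cur <- nxt
  }
  cur
}
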