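#' Observed mismatch distribution
#'
#' Distribution of pairwise nucleotide differences (gap-free, N-free
#' columns) over all pairs of sampled individuals, weighting between-
#' haplotype pairs by count products and within-haplotype pairs by
#' `choose(count, 2)`.
#'
#' @inheritParams seq_diversity
#' @return numeric vector of probabilities named `0..d_max`, summing to 1.
#' @export
mismatch <- function(hd, sites = NULL, haplotypes = NULL, group = NULL) {
  sub <- subset_haplotypes(hd, sites = sites, haplotypes = haplotypes,
                           group = group)
  cnt <- rowSums(sub$counts)
  n <- sum(cnt)
  if (n < 2L) stop("need at least 2 sampled individuals")
  dmat <- hap_diff_matrix(sub$seqs)
  w <- outer(cnt, cnt); diag(w) <- cnt * (cnt - 1) / 2
  w[lower.tri(w)] <- 0
  dmax <- max(dmat)
  out <- numeric(dmax + 1L)
  for (i in seq_len(nrow(dmat))) for (j in i:nrow(dmat))
    out[dmat[i, j] + 1L] <- out[dmat[i, j] + 1L] + w[i, j]
  out <- out / (n * (n - 1) / 2)
  names(out) <- 0:dmax
  out
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over difference classes, where
#' `d` is the largest observed difference and `x_{d+1} = 0` is the empty
#' class past it.  Low values indicate the smooth unimodal shape expected
#' after a sudden expansion.
#'
#' @param mm mismatch distribution (probabilities named `0..d`).
#' @return the raggedness index (numeric scalar).
#' @export
raggedness <- function(mm) {
  x <- c(as.numeric(mm), 0)
  sum(diff(x)^2)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Rogers-Harpending model: a population at mutation-scaled size `theta0`
#' grew instantaneously to `theta1` at time `tau` (units of 1/(2u)
#' generations) before the present.  The expected frequency of pairs with
#' `i` differences mixes the equilibrium geometric distribution at `theta1`
#' with a Poisson(`tau`) shift of the ancestral geometric at `theta0`.
#'
#' @param tau expansion age in mutational time, `>= 0`.
#' @param theta0,theta1 mutation-scaled population sizes before/after the
#'   expansion.
#' @param dmax largest difference class to evaluate.
#' @return numeric vector of expected frequencies for `0..dmax`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, dmax) {
  geom <- function(theta, i) {
    if (theta <= 0) return(as.numeric(i == 0))
    exp(i * log(theta) - (i + 1) * log(theta + 1))
  }
  i <- 0:dmax
  f1 <- geom(theta1, i)
  f0 <- geom(theta0, i)
  if (tau <= 0) return(f0)
  # log-space Poisson-type weights tau^j/j! * exp(-tau (theta1+1)/theta1)
  lw <- (0:dmax) * log(tau) - lgamma(1:(dmax + 1)) -
    tau * (theta1 + 1) / max(theta1, 1e-12)
  w <- exp(lw)
  conv <- vapply(i, function(ii)
    sum(w[1:(ii + 1)] * (f0[(ii:0) + 1] - f1[(ii:0) + 1])), numeric(1))
  f1 + conv
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of `(tau, theta0, theta1)` minimizing the sum of
#' squared deviations (SSD) between observed and expected class
#' frequencies, by Nelder-Mead started from a coarse grid (the SSD surface
#' is multimodal in `tau`).  P-values for SSD and for Harpending's
#' raggedness come from a parametric bootstrap: coalescent samples of the
#' same size are simulated under the fitted expansion, the model is refit
#' to each, and the p-value is the proportion of replicates with a
#' statistic at least as large as observed.
#'
#' @param mm observed mismatch distribution (probabilities named `0..d`).
#' @param n sample size behind `mm` (needed for the bootstrap).
#' @param reps bootstrap replicates (default 1000; 0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @return list of class `mismatch_fit`: `tau`, `theta0`, `theta1`, `SSD`,
#'   `raggedness`, `p_SSD`, `p_raggedness`, `expected`, `observed`, `reps`,
#'   `seed`.
#' @export
fit_sudden_expansion <- function(mm, n, reps = 1000, seed = 1L) {
  if (length(mm) < 2L) stop("mismatch distribution needs >= 2 support points")
  obs <- as.numeric(mm)
  dmax <- length(obs) - 1L
  fit <- fit_mismatch_ssd(obs)
  if (!fit$converged)
    stop("sudden-expansion fit failed to converge from every start; ",
         "best SSD = ", signif(fit$SSD, 4))
  r_obs <- raggedness(obs)
  p_ssd <- p_rag <- NA_real_
  if (reps > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    ssd_b <- rag_b <- numeric(reps)
    for (b in seq_len(reps)) {
      sim <- sim_coalescent_sample(n, tau = fit$tau, theta0 = fit$theta0,
                                   theta1 = fit$theta1)
      mm_b <- sim$mismatch
      refit <- fit_mismatch_ssd(mm_b, starts = list(
        c(fit$tau, fit$theta0, fit$theta1)), quick = TRUE)
      ssd_b[b] <- refit$SSD
      rag_b[b] <- raggedness(mm_b)
    }
    p_ssd <- mean(ssd_b >= fit$SSD)
    p_rag <- mean(rag_b >= r_obs)
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$SSD, raggedness = r_obs,
                 p_SSD = p_ssd, p_raggedness = p_rag,
                 expected = expected_mismatch(fit$tau, fit$theta0,
                                              fit$theta1, dmax),
                 observed = obs, reps = reps, seed = seed),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau=%.3f theta0=%.3f theta1=%.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD=%.5g (p=%s)  raggedness=%.4f (p=%s)\n", x$SSD,
              format(x$p_SSD), x$raggedness, format(x$p_raggedness)))
  invisible(x)
}

# multi-start bounded Nelder-Mead minimization of the SSD
fit_mismatch_ssd <- function(obs, starts = NULL, quick = FALSE) {
  dmax <- length(obs) - 1L
  ssd_of <- function(par) {
    tau <- par[1]; th0 <- par[2]; th1 <- par[3]
    if (tau < 0 || tau > 50 || th0 < 0 || th0 > 100 ||
        th1 < 0 || th1 > 100) return(1e6)
    sum((obs - expected_mismatch(tau, th0, th1, dmax))^2)
  }
  if (is.null(starts)) {
    kbar <- sum((0:dmax) * obs)
    starts <- list()
    for (tau in unique(pmin(c(0.5, 2, kbar, 10, 25), 50)))
      for (th0 in c(0.1, 2)) for (th1 in c(5, 50))
        starts[[length(starts) + 1L]] <- c(tau, th0, th1)
  } else if (!quick) {
    starts <- c(starts, list(c(1, 0.5, 10), c(5, 1, 50)))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, ssd_of, method = "Nelder-Mead",
                      control = list(maxit = if (quick) 300 else 1000,
                                     reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(tau = best$par[1], theta0 = best$par[2], theta1 = best$par[3],
       SSD = best$value, converged = best$value < 1e6)
}

#' Coalescent sample under the sudden-expansion model
#'
#' Simulates one Kingman coalescent genealogy of `n` lineages with
#' piecewise-constant mutation-scaled size (`theta1` more recently than
#' `tau`, `theta0` earlier) and infinite-sites mutations, returning the
#' summary statistics the expansion tests need.  Time is mutational
#' (units of 1/(2u) generations); with `tau = 0` this is a constant-size
#' coalescent at `theta0`.
#'
#' @param n sample size.
#' @param tau expansion age (0 for constant size).
#' @param theta0,theta1 sizes before/after the expansion.
#' @return list with `S` (segregating sites), `k` (mean pairwise
#'   difference), `eta_s` (singleton mutations, folded), and `mismatch`
#'   (probability vector over difference classes `0..d_max`).
#' @export
sim_coalescent_sample <- function(n, tau, theta0, theta1 = theta0) {
  stopifnot(n >= 2)
  D <- matrix(0L, n, n)
  lineages <- as.list(seq_len(n))
  s <- 0; kk <- n
  S <- 0L; eta_s <- 0L
  while (kk > 1L) {
    theta_cur <- if (s < tau) theta1 else theta0
    rate <- choose(kk, 2) / theta_cur
    t_next <- stats::rexp(1, rate)
    boundary <- s < tau && s + t_next > tau
    dt <- if (boundary) tau - s else t_next
    # mutations on each lineage during dt (rate 1/2 per unit per lineage)
    nm <- stats::rpois(kk, dt / 2)
    for (li in which(nm > 0)) {
      A <- lineages[[li]]
      sz <- length(A)
      S <- S + nm[li]
      if (sz == 1L || sz == n - 1L) eta_s <- eta_s + nm[li]
      D[A, -A] <- D[A, -A] + nm[li]
      D[-A, A] <- D[-A, A] + nm[li]
    }
    s <- s + dt
    if (boundary) next
    pair <- sample.int(kk, 2L)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    kk <- kk - 1L
  }
  dv <- D[upper.tri(D)]
  k <- mean(dv)
  mm <- tabulate(dv + 1L, nbins = max(dv) + 1L) / length(dv)
  names(mm) <- 0:max(dv)
  list(S = S, k = k, eta_s = eta_s, mismatch = mm)
}
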