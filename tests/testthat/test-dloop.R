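test_that("haplotype diversity matches closed forms", {
  hd1 <- make_hd(c("ACGT"), 5L)
  expect_equal(seq_diversity(hd1)$Hd, 0)

  hd2 <- make_hd(c("ACGT", "ACTT"), c(1L, 1L))
  expect_equal(seq_diversity(hd2)$Hd, 1.0)

  hd3 <- make_hd(c("ACGT", "ACTT"), c(3L, 1L))
  expect_equal(seq_diversity(hd3)$Hd, 0.5, tolerance = 1e-12)
})

test_that("segregating sites count substitutions and indel events", {
  # one substitution at a gap-free column + one 2-column contiguous gap:
  # 2 events with indels, 1 without
  hd <- make_hd(c("ACGTAA", "ACTTAA", "ACG--A"), c(2L, 1L, 1L))
  sd_with <- seq_diversity(hd, include_indels = TRUE)
  sd_without <- seq_diversity(hd, include_indels = FALSE)
  expect_equal(sd_with$S_indel_events, 1L)
  expect_equal(sd_with$S_substitutions, 1L)
  expect_equal(sd_with$S, 2L)
  expect_equal(sd_without$S, 1L)
  # pi and k use gap-free columns only (cols 1, 2, 3, 6)
  expect_equal(sd_with$n_sites_used, 4L)
})

test_that("diversity is invariant to splitting a haplotype record", {
  hd <- make_hd(c("ACGTACGT", "ACTTACGT", "ACGTACTT"), c(4L, 2L, 2L))
  # split H1 into two identical rows is impossible (rows must be distinct);
  # equivalently, spread its count over two sites
  counts2 <- rbind(c(2L, 2L), c(2L, 0L), c(0L, 2L))
  dimnames(counts2) <- list(c("H1", "H2", "H3"), c("s1", "s2"))
  hd2 <- haplotype_data(c(H1 = "ACGTACGT", H2 = "ACTTACGT", H3 = "ACGTACTT"),
                        counts2)
  a <- seq_diversity(hd); b <- seq_diversity(hd2)
  expect_equal(a$Hd, b$Hd); expect_equal(a$pi, b$pi); expect_equal(a$k, b$k)
})

test_that("statistics on expanded sequence lists equal the count form", {
  sim <- simulate_expansion(fixture_config("tiny"))
  hd <- sim$hd
  # expand to one record per individual and rebuild
  cnt <- rowSums(hd$counts)
  seqs <- apply(hd$seqs, 1, paste, collapse = "")
  expanded <- rep(seqs, cnt)
  names(expanded) <- paste0("ind", seq_along(expanded))
  key <- !duplicated(expanded)
  counts <- as.matrix(table(factor(expanded, levels = expanded[key])))
  colnames(counts) <- "all"
  rownames(counts) <- names(expanded)[key]
  hd_e <- haplotype_data(stats::setNames(expanded[key],
                                         names(expanded)[key]), counts)
  a <- seq_diversity(hd); b <- seq_diversity(hd_e)
  expect_equal(a$Hd, b$Hd); expect_equal(a$k, b$k); expect_equal(a$S, b$S)
  expect_equal(tajimas_d(hd)$D, tajimas_d(hd_e)$D)
  expect_equal(mismatch(hd), mismatch(hd_e))
})

test_that("Tajima's D matches a hand calculation through the constants", {
  # n = 4, one singleton mutation: S = 1, k = 2*1*3/(4*3/2) = 0.5... k is
  # the mean over C(4,2)=6 pairs of which 3 differ: k = 3/6 = 0.5
  hd <- make_hd(c("ACGT", "ACTT"), c(3L, 1L))
  x <- tajimas_d(hd)
  n <- 4; S <- 1
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_hand <- (0.5 - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(x$D, D_hand, tolerance = 1e-12)
  expect_equal(x$S, 1L)

  # identical sequences: undefined, not zero
  hd0 <- make_hd(c("ACGT", "ACGA"), c(4L, 0L))
  expect_error(tajimas_d(hd0), NA)  # subsetting drops the zero-count row
  expect_false(tajimas_d(make_hd("ACGT", 5L))$defined)
})

test_that("Tajima's D is near zero for constant-size coalescent samples", {
  set.seed(31)
  n <- 50; theta <- 5
  ds <- replicate(400, {
    s <- sim_coalescent_sample(n, tau = 0, theta0 = theta)
    if (s$S == 0) return(NA_real_)
    ct <- volesurf:::tajima_constants(n)
    (s$k - s$S / ct$a1) / sqrt(ct$e1 * s$S + ct$e2 * s$S * (s$S - 1))
  })
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})

test_that("Fu & Li's D* separates singleton-rich from singleton-free data", {
  # every mutation a singleton
  hd_sing <- make_hd(c("AAAAAA", "CAAAAA", "ACAAAA", "AACAAA"),
                     c(5L, 1L, 1L, 1L))
  # no mutation a singleton (each variant carried by 3 individuals)
  hd_bal <- make_hd(c("AAAAAA", "CCCAAA"), c(3L, 3L))
  a <- fu_li_tests(hd_sing); b <- fu_li_tests(hd_bal)
  expect_lt(a$D_star, b$D_star)
  expect_lt(a$F_star, b$F_star)
  expect_equal(a$eta_s, 3L)
  expect_false(fu_li_tests(make_hd("ACGT", 5L))$defined)
})

test_that("Fu & Li statistics are near zero under the neutral coalescent", {
  set.seed(13)
  n <- 30; theta <- 5
  i <- 1:(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2); an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  vals <- replicate(400, {
    s <- sim_coalescent_sample(n, tau = 0, theta0 = theta)
    if (s$S == 0) return(NA_real_)
    (n / (n - 1) * s$S - an * s$eta_s) / sqrt(uD * s$S + vD * s$S^2)
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.2)
})

test_that("Fu's Fs closed form holds at n = 2 and the Stirling ladder is exact", {
  # n = 2, one difference: k = 1, S' = P(K = 2) = theta/(1+theta) = 0.5
  hd <- make_hd(c("ACGT", "ACTT"), c(1L, 1L))
  x <- fu_fs(hd)
  expect_equal(x$S_prime, 0.5, tolerance = 1e-12)
  expect_equal(x$Fs, 0, tolerance = 1e-12)

  # Stirling numbers vs direct polynomial expansion of
  # theta (theta+1) ... (theta+n-1) for n = 10
  n <- 10
  ls <- volesurf:::log_stirling_first(n)
  coefs <- 1
  for (m in 0:(n - 1)) coefs <- c(0, coefs) + c(coefs * m, 0)
  # coefs[k+1] is the coefficient of theta^k; |s(n,k)| = coefs[k+1]
  expect_equal(exp(ls), coefs[2:(n + 1)], tolerance = 1e-10)

  # star-like data: strongly negative Fs
  star <- make_hd(c("AAAAAAAAAA", "CAAAAAAAAA", "ACAAAAAAAA", "AACAAAAAAA",
                    "AAACAAAAAA", "AAAACAAAAA", "AAAAACAAAA"),
                  c(30L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_lt(fu_fs(star)$Fs, -3)
})

test_that("mismatch distribution matches its closed form and brute force", {
  hd0 <- make_hd("ACGT", 6L)
  expect_equal(mismatch(hd0), c(`0` = 1))

  # two haplotypes d = 2 apart, counts 3 and 2
  hd <- make_hd(c("AAAA", "CCAA"), c(3L, 2L))
  mm <- mismatch(hd)
  n <- 5
  expect_equal(unname(mm["0"]), (choose(3, 2) + choose(2, 2)) / choose(n, 2))
  expect_equal(unname(mm["2"]), 3 * 2 / choose(n, 2))

  # brute force over expanded pairs for random small cases
  set.seed(21)
  for (rep in 1:10) {
    H <- sample(2:4, 1)
    len <- 12
    seqs <- unique(replicate(H, paste(sample(c("A", "C"), len, TRUE),
                                      collapse = "")))
    cnt <- sample(1:4, length(seqs), TRUE)
    hdr <- make_hd(seqs, as.integer(cnt))
    mm2 <- mismatch(hdr)
    expanded <- rep(seqs, cnt)
    diffs <- c()
    for (i in seq_along(expanded)[-length(expanded)])
      for (j in (i + 1):length(expanded))
        diffs <- c(diffs, sum(strsplit(expanded[i], "")[[1]] !=
                                strsplit(expanded[j], "")[[1]]))
    brute <- tabulate(diffs + 1L, nbins = max(diffs) + 1L) / length(diffs)
    expect_equal(as.numeric(mm2), brute, tolerance = 1e-12)
  }
})

test_that("raggedness follows the successive-difference convention", {
  # x = (0.5, 0.5): terms (x1-x0)^2 + (0-x1)^2 = 0 + 0.25
  expect_equal(raggedness(c(`0` = 0.5, `1` = 0.5)), 0.25)
  # smooth unimodal < two-peaked on the same support
  smooth <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  peaky <- c(0.4, 0.0, 0.2, 0.0, 0.4)
  expect_lt(raggedness(smooth), raggedness(peaky))
})

test_that("the sudden-expansion fit recovers parameters from its own curve", {
  tau <- 4; th0 <- 0.5; th1 <- 30
  curve <- expected_mismatch(tau, th0, th1, 20)
  names(curve) <- 0:20
  fit <- fit_sudden_expansion(curve, n = 100, reps = 0)
  expect_lt(fit$SSD, 1e-8)
  expect_equal(fit$tau, tau, tolerance = 0.05)
})

test_that("expected mismatch is a proper distribution and hits its limits", {
  f <- expected_mismatch(3, 0.2, 40, 400)
  expect_equal(sum(f), 1, tolerance = 1e-6)
  expect_true(all(f >= -1e-12))
  # tau = 0 collapses to the ancestral equilibrium geometric
  f0 <- expected_mismatch(0, 2, 40, 50)
  expect_equal(f0, 2^(0:50) / 3^(1:51), tolerance = 1e-12)
  # Monte-Carlo check of the transient formula at modest n
  set.seed(8)
  mean_sim <- mean(replicate(300, sim_coalescent_sample(20, 3, 0.5, 30)$k))
  mean_theory <- sum((0:400) * expected_mismatch(3, 0.5, 30, 400))
  expect_equal(mean_sim, mean_theory, tolerance = 0.15)
})

test_that("bootstrap p-values flag model-consistent data as non-significant", {
  set.seed(91)
  sim <- sim_coalescent_sample(60, tau = 3, theta0 = 0.1, theta1 = 50)
  fit <- fit_sudden_expansion(sim$mismatch, n = 60, reps = 60, seed = 5)
  expect_gte(fit$p_SSD, 0.05)
})
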