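# independent oracles shared by unit and acceptance tests

# Weir-Cockerham theta by literal nested ANOVA mean squares on gene-copy
# indicators -- a second, independent route to the same estimator
anova_theta <- function(gt) {
  pops <- site_ids(gt)
  r <- length(pops)
  num <- den <- 0
  for (l in seq_along(gt$loci)) {
    dat <- lapply(pops, function(s) {
      rows <- which(gt$site == s)
      a1 <- gt$a1[rows, l]; a2 <- gt$a2[rows, l]
      ok <- !is.na(a1)
      cbind(a1[ok], a2[ok])
    })
    ni <- vapply(dat, nrow, integer(1))
    if (any(ni < 1L)) next
    N <- sum(ni)
    nc <- (N - sum(ni^2) / N) / (r - 1)
    alleles <- sort(unique(unlist(dat)))
    for (al in alleles) {
      ybar_pop <- numeric(r); msg_num <- 0; msi_num <- 0
      for (i in seq_len(r)) {
        y <- (dat[[i]] == al) * 1
        ybar_ind <- rowMeans(y)
        ybar_pop[i] <- mean(ybar_ind)
        msg_num <- msg_num + sum((y - ybar_ind)^2)
        msi_num <- msi_num + 2 * sum((ybar_ind - ybar_pop[i])^2)
      }
      ybar_all <- sum(ni * ybar_pop) / N
      msp <- 2 * sum(ni * (ybar_pop - ybar_all)^2) / (r - 1)
      msi <- msi_num / sum(ni - 1)
      msg <- msg_num / N
      a <- (msp - msi) / (2 * nc)
      b <- (msi - msg) / 2
      num <- num + a
      den <- den + a + b + msg
    }
  }
  num / den
}

# rarefied allelic richness by exhaustive enumeration of every g-subset
exhaustive_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# location of the deposited study data (GenBank D-loop haplotypes and the
# supplementary haplotype count table); see inst/extdata/deposited/README.md
deposited_path <- function(file) {
  file.path(system.file("extdata", "deposited", package = "volesurf"), file)
}

# haplogroup memberships as printed in the source study's haplogroup table
hg_members <- function() {
  list(Hg1 = paste0("H", c(2, 3, 4, 6, 7, 9, 15, 16, 17, 18, 19, 21,
                           24, 25, 26, 27, 28, 29)),
       Hg2 = paste0("H", c(1, 5, 8, 10, 11, 12, 13, 14, 20, 22, 23, 30)))
}
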