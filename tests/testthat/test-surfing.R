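test_that("haversine distance hits its anchors and is symmetric", {
  expect_equal(haversine_km(45, 105, 45, 105), 0)
  expect_equal(haversine_km(0, 0, 0, 180), 6371.0088 * pi, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:20) {
    a <- c(stats::runif(1, -90, 90), stats::runif(1, -180, 180))
    b <- c(stats::runif(1, -90, 90), stats::runif(1, -180, 180))
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 haversine_km(b[1], b[2], a[1], a[2]), tolerance = 1e-9)
  }
})

test_that("IBD regression is exact on linear data and validates input", {
  # construct a theta matrix lying exactly on y = 0.02 ln(d) + 0.01
  meta <- site_meta(data.frame(site = paste0("s", 1:5),
                               lat = rep(45, 5),
                               lon = 105 + (0:4) * 1.3,
                               cluster = "X"))
  gd <- volesurf:::site_distance_matrix(meta)
  y <- 0.02 * log(gd) + 0.01
  th <- y / (1 + y)               # invert theta/(1-theta)
  diag(th) <- 0
  colnames(th) <- rownames(th) <- meta$site
  res <- ibd_regression(th, meta)
  expect_equal(res$slope, 0.02, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$n_pairs, choose(5, 2))

  expect_error(ibd_regression(th[1:3, 1:3], meta[1:3, ]), ">= 4 sites")
})

test_that("IBD slope significance is invariant to rescaling distances", {
  set.seed(4)
  meta <- site_meta(data.frame(site = paste0("s", 1:6), lat = rep(45, 6),
                               lon = 105 + (0:5) * 0.9, cluster = "X"))
  gd <- volesurf:::site_distance_matrix(meta)
  y <- 0.03 * log(gd) + 0.02 + matrix(stats::rnorm(36, 0, 0.002), 6)
  y <- (y + t(y)) / 2; diag(y) <- 0
  th <- y / (1 + y); colnames(th) <- rownames(th) <- meta$site
  r1 <- ibd_regression(th, meta)
  meta2 <- meta; meta2$lon <- 105 + (meta$lon - 105) * 3  # ~3x distances
  r2 <- ibd_regression(th, meta2)
  # distances scale only approximately under a longitude stretch on the
  # sphere, so the comparison is loose-but-tight at the 0.1% level
  expect_equal(r1$slope, r2$slope, tolerance = 1e-3)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-2)
})

test_that("IBD p-values are roughly uniform on unstructured data", {
  set.seed(12)
  meta <- site_meta(data.frame(site = paste0("s", 1:7), lat = rep(45, 7),
                               lon = 105 + (0:6) * 0.8, cluster = "X"))
  ps <- replicate(60, {
    y <- matrix(stats::runif(49, 0.01, 0.1), 7)
    y <- (y + t(y)) / 2; diag(y) <- 0
    th <- y / (1 + y); colnames(th) <- rownames(th) <- meta$site
    ibd_regression(th, meta)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(min(ps), 0)
})

test_that("cross-cluster mean F_ST finds a planted focal site", {
  meta <- site_meta(data.frame(
    site = c("a1", "a2", "a3", "b1", "b2"),
    lat = rep(45, 5), lon = 105:109,
    cluster = c("A", "A", "A", "B", "B")))
  th <- matrix(0.3, 5, 5, dimnames = list(meta$site, meta$site))
  diag(th) <- 0
  # a2 is nearly identical to the target pool
  th["a2", c("b1", "b2")] <- th[c("b1", "b2"), "a2"] <- c(0.01, 0.02)
  th["a1", c("b1", "b2")] <- th[c("b1", "b2"), "a1"] <- c(0.30, 0.32)
  th["a3", c("b1", "b2")] <- th[c("b1", "b2"), "a3"] <- c(0.28, 0.35)
  res <- cross_cluster_mean_fst(th, meta, "A", "B")
  expect_equal(res$focal, "a2")
  expect_true(res$significant)
  expect_false(res$tie)

  # exchangeable source sites: no significance
  th2 <- th
  th2[c("a1", "a2", "a3"), c("b1", "b2")] <- 0.30 +
    matrix(c(0.001, -0.002, 0.002, -0.001, 0.0, 0.001), 3)
  th2[c("b1", "b2"), c("a1", "a2", "a3")] <-
    t(th2[c("a1", "a2", "a3"), c("b1", "b2")])
  res2 <- cross_cluster_mean_fst(th2, meta, "A", "B")
  expect_false(res2$significant)
})

test_that("the focal site is invariant to adding a constant to theta", {
  meta <- site_meta(data.frame(
    site = c("a1", "a2", "a3", "b1", "b2"),
    lat = rep(45, 5), lon = 105:109,
    cluster = c("A", "A", "A", "B", "B")))
  set.seed(9)
  y <- matrix(stats::runif(25, 0.05, 0.3), 5)
  y <- (y + t(y)) / 2; diag(y) <- 0
  dimnames(y) <- list(meta$site, meta$site)
  r1 <- cross_cluster_mean_fst(y, meta, "A", "B")
  y2 <- y + 0.1; diag(y2) <- 0
  r2 <- cross_cluster_mean_fst(y2, meta, "A", "B")
  expect_equal(r1$focal, r2$focal)
})

test_that("route designations produce one start and one arrival per pair", {
  sim <- default_sim_batch(1)[[1]]
  foc <- suppressWarnings(
    identify_focal_sites(sim$fst, sim$sim$meta, c("SE", "NE", "W"), sim$div))
  expect_equal(nrow(foc), 4L)
  expect_equal(foc$role, c("starting", "arrival", "starting", "arrival"))
  expect_equal(foc$cluster, c("SE", "NE", "NE", "W"))
  # a starting site that is not the Ar maximum is retained with a warning
  # flag, never dropped
  expect_true(all(!is.na(foc$site)))
  expect_type(foc$ar_warning, "logical")
})

test_that("diversity clines are exact on constructed data", {
  sites <- paste0("s", 1:6)
  meta <- site_meta(data.frame(site = sites, lat = rep(45, 6),
                               lon = 105 + 0:5, cluster = "X"))
  th <- matrix(0, 6, 6, dimnames = list(sites, sites))
  th[, 1] <- th[1, ] <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4)
  th[2:6, 2:6] <- 0.25; diag(th) <- 0
  div <- list(per_site = data.frame(site = sites,
                                    He = 0.7 - 0.5 * th[, 1],
                                    Ar = 5 - 2 * th[, 1]))
  res <- diversity_cline(div, th, "s1", "X", meta)
  expect_equal(res$He$slope, -0.5, tolerance = 1e-9)
  expect_equal(res$He$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$Ar$slope, -2, tolerance = 1e-9)
  # focal site excluded: 5 points
  expect_equal(res$He$n, 5L)
  res_in <- diversity_cline(div, th, "s1", "X", meta, exclude_focal = FALSE)
  expect_equal(res_in$He$n, 6L)
})

test_that("allele cline scan flags exact clines and excludes degenerates", {
  sites <- paste0("s", 1:5)
  meta <- site_meta(data.frame(site = sites, lat = rep(45, 5),
                               lon = 105 + 0:4, cluster = "X"))
  th <- matrix(0.2, 5, 5, dimnames = list(sites, sites))
  th[, 1] <- th[1, ] <- c(0, 0.1, 0.2, 0.3, 0.4); diag(th) <- 0
  # allele 1 frequency proportional to theta; allele 2 the complement;
  # allele 3 constant
  fr <- do.call(rbind, lapply(2:5, function(i) data.frame(
    group = sites[i], locus = "L1",
    allele = c(101L, 102L, 103L),
    count = c(round(100 * th[i, 1]), 100 - round(100 * th[i, 1]) - 20L, 20L),
    freq = c(th[i, 1], 1 - th[i, 1] - 0.2, 0.2))))
  scan <- allele_cline_scan(fr, th, "s1", "X", meta, min_sites = 3)
  a1 <- scan$table[scan$table$allele == 101L, ]
  expect_equal(a1$r, 1, tolerance = 1e-9)
  expect_true(a1$significant)
  expect_true("zero variance across sites" %in% scan$excluded$reason)
  expect_equal(scan$n_significant_increasing, 1L)
  expect_equal(scan$n_significant_decreasing, 1L)
})

test_that("rare-to-common scan honours both thresholds", {
  meta <- site_meta(data.frame(site = c("a1", "a2", "b1", "b2"),
                               lat = rep(45, 4), lon = 105:108,
                               cluster = c("A", "A", "B", "B")))
  fr <- rbind(
    data.frame(group = "a1", locus = "L1", allele = 101L, count = 40L, freq = 1),
    data.frame(group = "a2", locus = "L1", allele = 101L, count = 38L, freq = 0.95),
    data.frame(group = "a2", locus = "L1", allele = 103L, count = 2L, freq = 0.05),
    data.frame(group = "b1", locus = "L1", allele = 101L, count = 24L, freq = 0.6),
    data.frame(group = "b1", locus = "L1", allele = 102L, count = 16L, freq = 0.4),
    data.frame(group = "b2", locus = "L1", allele = 101L, count = 40L, freq = 1))
  res <- rare_to_common_scan(fr, meta, "A", "B")
  # allele 102 absent from source, 0.4 in b1 -> listed
  expect_true(102L %in% res$table$allele)
  # allele 101 common in source -> never listed
  expect_false(101L %in% res$table$allele)
  row <- res$table[res$table$allele == 102L, ]
  expect_equal(row$source_freq, 0)
  expect_equal(row$derived_max_site_freq, 0.4)
})

test_that("the pipeline is deterministic and fails fast with stage names", {
  cfg <- sim_config(n_demes = 6, origin = 2, K = 50, founder_size = 6,
                    n_loci = 4, mt_len = 150, theta_mt = 1.5,
                    burn_in = 30, settle_gens = 10, sample_n = 15,
                    cluster_sizes = c(3, 3), cluster_labels = c("A", "B"),
                    seed = 88)
  sim <- simulate_expansion(cfg)
  rep1 <- suppressWarnings(
    run_surfing_pipeline(sim$gt, sim$meta, route = c("A", "B"), hd = sim$hd,
                         g = 6, amova_reps = 30, mismatch_reps = 10,
                         seed = 5))
  rep2 <- suppressWarnings(
    run_surfing_pipeline(sim$gt, sim$meta, route = c("A", "B"), hd = sim$hd,
                         g = 6, amova_reps = 30, mismatch_reps = 10,
                         seed = 5))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_surfing_report(rep1, f1); write_surfing_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(c("diversity", "fst", "amova", "ibd", "focal_sites",
                    "rare_to_common", "dloop") %in% names(rep1)))

  bad_meta <- sim$meta[1:2, ]
  expect_error(
    run_surfing_pipeline(sim$gt, bad_meta, route = c("A", "B"), seed = 1),
    "stage 'validate'")
})
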