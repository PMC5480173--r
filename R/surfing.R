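#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371.0088 km.  Vectorized over
#' coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# site-by-site great-circle distance matrix from metadata
site_distance_matrix <- function(meta) {
  n <- nrow(meta)
  m <- matrix(0, n, n, dimnames = list(meta$site, meta$site))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- haversine_km(meta$lat[i], meta$lon[i], meta$lat[j], meta$lon[j])
  m
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearized differentiation
#' `theta / (1 - theta)` on the natural log of great-circle distance (km)
#' over all unordered site pairs.  Pairs with `theta >= 1` or zero distance
#' are excluded with a warning; negative theta values are retained (the
#' transform is monotone for `theta < 1`).  An optional Mantel permutation
#' test (via \pkg{vegan}) supplements the parametric F-test.
#'
#' @param fst pairwise F_ST matrix from [pairwise_fst()].
#' @param meta a [site_meta()] table covering the matrix sites.
#' @param cluster optional cluster label restricting the analysis.
#' @param mantel_reps Mantel permutations (0 = skip).
#' @param seed integer seed for the Mantel permutations.
#' @return list of class `ibd_result`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `mantel_p`, `n_pairs`, `subset`, and the pair table.
#' @export
ibd_regression <- function(fst, meta, cluster = NULL, mantel_reps = 0,
                           seed = 1L) {
  sites <- colnames(fst)
  if (!is.null(cluster)) sites <- intersect(sites, cluster_sites(meta, cluster))
  if (length(sites) < 4L) stop("isolation by distance needs >= 4 sites")
  meta <- meta[match(sites, meta$site), ]
  gd <- site_distance_matrix(meta)
  pairs <- which(upper.tri(gd), arr.ind = TRUE)
  th <- fst[sites, sites][upper.tri(gd)]
  d <- gd[upper.tri(gd)]
  drop <- th >= 1 | d <= 0
  if (any(drop))
    warning(sum(drop), " pair(s) dropped (theta >= 1 or zero distance)")
  th <- th[!drop]; d <- d[!drop]
  pairs <- pairs[!drop, , drop = FALSE]
  x <- log(d)
  if (length(unique(round(x, 12))) < 2L)
    stop("degenerate design: all pairwise distances equal")
  y <- th / (1 - th)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  mantel_p <- NA_real_
  if (mantel_reps > 0) {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("vegan is required for the Mantel test")
    ydist <- fst[sites, sites] / (1 - fst[sites, sites])
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lgd <- gd; lgd[lgd > 0] <- log(lgd[lgd > 0])
    mt <- vegan::mantel(stats::as.dist(lgd), stats::as.dist(ydist),
                        permutations = mantel_reps)
    mantel_p <- mt$signif
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
    mantel_p = mantel_p, n_pairs = length(y),
    subset = if (is.null(cluster)) "all" else cluster,
    pairs = data.frame(site_a = sites[pairs[, 1]], site_b = sites[pairs[, 2]],
                       ln_km = x, fst_linearized = y)),
    class = "ibd_result")
}

#' Cross-cluster mean F_ST and the focal site of a cluster pair
#'
#' For every site `s` of the source cluster, collects the vector of
#' pairwise theta values between `s` and each site of the target cluster
#' and its mean; a one-way ANOVA across source sites (target-site values as
#' replicates) with all-pairs Tukey HSD at `alpha` identifies whether the
#' site with the lowest mean differs significantly from every other source
#' site.  Such a minimum is the focal site of the pair: the putative
#' colonization start (when read source-to-target) or arrival point.
#'
#' @param fst pairwise F_ST matrix.
#' @param meta a [site_meta()] table.
#' @param source,target cluster labels (source needs >= 3 sites, target
#'   >= 2).
#' @param alpha significance level for the Tukey comparisons.
#' @return list of class `focal_site_result`: `focal` (site id, or several
#'   on a tie), `significant` (focal mean differs from all others),
#'   `tie` flag, `site_means`, `anova_F`, `anova_p`, `tukey` table,
#'   `values` (site x target matrix).
#' @export
cross_cluster_mean_fst <- function(fst, meta, source, target, alpha = 0.05) {
  src <- intersect(colnames(fst), cluster_sites(meta, source))
  tgt <- intersect(colnames(fst), cluster_sites(meta, target))
  if (length(src) < 3L) stop("source cluster needs >= 3 sites")
  if (length(tgt) < 2L) stop("target cluster needs >= 2 sites")
  vals <- fst[src, tgt, drop = FALSE]
  means <- rowMeans(vals)
  df <- data.frame(theta = as.vector(t(vals)),
                   site = factor(rep(src, each = length(tgt)), levels = src))
  fit <- stats::aov(theta ~ site, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$site
  focal <- names(means)[means <= min(means) + 1e-12]
  tie <- length(focal) > 1L
  sig <- FALSE
  if (!tie) {
    others <- setdiff(src, focal)
    pair_p <- vapply(others, function(o) {
      key1 <- paste0(o, "-", focal); key2 <- paste0(focal, "-", o)
      if (key1 %in% rownames(tk)) tk[key1, "p adj"] else tk[key2, "p adj"]
    }, numeric(1))
    sig <- all(pair_p < alpha)
  }
  structure(list(focal = focal, significant = sig, tie = tie,
                 site_means = means,
                 anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tk, values = vals,
                 source = source, target = target, alpha = alpha),
            class = "focal_site_result")
}

#' Start and arrival sites along a colonization route
#'
#' For each consecutive ordered cluster pair `(A, B)` of the route, the
#' starting site in `A` is the site with the lowest mean F_ST to the sites
#' of `B`, and the arrival site in `B` is the site with the lowest mean
#' F_ST to the sites of `A`.  A starting site is additionally annotated
#' with whether it carries the highest allelic richness of its cluster;
#' when it does not, the designation is retained with a warning flag (the
#' expected pattern can fail at a bridge cluster without invalidating the
#' F_ST criterion).
#'
#' @param fst pairwise F_ST matrix.
#' @param meta a [site_meta()] table.
#' @param route ordered character vector of >= 2 cluster labels.
#' @param diversity a [diversity_summary()] (for the `Ar` annotation).
#' @param alpha Tukey significance level.
#' @return data.frame of class `focal_designations` with one row per
#'   designation: `pair`, `cluster`, `role` (`starting`/`arrival`), `site`,
#'   `mean_fst`, `significant`, `tie`, `max_ar` (starting rows only),
#'   `ar_warning`.  The underlying `focal_site_result`s are in attribute
#'   `details`.
#' @export
identify_focal_sites <- function(fst, meta, route, diversity, alpha = 0.05) {
  if (length(route) < 2L) stop("route needs at least two clusters")
  rows <- list(); details <- list()
  for (i in seq_len(length(route) - 1L)) {
    a <- route[i]; b <- route[i + 1L]
    start <- cross_cluster_mean_fst(fst, meta, a, b, alpha)
    arrive <- cross_cluster_mean_fst(fst, meta, b, a, alpha)
    ar <- diversity$per_site
    ar_a <- ar[ar$site %in% cluster_sites(meta, a), ]
    max_ar_site <- ar_a$site[which.max(ar_a$Ar)]
    is_max <- start$focal[1] == max_ar_site
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(a, b, sep = "->"), cluster = a, role = "starting",
      site = start$focal[1], mean_fst = min(start$site_means),
      significant = start$significant, tie = start$tie,
      max_ar = is_max, ar_warning = !is_max)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(a, b, sep = "->"), cluster = b, role = "arrival",
      site = arrive$focal[1], mean_fst = min(arrive$site_means),
      significant = arrive$significant, tie = arrive$tie,
      max_ar = NA, ar_warning = FALSE)
    details[[paste(a, b, sep = "->")]] <- list(start = start, arrival = arrive)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$ar_warning))
    warning("starting site(s) without the highest allelic richness: ",
            paste(out$site[out$ar_warning & out$role == "starting"],
                  collapse = ", "))
  attr(out, "details") <- details
  class(out) <- c("focal_designations", class(out))
  out
}

#' Diversity clines against F_ST to a focal site
#'
#' Regresses per-site expected heterozygosity and allelic richness on the
#' pairwise theta between each site of a cluster and the focal
#' (start/arrival) site.  The focal site itself is excluded by default: its
#' theta to itself is zero by construction and would anchor the fit.
#'
#' @param diversity a [diversity_summary()].
#' @param fst pairwise F_ST matrix.
#' @param focal focal site id.
#' @param cluster cluster label to analyse (needs >= 4 sites incl. focal),
#'   or `NULL` to regress across every site in the matrix (the whole-
#'   transect serial-founder prediction).
#' @param meta a [site_meta()] table.
#' @param exclude_focal drop the focal site from the regression points
#'   (default `TRUE`).
#' @return list of class `cline_result` with elements `He` and `Ar`, each
#'   `slope`, `r`, `r_squared`, `p_value`, `n`; plus the point table.
#' @export
diversity_cline <- function(diversity, fst, focal, cluster = NULL, meta,
                            exclude_focal = TRUE) {
  sites <- if (is.null(cluster)) colnames(fst) else
    intersect(colnames(fst), cluster_sites(meta, cluster))
  if (!focal %in% sites)
    stop("focal site ", focal, " not among the regression sites")
  pts <- if (exclude_focal) setdiff(sites, focal) else sites
  if (length(pts) < 3L) stop("cline regression needs >= 3 sites")
  ds <- diversity$per_site
  tab <- data.frame(site = pts,
                    theta = fst[pts, focal],
                    He = ds$He[match(pts, ds$site)],
                    Ar = ds$Ar[match(pts, ds$site)])
  reg <- function(y) {
    ok <- is.finite(y) & is.finite(tab$theta)
    if (sum(ok) < 3L) stop("cline regression needs >= 3 finite points")
    ct <- stats::cor.test(tab$theta[ok], y[ok])
    fit <- stats::lm(y[ok] ~ tab$theta[ok])
    list(slope = unname(stats::coef(fit)[2]),
         r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = sum(ok))
  }
  structure(list(He = reg(tab$He), Ar = reg(tab$Ar), points = tab,
                 focal = focal,
                 cluster = if (is.null(cluster)) "all" else cluster),
            class = "cline_result")
}

#' Allele-frequency cline scan within a cluster
#'
#' Pearson correlation between per-site allele frequency and theta to the
#' focal site, for every locus-allele observed in at least `min_sites`
#' sites of the cluster.  Alleles with zero frequency variance are excluded
#' with a reason.  Significance stars follow the ns / * / ** convention at
#' 0.05 and 0.01 with no multiple-testing correction; a Benjamini-Hochberg
#' column is emitted alongside.
#'
#' @param freqs per-site allele frequency table from [allele_frequencies()].
#' @param fst pairwise F_ST matrix.
#' @param focal focal site id.
#' @param cluster cluster label.
#' @param meta a [site_meta()] table.
#' @param min_sites minimum number of cluster sites an allele must be
#'   observed in (default 3).
#' @param alpha significance level (default 0.05).
#' @param exclude_focal drop the focal site from the regression points
#'   (default `TRUE`).
#' @return list of class `allele_cline_scan`: `table` (locus, allele,
#'   cluster-wide frequency, `r`, `r_squared`, `p_value`, `stars`, `p_BH`,
#'   `significant`), `excluded` (with reasons), and counts
#'   `n_significant_increasing` / `n_significant_decreasing`.
#' @export
allele_cline_scan <- function(freqs, fst, focal, cluster, meta,
                              min_sites = 3, alpha = 0.05,
                              exclude_focal = TRUE) {
  sites <- intersect(colnames(fst), cluster_sites(meta, cluster))
  pts <- if (exclude_focal) setdiff(sites, focal) else sites
  if (length(pts) < 3L) stop("cline scan needs >= 3 sites")
  theta <- fst[pts, focal]
  fr <- freqs[freqs$group %in% sites, ]
  out <- list(); excl <- list()
  for (l in unique(fr$locus)) {
    frl <- fr[fr$locus == l, ]
    for (al in unique(frl$allele)) {
      seen <- frl$group[frl$allele == al & frl$freq > 0]
      if (length(seen) < min_sites) {
        excl[[length(excl) + 1L]] <- data.frame(
          locus = l, allele = al, reason = paste0(
            "observed in ", length(seen), " < ", min_sites, " sites"))
        next
      }
      f <- vapply(pts, function(s) {
        v <- frl$freq[frl$group == s & frl$allele == al]
        if (length(v)) v else 0
      }, numeric(1))
      cw <- cluster_frequency(freqs, frl, al, sites)
      if (stats::sd(f) == 0) {
        excl[[length(excl) + 1L]] <- data.frame(
          locus = l, allele = al, reason = "zero variance across sites")
        next
      }
      ct <- stats::cor.test(theta, f)
      out[[length(out) + 1L]] <- data.frame(
        locus = l, allele = al, cluster_freq = cw,
        r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
        p_value = ct$p.value)
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(locus = character(), allele = integer(),
               cluster_freq = numeric(), r = numeric(),
               r_squared = numeric(), p_value = numeric())
  if (nrow(tab)) {
    tab$stars <- ifelse(tab$p_value < 0.01, "**",
                        ifelse(tab$p_value < alpha, "*", "ns"))
    tab$p_BH <- stats::p.adjust(tab$p_value, "BH")
    tab$significant <- tab$p_value < alpha
  }
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    excluded = if (length(excl)) do.call(rbind, excl) else NULL,
    n_significant_increasing = sum(tab$significant & tab$r > 0),
    n_significant_decreasing = sum(tab$significant & tab$r < 0),
    focal = focal, cluster = cluster, min_sites = min_sites, alpha = alpha),
    class = "allele_cline_scan")
}

# pooled within-cluster frequency of one locus-allele (weights by copies)
cluster_frequency <- function(freqs, frl, allele, sites) {
  tot <- sum(frl$count[frl$group %in% sites])
  sum(frl$count[frl$group %in% sites & frl$allele == allele]) / tot
}

#' Rare-to-common allele scan between clusters
#'
#' Lists alleles whose pooled frequency in the source cluster is below
#' `rare_thresh` but which show frequencies in the derived cluster
#' consistent with having surfed on the expansion front: a maximum per-site
#' frequency of at least `common_thresh`, or a pooled derived-cluster
#' frequency of at least `2 * rare_thresh`.  Both evidence columns are
#' reported so the threshold choice stays transparent.
#'
#' @param freqs per-site allele frequency table from [allele_frequencies()].
#' @param meta a [site_meta()] table.
#' @param source,derived cluster labels.
#' @param rare_thresh source-cluster rarity threshold (default 0.05).
#' @param common_thresh per-site commonness threshold in the derived
#'   cluster (default 0.25).
#' @return list of class `rare_to_common_result`: `table` (locus, allele,
#'   `source_freq`, `derived_max_site_freq`, `derived_freq`,
#'   `max_site`), plus the thresholds used.
#' @export
rare_to_common_scan <- function(freqs, meta, source, derived,
                                rare_thresh = 0.05, common_thresh = 0.25) {
  src_sites <- cluster_sites(meta, source)
  der_sites <- cluster_sites(meta, derived)
  fr <- freqs[freqs$group %in% c(src_sites, der_sites), ]
  out <- list()
  for (l in unique(fr$locus)) {
    frl <- fr[fr$locus == l, ]
    alleles <- unique(frl$allele[frl$group %in% der_sites])
    for (al in alleles) {
      src_tot <- sum(frl$count[frl$group %in% src_sites])
      src_f <- if (src_tot > 0)
        sum(frl$count[frl$group %in% src_sites & frl$allele == al]) / src_tot
      else NA_real_
      if (!is.finite(src_f) || src_f >= rare_thresh) next
      der_rows <- frl$allele == al & frl$group %in% der_sites
      der_tot <- sum(frl$count[frl$group %in% der_sites])
      der_f <- sum(frl$count[der_rows]) / der_tot
      if (!any(der_rows)) next
      mx <- max(frl$freq[der_rows])
      mx_site <- frl$group[der_rows][which.max(frl$freq[der_rows])]
      if (mx >= common_thresh || der_f >= 2 * rare_thresh)
        out[[length(out) + 1L]] <- data.frame(
          locus = l, allele = al, source_freq = src_f,
          derived_max_site_freq = mx, derived_freq = der_f,
          max_site = mx_site)
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(locus = character(), allele = integer(),
               source_freq = numeric(), derived_max_site_freq = numeric(),
               derived_freq = numeric(), max_site = character())
  rownames(tab) <- NULL
  structure(list(table = tab, source = source, derived = derived,
                 rare_thresh = rare_thresh, common_thresh = common_thresh),
            class = "rare_to_common_result")
}
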