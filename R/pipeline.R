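#' Run the full range-expansion / surfing analysis
#'
#' Orchestrates the microsatellite and (optionally) mtDNA stages: diversity
#' summary, pairwise F_ST, Nei's D_a and NJ tree, AMOVA, isolation by
#' distance (overall and per cluster), start/arrival-site identification
#' along the declared route, He/Ar cline regressions and allele-frequency
#' cline scans at every focal site, rare-to-common scans along the route,
#' and the D-loop diversity/neutrality/mismatch battery.  The report embeds
#' the configuration, seeds, and an MD5 hash of the configuration so that
#' identical inputs and seed give byte-identical reports.
#'
#' @param gt a [genotype_table()].
#' @param meta a [site_meta()] table.
#' @param route ordered character vector of cluster labels (colonization
#'   order).
#' @param hd optional [haplotype_data()] for the mtDNA stages.
#' @param g rarefaction size in gene copies (default 14).
#' @param rare_thresh rare-allele threshold (default 0.05).
#' @param common_thresh rare-to-common evidence threshold (default 0.25).
#' @param alpha significance level (default 0.05).
#' @param amova_reps,mismatch_reps permutation/bootstrap replicates.
#' @param seed master integer seed; each stage derives its own offset.
#' @return a list of class `surfing_report` with one element per stage plus
#'   `config`.
#' @export
run_surfing_pipeline <- function(gt, meta, route, hd = NULL,
                                 g = 14, rare_thresh = 0.05,
                                 common_thresh = 0.25, alpha = 0.05,
                                 amova_reps = 200, mismatch_reps = 200,
                                 seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  stage("validate", check_sites(gt, meta))
  if (!all(route %in% meta$cluster))
    stop("stage 'validate' failed: route cluster(s) missing from metadata")
  config <- list(g = g, rare_thresh = rare_thresh,
                 common_thresh = common_thresh, alpha = alpha,
                 amova_reps = amova_reps, mismatch_reps = mismatch_reps,
                 seed = seed, route = route,
                 n_individuals = length(gt$individuals),
                 n_loci = length(gt$loci), sites = site_ids(gt))
  cfg_file <- tempfile(); on.exit(unlink(cfg_file))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), cfg_file)
  config$hash <- unname(tools::md5sum(cfg_file))

  div <- stage("diversity", diversity_summary(gt, meta, g = g,
                                              rare_thresh = rare_thresh))
  freqs <- stage("allele_frequencies", allele_frequencies(gt, "site"))
  fst <- stage("fst", pairwise_fst(gt))
  da <- stage("nei_da", nei_da(gt))
  tree <- stage("nj_tree", as.character(nj_tree(da)))
  am <- stage("amova", amova(gt, meta, reps = amova_reps, seed = seed + 101L))

  ibd_all <- stage("ibd", ibd_regression(fst, meta))
  ibd_cl <- lapply(unique(meta$cluster), function(cl) {
    tryCatch(ibd_regression(fst, meta, cluster = cl),
             error = function(e) NULL)   # clusters below 4 sites: skipped
  })
  names(ibd_cl) <- unique(meta$cluster)

  focal <- stage("focal_sites",
                 identify_focal_sites(fst, meta, route, div, alpha = alpha))
  clines <- list(); scans <- list()
  for (r in seq_len(nrow(focal))) {
    key <- paste(focal$pair[r], focal$role[r], sep = ":")
    clines[[key]] <- tryCatch(
      diversity_cline(div, fst, focal$site[r], focal$cluster[r], meta),
      error = function(e) NULL)
    scans[[key]] <- tryCatch(
      allele_cline_scan(freqs, fst, focal$site[r], focal$cluster[r], meta,
                        alpha = alpha),
      error = function(e) NULL)
  }
  r2c <- list()
  for (i in seq_len(length(route) - 1L)) {
    key <- paste(route[i], route[i + 1L], sep = "->")
    r2c[[key]] <- stage("rare_to_common",
                        rare_to_common_scan(freqs, meta, route[i],
                                            route[i + 1L], rare_thresh,
                                            common_thresh))
  }

  dloop <- NULL
  if (!is.null(hd)) {
    dloop <- stage("dloop", {
      sd <- seq_diversity(hd)
      td <- tajimas_d(hd)
      fl <- fu_li_tests(hd)
      fs <- fu_fs(hd)
      mm <- mismatch(hd)
      fit <- fit_sudden_expansion(mm, n = sd$n, reps = mismatch_reps,
                                  seed = seed + 202L)
      list(diversity = sd, tajima = td, fu_li = fl, fu_fs = fs,
           mismatch = mm, expansion_fit = fit)
    })
  }
  structure(list(config = config, diversity = div, fst = fst, nei_da = da,
                 nj_tree = tree, amova = am, ibd = ibd_all,
                 ibd_by_cluster = ibd_cl, focal_sites = focal,
                 clines = clines, allele_clines = scans,
                 rare_to_common = r2c, dloop = dloop),
            class = "surfing_report")
}

#' @export
print.surfing_report <- function(x, ...) {
  cat("surfing_report (config hash", x$config$hash, ")\n")
  cat(" route:", paste(x$config$route, collapse = " -> "), "\n")
  cat(" sites:", length(x$config$sites), " loci:", x$config$n_loci, "\n")
  cat(" IBD: R^2 =", signif(x$ibd$r_squared, 3),
      " p =", signif(x$ibd$p_value, 3), "\n")
  print(x$focal_sites)
  invisible(x)
}

#' Write a surfing report to JSON
#'
#' Serializes every stage (matrices as named arrays, data frames as
#' records) deterministically so repeated runs with the same inputs and
#' seed are byte-identical.
#'
#' @param report a `surfing_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surfing_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "fst_matrix")) x <- unclass(x)
    if (is.matrix(x)) return(list(dimnames = dimnames(x),
                                  values = unname(as.data.frame(x))))
    if (is.data.frame(x)) { attr(x, "details") <- NULL; return(x) }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  json <- jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE,
                           digits = NA, na = "null", force = TRUE)
  writeLines(json, path)
  invisible(path)
}
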