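#' Allele frequencies by site or cluster
#'
#' Tallies gene copies per group x locus and returns relative frequencies.
#' Missing calls are excluded from the denominator.  A group x locus cell
#' with zero non-missing calls yields no rows (it is undefined, not zero);
#' such cells are listed in the `undefined` attribute.
#'
#' @param gt a [genotype_table()].
#' @param by `"site"` (default) or `"cluster"`; the latter needs `meta`.
#' @param meta a [site_meta()] table (required for `by = "cluster"`).
#' @return a `data.frame` with columns `group`, `locus`, `allele`, `count`,
#'   `freq`; per group x locus the `freq` values sum to 1.
#' @export
allele_frequencies <- function(gt, by = c("site", "cluster"), meta = NULL) {
  by <- match.arg(by)
  if (by == "cluster") {
    if (is.null(meta)) stop("cluster grouping requires site metadata")
    check_sites(gt, meta)
    grp <- meta$cluster[match(gt$site, meta$site)]
  } else {
    grp <- unname(gt$site)
  }
  out <- list(); undef <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    for (l in seq_along(gt$loci)) {
      copies <- c(gt$a1[rows, l], gt$a2[rows, l])
      copies <- copies[!is.na(copies)]
      if (!length(copies)) {
        undef[[length(undef) + 1L]] <- data.frame(group = g, locus = gt$loci[l])
        next
      }
      tab <- table(copies)
      out[[length(out) + 1L]] <- data.frame(
        group = g, locus = gt$loci[l],
        allele = as.integer(names(tab)),
        count = as.integer(tab),
        freq = as.numeric(tab) / length(copies))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "undefined") <- if (length(undef)) do.call(rbind, undef) else NULL
  res
}

# frequency vector of one group x locus from an allele_frequencies table
freq_vector <- function(freqs, group, locus) {
  rows <- freqs$group == group & freqs$locus == locus
  stats::setNames(freqs$freq[rows], freqs$allele[rows])
}
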