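#' Diploid microsatellite genotype table
#'
#' A `genotype_table` stores diploid calls for a set of individuals at a set
#' of codominant loci, together with the sampling site of every individual.
#' Allele labels are positive integers (typically PCR fragment sizes or
#' repeat counts).  A call is either complete (both gene copies observed) or
#' wholly missing; half-calls are rejected because they cannot enter
#' frequency estimates.
#'
#' @param individuals character vector of unique individual ids.
#' @param loci character vector of unique locus ids.
#' @param a1,a2 integer matrices (`length(individuals)` x `length(loci)`)
#'   holding the two allele labels of each call; `NA` in both marks a missing
#'   call.  The pair is unordered: (a1, a2) and (a2, a1) are the same call.
#' @param site character vector, one sampling-site id per individual.
#' @return An object of class `genotype_table` with elements `individuals`,
#'   `loci`, `a1`, `a2`, `site`.
#' @export
genotype_table <- function(individuals, loci, a1, a2, site) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  site <- as.character(site)
  if (anyDuplicated(individuals))
    stop("duplicated individual id: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicated locus id")
  if (length(loci) < 1L) stop("at least one locus is required")
  if (nrow(a1) != length(individuals) || ncol(a1) != length(loci) ||
      any(dim(a1) != dim(a2)))
    stop("allele matrices must be individuals x loci")
  if (length(site) != length(individuals))
    stop("every individual must map to exactly one site")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing call(s) found; a call must be complete or wholly missing")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele labels must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
         site = stats::setNames(site, individuals)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals,",
      length(x$loci), "loci,", length(unique(x$site)), "sites\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype table by individuals or sites
#'
#' @param gt a [genotype_table()].
#' @param individuals individual ids to keep (default all).
#' @param sites site ids to keep (default all).
#' @return a `genotype_table` restricted to the selection.
#' @export
subset_genotypes <- function(gt, individuals = NULL, sites = NULL) {
  keep <- rep(TRUE, length(gt$individuals))
  if (!is.null(sites)) keep <- keep & gt$site %in% sites
  if (!is.null(individuals)) keep <- keep & gt$individuals %in% individuals
  if (!any(keep)) stop("selection leaves no individuals")
  genotype_table(gt$individuals[keep], gt$loci,
                 gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE],
                 gt$site[keep])
}

#' Sampling-site ids of a genotype table
#' @param gt a [genotype_table()].
#' @return character vector of distinct site ids in order of appearance.
#' @export
site_ids <- function(gt) unique(unname(gt$site))
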