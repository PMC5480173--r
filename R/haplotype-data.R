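#' Aligned haplotype data with per-site occurrence counts
#'
#' Container for an alignment of distinct haplotype sequences (equal-length
#' character strings over `A,C,G,T,-,N`) plus a haplotype-by-site matrix of
#' occurrence counts and an optional haplogroup assignment.  Statistics that
#' need per-individual sequences expand the counts; the two representations
#' are exactly equivalent for every statistic in the package.
#'
#' @param seqs character matrix (haplotypes x alignment columns) or a named
#'   character vector of equal-length strings.
#' @param counts integer matrix (haplotypes x sites) of occurrence counts;
#'   a named vector is taken as a single site named `all`.
#' @param hap_group optional named character vector mapping haplotype id to
#'   group label (e.g. `Hg1`/`Hg2`).
#' @return an object of class `haplotype_data` with elements `seqs`,
#'   `counts`, `hap_group`.
#' @export
haplotype_data <- function(seqs, counts, hap_group = NULL) {
  if (!is.matrix(seqs)) {
    nm <- names(seqs)
    seqs <- toupper(as.character(seqs))
    if (length(unique(nchar(seqs))) != 1L)
      stop("alignment error: sequences have unequal lengths")
    seqs <- do.call(rbind, strsplit(seqs, ""))
    rownames(seqs) <- nm
  } else {
    seqs <- toupper(seqs)
  }
  if (is.null(rownames(seqs)))
    rownames(seqs) <- paste0("H", seq_len(nrow(seqs)))
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("alignment contains unexpected symbol(s): ", paste(bad, collapse = ""))
  key <- apply(seqs, 1L, paste, collapse = "")
  if (anyDuplicated(key)) stop("haplotype sequences must be pairwise distinct")
  if (!is.matrix(counts)) counts <- cbind(all = counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) && nrow(counts) == nrow(seqs))
    rownames(counts) <- rownames(seqs)
  if (!setequal(rownames(counts), rownames(seqs)) ||
      nrow(counts) != nrow(seqs))
    stop("count table must cover exactly the haplotypes in the alignment")
  counts <- counts[rownames(seqs), , drop = FALSE]
  if (any(counts < 0L) || anyNA(counts))
    stop("counts must be non-negative integers")
  if (!is.null(hap_group)) {
    unknown <- setdiff(names(hap_group), rownames(seqs))
    if (length(unknown))
      stop("hap_group references unknown haplotype(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(seqs = seqs, counts = counts, hap_group = hap_group),
            class = "haplotype_data")
}

#' @export
print.haplotype_data <- function(x, ...) {
  cat("haplotype_data:", nrow(x$seqs), "haplotypes,", ncol(x$seqs),
      "aligned positions,", sum(x$counts), "individuals,",
      ncol(x$counts), "site(s)\n")
  invisible(x)
}

#' Read an aligned FASTA file as haplotype data
#'
#' Identical sequences are collapsed into haplotypes.  When a sidecar count
#' table is given (TSV with columns `haplotype`, `site`, `count`, haplotype
#' ids matching the FASTA record names), occurrence counts come from it;
#' otherwise every record contributes one individual, with its site taken
#' from a `site=<id>` token in the FASTA description (site `all` when
#' absent).
#'
#' @param path path to the FASTA alignment.
#' @param counts_path optional path to the sidecar count TSV.
#' @return a [haplotype_data()].
#' @export
read_fasta_alignment <- function(path, counts_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("alignment error: FASTA file has no records")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  mat <- toupper(as.character(as.matrix(dna)))
  headers <- rownames(mat)
  rec_id <- sub("\\s.*$", "", headers)
  rec_site <- ifelse(grepl("site=", headers),
                     sub(".*site=([^\\s]+).*", "\\1", headers), "all")

  key <- apply(mat, 1L, paste, collapse = "")
  first <- !duplicated(key)
  hap_of_rec <- match(key, key[first])
  hseqs <- mat[first, , drop = FALSE]
  hap_ids <- rec_id[first]
  if (anyDuplicated(hap_ids)) hap_ids <- make.unique(hap_ids, sep = "_")
  rownames(hseqs) <- hap_ids

  if (is.null(counts_path)) {
    sites <- sort(unique(rec_site))
    counts <- matrix(0L, nrow(hseqs), length(sites),
                     dimnames = list(hap_ids, sites))
    for (r in seq_along(rec_id))
      counts[hap_of_rec[r], rec_site[r]] <- counts[hap_of_rec[r], rec_site[r]] + 1L
  } else {
    tab <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
    need <- c("haplotype", "site", "count")
    if (!all(need %in% names(tab)))
      stop("count table must have columns ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(tab$haplotype), hap_ids)
    if (length(unknown))
      stop("count table references unknown haplotype id(s): ",
           paste(unknown, collapse = ", "))
    sites <- unique(tab$site)
    counts <- matrix(0L, nrow(hseqs), length(sites),
                     dimnames = list(hap_ids, sites))
    for (r in seq_len(nrow(tab)))
      counts[tab$haplotype[r], tab$site[r]] <-
        counts[tab$haplotype[r], tab$site[r]] + as.integer(tab$count[r])
  }
  haplotype_data(hseqs, counts)
}

#' Write haplotype data as FASTA plus a count TSV
#'
#' @param hd a [haplotype_data()].
#' @param fasta_path output FASTA path.
#' @param counts_path optional output path for the sidecar count table.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_alignment <- function(hd, fasta_path, counts_path = NULL) {
  dna <- ape::as.DNAbin(tolower(hd$seqs))
  ape::write.FASTA(dna, fasta_path)
  if (!is.null(counts_path)) {
    idx <- which(hd$counts > 0L, arr.ind = TRUE)
    tab <- data.frame(haplotype = rownames(hd$counts)[idx[, 1]],
                      site = colnames(hd$counts)[idx[, 2]],
                      count = hd$counts[idx])
    utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Restrict haplotype data to sites, haplotypes, or a haplogroup
#'
#' @param hd a [haplotype_data()].
#' @param sites site ids to keep (default all).
#' @param haplotypes haplotype ids to keep (default all).
#' @param group haplogroup label to keep (requires `hap_group`).
#' @param drop_absent drop haplotypes whose total count becomes zero
#'   (default `TRUE`).
#' @return a `haplotype_data` for the subset.
#' @export
subset_haplotypes <- function(hd, sites = NULL, haplotypes = NULL,
                              group = NULL, drop_absent = TRUE) {
  counts <- hd$counts
  if (!is.null(sites)) {
    missing <- setdiff(sites, colnames(counts))
    if (length(missing)) stop("unknown site(s): ", paste(missing, collapse = ", "))
    counts <- counts[, sites, drop = FALSE]
  }
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(haplotypes)) keep <- keep & rownames(counts) %in% haplotypes
  if (!is.null(group)) {
    if (is.null(hd$hap_group)) stop("no haplogroup assignment present")
    keep <- keep & rownames(counts) %in%
      names(hd$hap_group)[hd$hap_group == group]
  }
  if (drop_absent) keep <- keep & rowSums(counts) > 0L
  if (!any(keep)) stop("subset is empty")
  haplotype_data(hd$seqs[keep, , drop = FALSE],
                 counts[keep, , drop = FALSE],
                 if (!is.null(hd$hap_group))
                   hd$hap_group[intersect(names(hd$hap_group),
                                          rownames(counts)[keep])])
}
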