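#' Read a GenePop file into a genotype table
#'
#' Parses the classic GenePop interchange format for diploid codominant
#' data: a title line, one locus name per line (or a single comma-separated
#' line), then `POP`-delimited blocks of `id ,  aabb ccdd ...` rows.  Both
#' 2- and 3-digit allele encodings are accepted and auto-detected per file
#' from the genotype field width (4 characters = 2-digit, 6 = 3-digit).
#' An allele encoded `00`/`000` marks the whole call as missing.
#'
#' @param path path to a GenePop (.gen) file.
#' @param site_names optional character vector naming the POP blocks in file
#'   order; defaults to the label of the last individual of each block (the
#'   GenePop convention) with any trailing `_<number>` suffix stripped, so
#'   ids of the form `BX_12` yield site `BX`; falls back to `pop1..popK`
#'   when the derived labels repeat across blocks.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, site_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("GenePop parse error: file too short")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("GenePop parse error: no POP line after header (line ",
         ifelse(is.na(first_pop), "none", first_pop), ")")
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("GenePop parse error: duplicated locus name")
  L <- length(loci)

  pop_of_line <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop - 1L & nzchar(trimws(lines)))
  if (!length(body)) stop("GenePop parse error: no individuals")

  ids <- character(0); a1 <- list(); a2 <- list(); popidx <- integer(0)
  last_label <- character(max(pop_of_line))
  for (i in body) {
    ln <- lines[i]
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("GenePop parse error at line ", i, ": missing ',' separator")
    id <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != L)
      stop("GenePop parse error at line ", i, ": expected ", L,
           " genotypes, found ", length(gstr))
    w <- unique(nchar(gstr))
    if (length(w) != 1L || !w %in% c(4L, 6L))
      stop("GenePop parse error at line ", i,
           ": genotype fields must be uniformly 4 or 6 characters")
    half <- w / 2L
    x1 <- as.integer(substr(gstr, 1L, half))
    x2 <- as.integer(substr(gstr, half + 1L, w))
    if (anyNA(x1) || anyNA(x2))
      stop("GenePop parse error at line ", i, ": non-numeric allele code")
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id)
    a1[[length(a1) + 1L]] <- x1
    a2[[length(a2) + 1L]] <- x2
    popidx <- c(popidx, pop_of_line[i])
    last_label[pop_of_line[i]] <- id
  }
  npop <- max(popidx)
  if (is.null(site_names)) {
    site_names <- sub("_[0-9]+$", "", last_label[seq_len(npop)])
    if (anyDuplicated(site_names) || any(!nzchar(site_names)))
      site_names <- paste0("pop", seq_len(npop))
  }
  if (length(site_names) != npop)
    stop("site_names must have one entry per POP block (", npop, ")")
  if (anyDuplicated(ids)) {
    # disambiguate GenePop's habit of repeating the site label as the id
    ids <- make.unique(ids, sep = "_")
  }
  genotype_table(ids, loci,
                 do.call(rbind, a1), do.call(rbind, a2),
                 site_names[popidx])
}

#' Write a genotype table in GenePop format
#'
#' Individuals are grouped into one POP block per site, in the site order of
#' first appearance.  Alleles are written 3-digit (2-digit if every label is
#' below 100); missing calls become `000000`/`0000`.  Individual ids are
#' written verbatim; when ids follow the `<site>_<number>` convention (as the
#' bundled simulator's outputs do) [read_genepop()] recovers the site names
#' from the trailing label of each block, so write-then-read round-trips the
#' full table.
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "volesurf genotypes") {
  digits <- if (max(c(gt$a1, gt$a2), na.rm = TRUE) < 100L) 2L else 3L
  if (max(c(gt$a1, gt$a2), 0L, na.rm = TRUE) >= 10^digits)
    stop("allele label too large for ", digits, "-digit GenePop encoding")
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  for (s in site_ids(gt)) {
    writeLines("POP", con)
    idx <- which(gt$site == s)
    for (i in idx) {
      g <- sprintf(fmt, ifelse(is.na(gt$a1[i, ]), 0L, gt$a1[i, ]),
                   ifelse(is.na(gt$a2[i, ]), 0L, gt$a2[i, ]))
      writeLines(paste0(gt$individuals[i], " ,  ", paste(g, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
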