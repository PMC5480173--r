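#' Read sampling-site metadata
#'
#' Reads a tab-separated table with header columns `site`, `lat`, `lon`,
#' `cluster` (an optional `n_sampled` column is kept when present; any other
#' columns are ignored with a warning).  Coordinates are decimal degrees
#' (WGS84), one point per site.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `site_meta` with columns `site`, `lat`,
#'   `lon`, `cluster` (and `n_sampled` when supplied).
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("site", "lat", "lon", "cluster")
  if (!all(need %in% names(df)))
    stop("site metadata must have columns ", paste(need, collapse = ", "))
  extra <- setdiff(names(df), c(need, "n_sampled"))
  if (length(extra))
    warning("ignoring unknown metadata column(s): ",
            paste(extra, collapse = ", "))
  df <- df[, intersect(c(need, "n_sampled"), names(df)), drop = FALSE]
  site_meta(df)
}

#' Validate a site-metadata table
#'
#' @param df data.frame with columns `site`, `lat`, `lon`, `cluster` and
#'   optionally `n_sampled`.
#' @return the validated data.frame, classed `site_meta`.
#' @export
site_meta <- function(df) {
  df$site <- as.character(df$site)
  df$cluster <- as.character(df$cluster)
  if (anyDuplicated(df$site))
    stop("duplicate site id in metadata: ",
         paste(unique(df$site[duplicated(df$site)]), collapse = ", "))
  if (any(!is.finite(df$lat)) || any(abs(df$lat) > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(df$lon)) || any(abs(df$lon) > 180))
    stop("longitude out of range [-180, 180]")
  class(df) <- c("site_meta", "data.frame")
  df
}

#' Check that genotype sites and metadata agree
#'
#' @param gt a [genotype_table()].
#' @param meta a [site_meta()] table.
#' @return invisibly `TRUE`; errors when any genotyped site is absent from
#'   the metadata.
#' @export
check_sites <- function(gt, meta) {
  missing <- setdiff(site_ids(gt), meta$site)
  if (length(missing))
    stop("site(s) in genotypes but not in metadata: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

cluster_sites <- function(meta, cluster) {
  s <- meta$site[meta$cluster == cluster]
  if (!length(s)) stop("unknown cluster: ", cluster)
  s
}
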