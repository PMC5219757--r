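#' Remove binding calls whose summit falls inside blacklist intervals
#'
#' Blacklist intervals are 0-based half-open, so a summit at the interval
#' end coordinate is kept.
#'
#' @param calls [binding_calls()].
#' @param blacklist data frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]), or `NULL`/empty for no filtering.
#' @return filtered [binding_calls()].
#' @export
filter_blacklist <- function(calls, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(calls)
  bl <- GenomicRanges::GRanges(
    blacklist$chrom,
    IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end))
  pts <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$summit + 1L, width = 1L))
  hit <- GenomicRanges::countOverlaps(pts, bl) > 0
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_calls", "data.frame")
  out
}

#' Construct non-overlapping co-binding regions from pooled binding calls
#'
#' Every summit is expanded to the half-open interval
#' `[max(summit - expand_bp, 0), summit + expand_bp)`; overlapping expanded
#' intervals are merged transitively per chromosome into maximal
#' non-overlapping spans, and spans holding fewer than `min_sites` calls are
#' discarded.  Intervals that merely touch (half-open adjacency) are not
#' merged, so two summits merge exactly when they are closer than
#' `2 * expand_bp`.
#'
#' @param calls pooled [binding_calls()] from one cell type.
#' @param expand_bp half-width of the summit expansion in bp (default 50,
#'   matching ~30-50 bp ChIP-seq summit resolution; 100 gives similar
#'   module structure but merges more aggressively).
#' @param min_sites minimum number of binding calls per retained region
#'   (default 3).
#' @return an object of class `cobinding_regions`: a list with
#'   \describe{
#'     \item{regions}{data frame `region_id`, `chrom`, `start`, `end`
#'       (0-based half-open), `n_sites`, ordered by position;}
#'     \item{sites}{the retained calls with a `region_id` and a
#'       within-region `site_index` column (sites ordered by summit);}
#'     \item{n_dropped_sites}{calls lost to the `min_sites` filter;}
#'     \item{params}{the parameters used.}
#'   }
#' @export
build_cobinding_regions <- function(calls, expand_bp = 50L, min_sites = 3L) {
  if (expand_bp < 0) stop("expand_bp must be >= 0")
  if (min_sites < 1) stop("min_sites must be >= 1")
  if (nrow(calls) == 0) stop("no binding calls supplied")

  start0 <- pmax(calls$summit - expand_bp, 0L)
  end0 <- calls$summit + expand_bp  # half-open end
  # to 1-based closed for IRanges; min.gapwidth = 0 keeps the half-open
  # convention (touching intervals stay separate)
  gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  stopifnot(length(hits) == nrow(calls))
  region_of <- S4Vectors::subjectHits(hits)

  counts <- tabulate(region_of, nbins = length(merged))
  keep <- counts >= min_sites
  n_dropped <- sum(counts[!keep])

  kept <- which(keep)
  # order regions by chromosome then start
  ord <- order(as.character(GenomicRanges::seqnames(merged)[kept]),
               GenomicRanges::start(merged)[kept])
  kept <- kept[ord]
  region_id <- sprintf("R%06d", seq_along(kept))
  regions <- data.frame(
    region_id = region_id,
    chrom = as.character(GenomicRanges::seqnames(merged)[kept]),
    start = GenomicRanges::start(merged)[kept] - 1L,
    end = GenomicRanges::end(merged)[kept],
    n_sites = counts[kept],
    stringsAsFactors = FALSE
  )

  new_id <- rep(NA_character_, length(merged))
  new_id[kept] <- region_id
  sites <- as.data.frame(calls)
  sites$region_id <- new_id[region_of]
  sites <- sites[!is.na(sites$region_id), , drop = FALSE]
  sites <- sites[order(sites$region_id, sites$summit, sites$factor), ,
                 drop = FALSE]
  sites$site_index <- stats::ave(seq_len(nrow(sites)), sites$region_id,
                                 FUN = seq_along)
  rownames(sites) <- NULL

  structure(
    list(regions = regions, sites = sites, n_dropped_sites = n_dropped,
         params = list(expand_bp = expand_bp, min_sites = min_sites)),
    class = "cobinding_regions")
}

#' @export
print.cobinding_regions <- function(x, ...) {
  cat("co-binding regions:", nrow(x$regions), "regions,",
      nrow(x$sites), "sites (", x$n_dropped_sites,
      "sites dropped by min_sites filter)\n")
  invisible(x)
}

#' Build the region-TF count matrix (the topic-model corpus matrix)
#'
#' @param regions a `cobinding_regions` object.
#' @param factor_labels ordered factor vocabulary; defaults to the sorted
#'   set of factors seen in the sites.  Every site factor must appear here.
#' @return integer matrix regions x factors; row sums equal per-region site
#'   counts.
#' @export
build_region_tf_matrix <- function(regions, factor_labels = NULL) {
  sites <- regions$sites
  if (is.null(factor_labels)) factor_labels <- sort(unique(sites$factor))
  unknown <- setdiff(unique(sites$factor), factor_labels)
  if (length(unknown) > 0) {
    stop("factor label(s) not in vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  ids <- regions$regions$region_id
  m <- matrix(0L, nrow = length(ids), ncol = length(factor_labels),
              dimnames = list(ids, factor_labels))
  if (nrow(sites) > 0) {
    tab <- table(factor(sites$region_id, levels = ids),
                 factor(sites$factor, levels = factor_labels))
    m[] <- as.integer(tab)
  }
  m
}
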