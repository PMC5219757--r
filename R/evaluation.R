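#' Rediscovery of protein-protein interaction pairs by module co-membership
#'
#' An interaction pair counts as rediscovered when both factors are main
#' drivers of the same module.
#'
#' @param drivers a `module_drivers` object from [call_main_drivers()], or
#'   a plain list of per-module driver character vectors.
#' @param ppi data frame with columns `bait`, `partner` (duplicates and
#'   pair orientation collapsed).
#' @return list with `n_recovered`, logical `recovered` per unique pair,
#'   and the deduplicated `pairs`.
#' @export
ppi_rediscovery <- function(drivers, ppi) {
  if (inherits(drivers, "module_drivers")) drivers <- drivers$drivers
  pairs <- dedupe_pairs(ppi)
  if (nrow(pairs) == 0) {
    return(list(n_recovered = 0L, recovered = logical(0), pairs = pairs))
  }
  recovered <- vapply(seq_len(nrow(pairs)), function(i) {
    any(vapply(drivers, function(d) {
      pairs$bait[i] %in% d && pairs$partner[i] %in% d
    }, TRUE))
  }, TRUE)
  list(n_recovered = sum(recovered), recovered = recovered, pairs = pairs)
}

dedupe_pairs <- function(ppi) {
  if (nrow(ppi) == 0) {
    return(data.frame(bait = character(), partner = character(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(ppi$bait, ppi$partner)
  b <- pmax(ppi$bait, ppi$partner)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(bait = ppi$bait[keep], partner = ppi$partner[keep],
             stringsAsFactors = FALSE)
}

#' Permutation test for protein-interaction rediscovery
#'
#' Baits are held fixed while each partner is replaced by a factor drawn
#' uniformly from the vocabulary (self-pairs disallowed, duplicate
#' resulting pairs collapsed before counting).  The p-value uses the
#' +1-corrected Monte-Carlo estimator, so it is never 0 and lies in
#' (0, 1].
#'
#' @inheritParams ppi_rediscovery
#' @param vocabulary factor labels the permuted partners are drawn from.
#' @param n_perm number of permutations (default 200, resolving p to about
#'   the 0.05 level).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` count, and the permuted
#'   `perm_counts`.
#' @export
ppi_permutation_test <- function(drivers, ppi, vocabulary, n_perm = 200L,
                                 seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(drivers, "module_drivers")) drivers <- drivers$drivers
  observed <- ppi_rediscovery(drivers, ppi)$n_recovered

  # factor -> modules-driven incidence, for fast co-membership lookups
  memb <- vapply(drivers, function(d) vocabulary %in% d,
                 logical(length(vocabulary)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(vocabulary))
  rownames(memb) <- vocabulary
  co <- tcrossprod(memb) > 0  # V x V co-driver indicator

  pairs <- dedupe_pairs(ppi)
  baits <- pairs$bait
  set.seed(as.integer(seed))
  perm_counts <- vapply(seq_len(n_perm), function(p) {
    partners <- vapply(baits, function(bt) {
      sample(setdiff(vocabulary, bt), 1)
    }, "")
    pp <- dedupe_pairs(data.frame(bait = baits, partner = partners,
                                  stringsAsFactors = FALSE))
    in_vocab <- pp$bait %in% vocabulary
    n <- 0L
    if (any(in_vocab)) {
      n <- sum(co[cbind(pp$bait[in_vocab], pp$partner[in_vocab])])
    }
    n
  }, 0L)
  p <- (1 + sum(perm_counts >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, perm_counts = perm_counts)
}

#' Fraction of module-using regions overlapping annotation tracks
#'
#' A region is annotated by a track when it overlaps any of the track's
#' intervals by at least 1 bp (0-based half-open on both sides).  For each
#' module, the fraction is computed over the regions that use the module.
#'
#' @param regions `cobinding_regions` object or a data frame with
#'   `region_id`, `chrom`, `start`, `end`.
#' @param usage logical usage matrix (regions x modules) with region ids as
#'   rownames.
#' @param tracks named list of interval data frames (`chrom`, `start`,
#'   `end`), one per annotation label.
#' @return matrix modules x tracks of fractions (NA for unused modules).
#' @export
annotation_overlap_fractions <- function(regions, usage, tracks) {
  df <- if (is.data.frame(regions)) regions else regions$regions
  df <- df[match(rownames(usage), df$region_id), , drop = FALSE]
  if (any(is.na(df$region_id))) stop("usage rows missing from regions")
  reg <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
  overlaps <- vapply(tracks, function(tr) {
    g <- GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(start = tr$start + 1L, end = tr$end))
    GenomicRanges::countOverlaps(reg, g, minoverlap = 1L) > 0
  }, logical(length(reg)))
  if (is.null(dim(overlaps))) {
    overlaps <- matrix(overlaps, nrow = length(reg))
  }
  out <- matrix(NA_real_, ncol(usage), length(tracks),
                dimnames = list(colnames(usage), names(tracks)))
  for (k in seq_len(ncol(usage))) {
    using <- usage[, k]
    if (any(using)) out[k, ] <- colMeans(overlaps[using, , drop = FALSE])
  }
  out
}

#' Build a combined cross-cell-type corpus
#'
#' Co-binding regions are constructed independently within each cell type
#' (never merged across types) and the resulting documents are
#' concatenated; region ids are prefixed with the cell type so identical
#' coordinates in two cell types stay distinct, and each document carries
#' an origin tag.
#'
#' @param calls [binding_calls()] with a non-NA `cell_type` column.
#' @param expand_bp,min_sites region construction parameters (see
#'   [build_cobinding_regions()]).
#' @return list with `corpus` (a `tf_corpus` over the union vocabulary),
#'   `origins` (named vector region_id -> cell type), `matrix` (combined
#'   region-TF matrix), and `regions_by_type`.
#' @export
cross_celltype_corpus <- function(calls, expand_bp = 50L, min_sites = 3L) {
  if (any(is.na(calls$cell_type))) stop("calls must carry a cell_type")
  types <- unique(calls$cell_type)
  vocab <- sort(unique(calls$factor))
  per_type <- lapply(types, function(ct) {
    sub <- calls[calls$cell_type == ct, , drop = FALSE]
    class(sub) <- c("binding_calls", "data.frame")
    reg <- build_cobinding_regions(sub, expand_bp, min_sites)
    prefix <- function(id) paste(ct, id, sep = "_")
    reg$regions$region_id <- prefix(reg$regions$region_id)
    reg$sites$region_id <- prefix(reg$sites$region_id)
    reg
  })
  names(per_type) <- types
  mats <- lapply(per_type, build_region_tf_matrix, factor_labels = vocab)
  m <- do.call(rbind, mats)
  origins <- rep(types, vapply(mats, nrow, 0L))
  names(origins) <- rownames(m)
  list(corpus = corpus_from_matrix(m), origins = origins, matrix = m,
       regions_by_type = per_type)
}

#' Per-module cell-type usage fractions
#'
#' For each module, the fraction of the regions using it that originate
#' from each cell type; fractions sum to 1 per used module.
#'
#' @param usage logical usage matrix with region ids as rownames.
#' @param origins named vector region_id -> cell type (from
#'   [cross_celltype_corpus()]).
#' @return matrix modules x cell types (rows NA for unused modules).
#' @export
celltype_fractions <- function(usage, origins) {
  types <- sort(unique(origins))
  org <- origins[rownames(usage)]
  out <- matrix(NA_real_, ncol(usage), length(types),
                dimnames = list(colnames(usage), types))
  for (k in seq_len(ncol(usage))) {
    using <- usage[, k]
    if (any(using)) {
      tab <- table(factor(org[using], levels = types))
      out[k, ] <- as.numeric(tab) / sum(tab)
    }
  }
  out
}

#' Spacing histogram between two factors' binding sites
#'
#' For each anchor site, the signed distance (partner minus anchor summit)
#' to the nearest partner site on the same chromosome; anchors with no
#' partner within `window` bp are excluded.
#'
#' @param anchor,partner [binding_calls()] for the two factors.
#' @param window maximum absolute distance in bp.
#' @return list with `distances` (one per retained anchor) and `histogram`
#'   (data frame `distance`, `count`).
#' @export
motif_spacing <- function(anchor, partner, window = 100L) {
  dists <- numeric(0)
  for (ch in unique(anchor$chrom)) {
    a <- sort(anchor$summit[anchor$chrom == ch])
    b <- sort(partner$summit[partner$chrom == ch])
    if (length(b) == 0) next
    # nearest partner via binary placement in the sorted vector
    pos <- findInterval(a, b)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(b))
    d_lo <- b[lo] - a
    d_hi <- b[hi] - a
    d <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
    dists <- c(dists, d[abs(d) <= window])
  }
  tab <- table(dists)
  hist <- data.frame(distance = as.integer(names(tab)),
                     count = as.integer(tab))
  list(distances = dists, histogram = hist)
}
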