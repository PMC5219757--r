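# Independent oracles used across the suite.  These deliberately use naive
# algorithms (pairwise scans, greedy agglomeration) so they share no code
# path with the implementation they check.

# O(n^2) pairwise-overlap interval merger over expanded summits.
# Returns merged spans (0-based half-open) with per-span site counts,
# sorted by chrom then start.
brute_merge <- function(chrom, summit, expand) {
  n <- length(summit)
  start <- pmax(summit - expand, 0L)
  end <- summit + expand
  comp <- seq_len(n)
  same_chrom <- outer(chrom, chrom, "==")
  ov <- outer(start, end, "<") & t(outer(start, end, "<")) & same_chrom
  edges <- which(ov & upper.tri(ov), arr.ind = TRUE)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) comp[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  spans <- do.call(rbind, lapply(split(seq_len(n), root), function(ix) {
    data.frame(chrom = chrom[ix[1]], start = min(start[ix]),
               end = max(end[ix]), n_sites = length(ix),
               stringsAsFactors = FALSE)
  }))
  spans <- spans[order(spans$chrom, spans$start), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

# Greedy brute-force average-linkage agglomeration on a distance matrix,
# merging while the smallest average inter-cluster distance is <= cutoff.
brute_average_linkage_groups <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) { best_d <- avg; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  groups <- integer(n)
  for (g in seq_along(clusters)) groups[clusters[[g]]] <- g
  groups
}

# same-partition check up to label permutation: co-membership must agree
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# small helper: write a temporary headerless call TSV, return its path
write_call_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(rows, path)
  path
}

# bag-of-words counts of a corpus, for round-trip checks
corpus_bag <- function(corpus) {
  t(vapply(corpus$documents, function(d) {
    tabulate(d, nbins = length(corpus$vocabulary))
  }, integer(length(corpus$vocabulary))))
}
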