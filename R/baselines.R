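#' k-means clustering baseline at fixed k
#'
#' Euclidean-distance k-means on the region rows, with seeded k-means++
#' initialization and `nstart` restarts keeping the lowest total
#' within-cluster sum of squares.  Cluster centroids play the role of
#' module vectors.
#'
#' @param m region-TF count matrix.
#' @param k number of clusters (1 <= k <= distinct rows).
#' @param seed integer seed (fit is deterministic given the seed).
#' @param nstart number of restarts (default 10).
#' @param iter_max Lloyd iterations per restart.
#' @return `baseline_decomposition`: list with `method = "kmeans"`,
#'   `module_matrix` (k x V centroids), `k`, `cluster`, `inertia`.
#' @export
fit_kmeans_modules <- function(m, k, seed = 1L, nstart = 10L,
                               iter_max = 100L) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(m)) stop("k must be <= number of regions")
  m <- as.matrix(m)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- kmeanspp_init(m, k)
    fit <- suppressWarnings(
      kmeans(m, centers = centers, iter.max = iter_max,
             algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(method = "kmeans",
                 module_matrix = unname(best$centers) |>
                   `dimnames<-`(list(NULL, colnames(m))),
                 k = k, cluster = best$cluster,
                 inertia = best$tot.withinss),
            class = "baseline_decomposition")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  idx <- sample.int(n, 1)
  centers[1, ] <- m[idx, ]
  if (k > 1) {
    d2 <- rowSums((m - rep(centers[1, ], each = n))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        stop("fewer than k distinct rows; cannot place k centers")
      }
      idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- m[idx, ]
      d2 <- pmin(d2, rowSums((m - rep(centers[j, ], each = n))^2))
    }
  }
  centers
}

#' Non-negative matrix factorization baseline at fixed rank
#'
#' Frobenius-loss NMF with multiplicative updates and seeded random
#' initialization: `m ~ W H`, and the rows of H are the module vectors.
#'
#' @param m non-negative region-TF matrix.
#' @param k factorization rank.
#' @param seed integer seed.
#' @param max_iter maximum multiplicative updates (default 500).
#' @return `baseline_decomposition` with `method = "nmf"`, `module_matrix`
#'   (= H), `W`, `k`, and the Frobenius `error_trace`.
#' @export
fit_nmf_modules <- function(m, k, seed = 1L, max_iter = 500L) {
  if (k < 1) stop("k must be >= 1")
  m <- as.matrix(m)
  if (any(m < 0)) stop("NMF requires a non-negative matrix")
  n <- nrow(m); v <- ncol(m)
  set.seed(as.integer(seed))
  scale0 <- sqrt(mean(m) / k)
  W <- matrix(runif(n * k), n, k) * scale0
  H <- matrix(runif(k * v), k, v) * scale0
  eps <- 1e-10
  err <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, m)) / (crossprod(W) %*% H + eps)
    W <- W * (m %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err[it] <- sqrt(sum((m - W %*% H)^2))
  }
  structure(list(method = "nmf",
                 module_matrix = `dimnames<-`(H, list(NULL, colnames(m))),
                 W = W, k = k, error_trace = err),
            class = "baseline_decomposition")
}

#' @export
print.baseline_decomposition <- function(x, ...) {
  cat(x$method, "decomposition with k =", x$k, "modules over",
      ncol(x$module_matrix), "factors\n")
  invisible(x)
}

#' TF-TF correlation fidelity of a module decomposition
#'
#' How well a k x V module matrix preserves the pairwise TF-TF Pearson
#' correlation structure of the original region-TF matrix: the Pearson
#' correlation between the upper-triangle entries of the two TF-TF
#' correlation matrices (computed over regions and over modules,
#' respectively).  Factors with zero variance in either matrix are excluded
#' (with a warning) before comparing.
#'
#' @param original region-TF count matrix.
#' @param modules k x V module matrix over the same factor vocabulary.
#' @return a single Pearson r.
#' @export
tf_correlation_fidelity <- function(original, modules) {
  if (!identical(colnames(original), colnames(modules))) {
    stop("factor vocabularies differ between the two matrices")
  }
  sd1 <- apply(original, 2, sd)
  sd2 <- apply(modules, 2, sd)
  use <- is.finite(sd1) & sd1 > 0 & is.finite(sd2) & sd2 > 0
  if (sum(use) < 2) stop("fewer than 2 usable (non-constant) factors")
  if (any(!use)) {
    warning(sum(!use), " zero-variance factor column(s) excluded: ",
            paste(head(colnames(original)[!use], 5), collapse = ", "))
  }
  c1 <- cor(original[, use, drop = FALSE])
  c2 <- cor(modules[, use, drop = FALSE])
  ut <- upper.tri(c1)
  cor(c1[ut], c2[ut])
}

#' Cross-match two module sets by Pearson correlation
#'
#' @param a,b module matrices (k1 x V and k2 x V, same vocabulary).
#' @param threshold correlation above which a module counts as matched
#'   (default 0.5).
#' @return `match_report`: list with the full `correlation` matrix
#'   (k1 x k2), per-module best matches `best_a`/`best_b`, and logical
#'   `matched_a`/`matched_b`.
#' @export
match_modules <- function(a, b, threshold = 0.5) {
  if (!identical(colnames(a), colnames(b))) {
    stop("factor vocabularies differ between the two module sets")
  }
  r <- suppressWarnings(cor(t(a), t(b)))
  rr <- r
  rr[!is.finite(rr)] <- -Inf  # constant module vectors never match
  best_a <- apply(rr, 1, max)
  best_b <- apply(rr, 2, max)
  structure(list(correlation = r, threshold = threshold,
                 best_a = best_a, best_b = best_b,
                 matched_a = best_a > threshold,
                 matched_b = best_b > threshold),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("module match report:", sum(x$matched_a), "/", length(x$matched_a),
      "rows and", sum(x$matched_b), "/", length(x$matched_b),
      "columns matched at r >", x$threshold, "\n")
  invisible(x)
}
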