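#' Standardize a count matrix along one margin
#'
#' Each vector along the chosen margin is centered and scaled by its sample
#' standard deviation (n - 1).  Constant vectors map to all zeros rather
#' than NaN, so they can never pass a z-score cutoff.
#'
#' @param m numeric matrix.
#' @param margin 2 to standardize each column (a TF participation vector
#'   across modules, the Fig.-2-style "standardized along the columns"),
#'   1 to standardize each row (a module vector across factors).
#' @return matrix of z-scores with the same shape and dimnames.
#' @export
zscore_matrix <- function(m, margin = 2) {
  if (length(m) == 0) stop("empty matrix")
  stopifnot(margin %in% c(1, 2))
  scale_vec <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  if (margin == 2) {
    out <- apply(m, 2, scale_vec)
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  } else {
    out <- t(apply(m, 1, scale_vec))
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Call module participation of each factor
#'
#' A factor participates in a module when the z-score of its site count,
#' standardized along the factor's column (across modules), exceeds
#' `z_cut`.
#'
#' @param module_tf module-TF count matrix (modules x factors).
#' @param z_cut z-score cutoff (default 1).
#' @return logical matrix, same shape as `module_tf`.
#' @export
call_participation <- function(module_tf, z_cut = 1) {
  zscore_matrix(module_tf, margin = 2) > z_cut
}

#' Call the main drivers of each module
#'
#' A factor is a main driver of a module when the z-score of its site
#' count, standardized along the module's row (across factors), exceeds
#' `z_cut`.  Drivers are ranked by descending z-score and concatenated into
#' a module label; a module with no drivers is labeled `module_<k>`.
#'
#' @param module_tf module-TF count matrix.
#' @param z_cut z-score cutoff (default 1).
#' @param max_label maximum number of drivers in a label (default 8).
#' @return object of class `module_drivers`: list with `drivers` (list of
#'   ranked character vectors per module), `labels`, and the row `z`
#'   matrix.
#' @export
call_main_drivers <- function(module_tf, z_cut = 1, max_label = 8) {
  z <- zscore_matrix(module_tf, margin = 1)
  factors <- colnames(module_tf)
  drivers <- lapply(seq_len(nrow(z)), function(k) {
    hit <- which(z[k, ] > z_cut)
    # ties in z broken by factor name for determinism
    hit <- hit[order(-z[k, hit], factors[hit])]
    factors[hit]
  })
  labels <- vapply(seq_along(drivers), function(k) {
    if (length(drivers[[k]]) == 0) sprintf("module_%d", k)
    else paste(head(drivers[[k]], max_label), collapse = "+")
  }, "")
  names(drivers) <- names(labels) <- rownames(module_tf)
  structure(list(drivers = drivers, labels = labels, z = z),
            class = "module_drivers")
}

#' @export
print.module_drivers <- function(x, ...) {
  for (k in seq_along(x$labels)) {
    cat(names(x$labels)[k], ": ", x$labels[k], "\n", sep = "")
  }
  invisible(x)
}

#' Summarize the assignment table into a region-module count matrix
#'
#' @param assignments assignment table from [extract_outputs()].
#' @param n_modules total number of modules K; defaults to the maximum
#'   module id seen.
#' @return integer matrix regions x modules (columns `M01`...), rows in
#'   order of first appearance of each region; row sums equal region site
#'   counts.
#' @export
region_module_matrix <- function(assignments, n_modules = NULL) {
  if (is.null(n_modules)) n_modules <- max(assignments$module)
  ids <- unique(assignments$region_id)
  tab <- table(factor(assignments$region_id, levels = ids),
               factor(assignments$module, levels = seq_len(n_modules)))
  m <- matrix(as.integer(tab), nrow = length(ids),
              dimnames = list(ids, sprintf("M%02d", seq_len(n_modules))))
  m
}

#' Call which modules each region uses
#'
#' A region uses a module when (1) at least `min_sites` of the region's
#' sites are assigned to the module and (2) the z-score of that count,
#' standardized within the region across all K modules, exceeds `z_cut`.
#' With `axis = "module"` the z-score is instead standardized within each
#' module column across regions (an alternative reading of the rule; the
#' within-region default is used throughout).
#'
#' @param rmm region-module count matrix.
#' @param min_sites minimum assigned sites (default 3).
#' @param z_cut z-score cutoff (default 1).
#' @param axis `"region"` (default) or `"module"`; which margin the
#'   z-score is computed along.
#' @return logical usage matrix, regions x modules.
#' @export
call_module_usage <- function(rmm, min_sites = 3, z_cut = 1,
                              axis = c("region", "module")) {
  axis <- match.arg(axis)
  z <- zscore_matrix(rmm, margin = if (axis == "region") 1 else 2)
  (rmm >= min_sites) & (z > z_cut)
}

#' Histogram of the number of modules used per region
#'
#' @param usage logical usage matrix from [call_module_usage()].
#' @return named integer vector: counts of regions using 0, 1, 2, ...
#'   modules; the total equals the number of regions.
#' @export
multi_module_census <- function(usage) {
  n <- rowSums(usage)
  counts <- tabulate(n + 1L, nbins = max(n) + 1L)
  names(counts) <- as.character(seq_along(counts) - 1L)
  counts
}

#' Group similar modules by hierarchical clustering
#'
#' Average-linkage clustering of module rows under Pearson correlation
#' distance (1 - r), cut at height `cutoff`.
#'
#' @param module_tf module-TF count matrix.
#' @param cutoff tree-cut height (default 0.5, i.e. modules correlated
#'   above 0.5 tend to share a group).
#' @return object of class `module_groups`: list with `groups` (named
#'   integer vector module -> group) and the `hclust` record (`NULL` for a
#'   single module).
#' @export
group_modules <- function(module_tf, cutoff = 0.5) {
  K <- nrow(module_tf)
  if (K == 1) {
    return(structure(list(groups = setNames(1L, rownames(module_tf)),
                          hclust = NULL, cutoff = cutoff),
                     class = "module_groups"))
  }
  r <- suppressWarnings(cor(t(module_tf)))
  r[!is.finite(r)] <- 0  # constant module rows: treat as uncorrelated
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  groups <- cutree(hc, h = cutoff)
  structure(list(groups = groups, hclust = hc, cutoff = cutoff),
            class = "module_groups")
}

#' @export
print.module_groups <- function(x, ...) {
  cat("module groups:", length(unique(x$groups)), "groups for",
      length(x$groups), "modules (cutoff", x$cutoff, ")\n")
  invisible(x)
}

#' Principal component analysis over the module dimension
#'
#' The module-TF matrix is transposed so that factors are observations and
#' modules are variables; module columns are mean-centered (no scaling).
#' The loadings therefore live over modules (orthonormal columns) and the
#' variance-explained fractions sum to 1.
#'
#' @param module_tf module-TF count matrix (needs >= 2 factors).
#' @return list with `loadings` (modules x components), `var_explained`
#'   (fractions summing to 1), and `scores` (factors projected on the
#'   components).
#' @export
pca_modules <- function(module_tf) {
  if (ncol(module_tf) < 2) stop("need >= 2 factors for PCA")
  x <- t(module_tf)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  list(loadings = p$rotation, var_explained = v / sum(v), scores = p$x)
}
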