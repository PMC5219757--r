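#' Configuration for the synthetic binding-data generator
#'
#' The generator emits the statistical world the module analysis assumes:
#' regions anchored along one synthetic chromosome far enough apart that
#' planted regions can never merge, each region drawing its sites from one
#' or two planted module distributions.
#'
#' @param n_factors vocabulary size V (default 30).
#' @param n_modules number of planted modules K (default 6).
#' @param n_regions number of regions (default 3000).
#' @param multi_module_frac fraction of regions using two modules
#'   (default 0.2); the remainder use one.
#' @param modules_per_multi modules per multi-module region (default 2).
#' @param phi_concentration symmetric Dirichlet concentration for the
#'   planted module-over-factor distributions (default 0.05: sparse,
#'   interpretable modules).
#' @param top_factors planted distributions are truncated to their top
#'   this-many factors and renormalized (default 8).
#' @param sites_shift,sites_lambda sites per region are
#'   `sites_shift + Poisson(sites_lambda)` (defaults 3 + Pois(5), so the
#'   min-3-sites region filter never fires on planted regions).
#' @param anchor_spacing distance between region anchors in bp (default
#'   1000; must exceed `2 * (expand_bp + jitter)` so regions never merge).
#' @param jitter site summits are `anchor + Uniform(-jitter, jitter)`
#'   (default 40).  Must stay below `expand_bp`: then any two sites of a
#'   region are closer than `2 * expand_bp`, so a planted region can never
#'   split during region construction and the planted regions round-trip
#'   exactly.
#' @param expand_bp expansion used downstream, for the spacing check.
#' @param chrom synthetic chromosome name.
#' @param cell_types optional character vector of cell-type labels;
#'   regions are divided evenly among them.
#' @param celltype_bias optional K x n_types matrix of multiplicative
#'   module-usage biases per cell type (columns named by type); module
#'   draw probabilities are proportional to the bias column of the
#'   region's type.
#' @param annotation_prob probability that a region emits an interval into
#'   its modules' annotation tracks (default 0.8).
#' @param seed integer seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_factors = 30L, n_modules = 6L,
                             n_regions = 3000L, multi_module_frac = 0.2,
                             modules_per_multi = 2L,
                             phi_concentration = 0.05, top_factors = 8L,
                             sites_shift = 3L, sites_lambda = 5,
                             anchor_spacing = 1000L, jitter = 40L,
                             expand_bp = 50L, chrom = "chrS",
                             cell_types = NULL, celltype_bias = NULL,
                             annotation_prob = 0.8, seed = 1L) {
  cfg <- as.list(environment())
  if (anchor_spacing <= 2 * (expand_bp + jitter)) {
    stop("anchor_spacing must exceed 2 * (expand_bp + jitter) so planted ",
         "regions never merge")
  }
  if (jitter >= expand_bp) {
    stop("jitter must be < expand_bp so planted regions never split")
  }
  if (multi_module_frac < 0 || multi_module_frac > 1) {
    stop("multi_module_frac must be in [0, 1]")
  }
  if (modules_per_multi > n_modules) {
    stop("modules_per_multi cannot exceed n_modules")
  }
  if (top_factors > n_factors) stop("top_factors cannot exceed n_factors")
  if (sites_shift < 1) stop("sites_shift must be >= 1")
  if (!is.null(celltype_bias)) {
    stopifnot(nrow(celltype_bias) == n_modules,
              ncol(celltype_bias) == length(cell_types))
  }
  structure(cfg, class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Generate a synthetic binding-call dataset with planted module structure
#'
#' Each planted module is a sparse distribution over factors drawn from a
#' symmetric Dirichlet and truncated to its top factors.  Each region
#' draws a module set (one module, or `modules_per_multi` distinct modules
#' with equal weights for the multi-module fraction), a site count, then
#' per site a module and a factor; summits are jittered around the
#' region's anchor.  One annotation track per module receives the spans of
#' regions using that module with probability `annotation_prob`.
#' Everything is reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset`: list with `calls` ([binding_calls()],
#'   summit-sorted), `truth` (list: `phi` K x V planted distributions,
#'   `regions` data frame with anchor/modules/cell type/site count,
#'   `sites` data frame with the planted per-site module labels),
#'   `annotations` (named list of BED-style data frames), and the
#'   `config`.
#' @export
simulate_binding_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_modules; V <- config$n_factors
  factors <- sprintf("TF%02d", seq_len(V))

  phi <- t(vapply(seq_len(K), function(k) {
    p <- rdirichlet1(rep(config$phi_concentration, V))
    keep <- order(p, decreasing = TRUE)[seq_len(config$top_factors)]
    p[-keep] <- 0
    p / sum(p)
  }, numeric(V)))
  colnames(phi) <- factors
  rownames(phi) <- sprintf("planted%02d", seq_len(K))

  n <- config$n_regions
  types <- config$cell_types
  region_type <- if (is.null(types)) rep(NA_character_, n) else {
    rep(types, length.out = n)[sample.int(n)]
  }

  n_multi <- round(config$multi_module_frac * n)
  is_multi <- seq_len(n) <= n_multi  # deterministic count, random content
  module_sets <- lapply(seq_len(n), function(r) {
    prob <- rep(1, K)
    if (!is.null(config$celltype_bias) && !is.na(region_type[r])) {
      prob <- config$celltype_bias[, region_type[r]]
    }
    size <- if (is_multi[r]) config$modules_per_multi else 1L
    sort(sample.int(K, size, prob = prob))
  })

  n_sites <- config$sites_shift + rpois(n, config$sites_lambda)
  anchors <- config$anchor_spacing * seq_len(n)

  site_rows <- lapply(seq_len(n), function(r) {
    mods <- module_sets[[r]]
    m <- mods[sample.int(length(mods), n_sites[r], replace = TRUE)]
    f <- vapply(m, function(k) sample.int(V, 1, prob = phi[k, ]), 0L)
    s <- anchors[r] + sample(seq(-config$jitter, config$jitter),
                             n_sites[r], replace = TRUE)
    data.frame(region_index = r, module = m, factor = factors[f],
               summit = s, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$summit, sites$factor), , drop = FALSE]
  sites$site_index <- stats::ave(seq_len(nrow(sites)), sites$region_index,
                                 FUN = seq_along)
  rownames(sites) <- NULL
  sites$cell_type <- region_type[sites$region_index]

  calls <- binding_calls(factor = sites$factor, chrom = config$chrom,
                         summit = sites$summit,
                         cell_type = sites$cell_type)

  annotations <- lapply(seq_len(K), function(k) {
    uses <- vapply(module_sets, function(s) k %in% s, TRUE)
    emit <- uses & (runif(n) < config$annotation_prob)
    data.frame(chrom = config$chrom,
               start = anchors[emit] - config$jitter - config$expand_bp,
               end = anchors[emit] + config$jitter + config$expand_bp,
               stringsAsFactors = FALSE)
  })
  names(annotations) <- paste0("annot_", rownames(phi))

  truth_regions <- data.frame(
    region_index = seq_len(n),
    anchor = anchors,
    modules = vapply(module_sets, paste, "", collapse = "+"),
    n_modules = lengths(module_sets),
    n_sites = n_sites,
    cell_type = region_type,
    stringsAsFactors = FALSE)

  structure(list(calls = calls,
                 truth = list(phi = phi, regions = truth_regions,
                              sites = sites),
                 annotations = annotations, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset:", nrow(x$truth$regions), "regions,",
      nrow(x$calls), "sites,", x$config$n_modules, "planted modules,",
      x$config$n_factors, "factors\n")
  invisible(x)
}

#' Generate a direct/indirect co-binding dataset
#'
#' For each of `n_split` sequence-specific factors X, regions contain one
#' X site (direct with probability 1/2, carrying a motif flag) plus
#' partner sites.  Direct X sites draw partners uniformly from a dedicated
#' pool; indirect X sites draw from the direct pool with probability
#' `1 - divergence` and from a second, disjoint pool otherwise.  At
#' divergence 0 the two variants have identical partner distributions
#' (co-binding carries no signal); at divergence 1 their partner pools are
#' disjoint by construction.
#'
#' @param n_split number of split factors (default 5).
#' @param regions_per_factor regions generated per split factor
#'   (default 400).
#' @param divergence partner divergence in \[0, 1\].
#' @param partner_pool_size factors per partner pool (default 4).
#' @param partner_shift,partner_lambda partner sites per region are
#'   `partner_shift + Poisson(partner_lambda)` (defaults 2 + Pois(3), so
#'   every region holds >= 3 sites).
#' @param anchor_spacing,jitter,chrom as in [synthetic_config()].
#' @param seed integer seed.
#' @return list with `calls` (split factors carry motif flags), `truth`
#'   (per-region factor and direct/indirect class), and the parameter
#'   list.  Split factors are labeled `X1..X<n>`, partners
#'   `P001..P<2*pool*n>`.
#' @export
simulate_direct_indirect_data <- function(n_split = 5L,
                                          regions_per_factor = 400L,
                                          divergence = 1,
                                          partner_pool_size = 4L,
                                          partner_shift = 2L,
                                          partner_lambda = 3,
                                          anchor_spacing = 1000L,
                                          jitter = 40L, chrom = "chrS",
                                          seed = 1L) {
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0,1]")
  set.seed(as.integer(seed))
  xs <- paste0("X", seq_len(n_split))
  n_pool <- 2L * partner_pool_size * n_split
  partners <- sprintf("P%03d", seq_len(n_pool))
  pools <- split(partners, rep(seq_len(2L * n_split),
                               each = partner_pool_size))
  direct_pool <- pools[seq(1, 2 * n_split, by = 2)]
  indirect_pool <- pools[seq(2, 2 * n_split, by = 2)]

  n <- n_split * regions_per_factor
  region_factor <- rep(xs, each = regions_per_factor)
  direct <- runif(n) < 0.5
  anchors <- anchor_spacing * seq_len(n)

  rows <- lapply(seq_len(n), function(r) {
    f_idx <- match(region_factor[r], xs)
    np <- partner_shift + rpois(1, partner_lambda)
    from_direct <- direct[r] | (runif(np) >= divergence)
    pool_d <- direct_pool[[f_idx]]
    pool_i <- indirect_pool[[f_idx]]
    pf <- ifelse(from_direct,
                 pool_d[sample.int(length(pool_d), np, replace = TRUE)],
                 pool_i[sample.int(length(pool_i), np, replace = TRUE)])
    fac <- c(region_factor[r], pf)
    data.frame(
      region_index = r,
      factor = fac,
      summit = anchors[r] + sample(seq(-jitter, jitter), np + 1L,
                                   replace = TRUE),
      motif_present = c(direct[r], rep(NA, np)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  calls <- binding_calls(factor = df$factor, chrom = chrom,
                         summit = df$summit,
                         motif_present = df$motif_present)
  truth <- data.frame(region_index = seq_len(n), factor = region_factor,
                      direct = direct, anchor = anchors,
                      stringsAsFactors = FALSE)
  list(calls = calls, truth = truth,
       split_factors = xs,
       params = list(n_split = n_split, divergence = divergence,
                     regions_per_factor = regions_per_factor,
                     seed = seed))
}
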