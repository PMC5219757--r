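test_that("config validation catches infeasible worlds", {
  expect_error(synthetic_config(anchor_spacing = 150L), "anchor_spacing")
  expect_error(synthetic_config(jitter = 60L, expand_bp = 50L), "jitter")
  expect_error(synthetic_config(top_factors = 40L), "top_factors")
  expect_error(synthetic_config(modules_per_multi = 9L),
               "modules_per_multi")
  expect_error(synthetic_config(multi_module_frac = 1.2),
               "multi_module_frac")
})

test_that("planted regions round-trip exactly through construction", {
  cfg <- synthetic_config(n_factors = 15, n_modules = 4, n_regions = 300,
                          seed = 9)
  ds <- simulate_binding_data(cfg)
  reg <- build_cobinding_regions(ds$calls, cfg$expand_bp)
  expect_equal(nrow(reg$regions), cfg$n_regions)
  expect_equal(reg$n_dropped_sites, 0L)
  expect_equal(reg$regions$n_sites, ds$truth$regions$n_sites)
  # each built region span brackets its planted anchor
  expect_true(all(reg$regions$start < ds$truth$regions$anchor &
                    reg$regions$end > ds$truth$regions$anchor))
  # emitted site count equals the sum of drawn per-region counts
  expect_equal(nrow(ds$calls), sum(ds$truth$regions$n_sites))
  expect_true(all(ds$truth$regions$n_sites >= cfg$sites_shift))
})

test_that("zero multi-module fraction plants single-module regions", {
  cfg <- synthetic_config(n_factors = 12, n_modules = 4, n_regions = 150,
                          multi_module_frac = 0, seed = 3)
  ds <- simulate_binding_data(cfg)
  per_region <- tapply(ds$truth$sites$module,
                       ds$truth$sites$region_index,
                       function(m) length(unique(m)))
  expect_true(all(per_region == 1))
  expect_true(all(ds$truth$regions$n_modules == 1))
})

test_that("the generator is byte-reproducible from its seed", {
  cfg <- synthetic_config(n_factors = 10, n_modules = 3, n_regions = 100,
                          seed = 77)
  d1 <- simulate_binding_data(cfg)
  d2 <- simulate_binding_data(cfg)
  expect_identical(d1$calls, d2$calls)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$annotations, d2$annotations)
  d3 <- simulate_binding_data(synthetic_config(
    n_factors = 10, n_modules = 3, n_regions = 100, seed = 78))
  expect_false(identical(d1$calls, d3$calls))
})

test_that("planted phi rows are sparse normalized distributions", {
  cfg <- synthetic_config(seed = 2)
  phi <- simulate_binding_data(cfg)$truth$phi
  expect_equal(unname(rowSums(phi)), rep(1, cfg$n_modules))
  expect_true(all(rowSums(phi > 0) == cfg$top_factors))
})

test_that("annotation tracks cover only regions using the module", {
  cfg <- synthetic_config(n_factors = 12, n_modules = 3, n_regions = 200,
                          annotation_prob = 1, seed = 6)
  ds <- simulate_binding_data(cfg)
  for (k in seq_len(cfg$n_modules)) {
    tr <- ds$annotations[[k]]
    uses <- grepl(paste0("(^|\\+)", k, "($|\\+)"),
                  ds$truth$regions$modules)
    expect_equal(nrow(tr), sum(uses))
    anchors <- ds$truth$regions$anchor[uses]
    expect_true(all(tr$start < anchors & tr$end > anchors))
  }
})

test_that("cell-type bias shifts module usage between types", {
  bias <- cbind(T1 = c(10, 1, 1), T2 = c(1, 10, 10))
  cfg <- synthetic_config(n_factors = 12, n_modules = 3, n_regions = 400,
                          multi_module_frac = 0, cell_types = c("T1", "T2"),
                          celltype_bias = bias, seed = 8)
  ds <- simulate_binding_data(cfg)
  tr <- ds$truth$regions
  m1_frac_t1 <- mean(tr$modules[tr$cell_type == "T1"] == "1")
  m1_frac_t2 <- mean(tr$modules[tr$cell_type == "T2"] == "1")
  expect_gt(m1_frac_t1, 0.6)
  expect_lt(m1_frac_t2, 0.3)
})

test_that("full divergence gives disjoint partner pools by construction", {
  ds <- simulate_direct_indirect_data(n_split = 2,
                                      regions_per_factor = 80,
                                      divergence = 1, seed = 4)
  sp <- split_factors(ds$calls, ds$split_factors)
  reg <- build_cobinding_regions(sp)
  expect_equal(nrow(reg$regions), nrow(ds$truth))
  partners_of <- function(f, direct) {
    idx <- ds$truth$region_index[ds$truth$factor == f &
                                   ds$truth$direct == direct]
    ids <- reg$regions$region_id[idx]
    unique(reg$sites$factor[reg$sites$region_id %in% ids &
                              !grepl("^[di]X", reg$sites$factor)])
  }
  expect_length(intersect(partners_of("X1", TRUE),
                          partners_of("X1", FALSE)), 0)
  # at divergence 0 the pools coincide
  ds0 <- simulate_direct_indirect_data(n_split = 2,
                                       regions_per_factor = 80,
                                       divergence = 0, seed = 4)
  expect_error(simulate_direct_indirect_data(divergence = 2), "divergence")
  expect_equal(sort(unique(ds0$calls$factor[ds0$calls$factor != "X1" &
                                              ds0$calls$factor != "X2"])),
               sort(unique(grep("^P", ds0$calls$factor, value = TRUE))))
})

test_that("recovery scoring is exact for the planted solution", {
  cfg <- synthetic_config(n_factors = 12, n_modules = 3, n_regions = 200,
                          seed = 10)
  ds <- simulate_binding_data(cfg)
  truth_sites <- ds$truth$sites
  ids <- sprintf("R%06d", truth_sites$region_index)
  at <- data.frame(region_id = ids, site_index = truth_sites$site_index,
                   factor = truth_sites$factor,
                   module = truth_sites$module,
                   stringsAsFactors = FALSE)
  mtm <- t(vapply(1:3, function(k) {
    counts <- table(factor(truth_sites$factor[truth_sites$module == k],
                           levels = colnames(ds$truth$phi)))
    as.numeric(counts)
  }, numeric(ncol(ds$truth$phi))))
  colnames(mtm) <- colnames(ds$truth$phi)
  rownames(mtm) <- sprintf("M%02d", 1:3)
  sc <- score_recovery(ds$truth, mtm, at)
  expect_equal(sc$token_accuracy, 1)
  expect_gte(sc$mean_cosine, 0.95)
  expect_equal(sc$k_diff, 0)

  # invariance to module relabeling
  perm <- c(3, 1, 2)
  at2 <- at; at2$module <- match(at$module, perm)
  sc2 <- score_recovery(ds$truth, mtm[perm, ], at2)
  expect_equal(sc2$token_accuracy, sc$token_accuracy)
  expect_equal(sc2$mean_cosine, sc$mean_cosine)
})

test_that("random assignments score near chance accuracy", {
  cfg <- synthetic_config(n_factors = 12, n_modules = 4, n_regions = 300,
                          multi_module_frac = 0, seed = 12)
  ds <- simulate_binding_data(cfg)
  truth_sites <- ds$truth$sites
  set.seed(1)
  at <- data.frame(
    region_id = sprintf("R%06d", truth_sites$region_index),
    site_index = truth_sites$site_index,
    factor = truth_sites$factor,
    module = sample.int(4, nrow(truth_sites), replace = TRUE),
    stringsAsFactors = FALSE)
  mtm <- matrix(5, 4, ncol(ds$truth$phi),
                dimnames = list(sprintf("M%02d", 1:4),
                                colnames(ds$truth$phi)))
  sc <- score_recovery(ds$truth, mtm, at)
  expect_lt(abs(sc$token_accuracy - 0.25), 0.1)
})
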