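test_that("z-scores standardize with sample sd and guard constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_matrix(m, margin = 2)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_error(zscore_matrix(matrix(numeric(0), 0, 0)), "empty")

  set.seed(1)
  r <- matrix(rpois(60, 4) + runif(60), 6, 10)
  zc <- zscore_matrix(r, margin = 2)
  expect_equal(unname(colMeans(zc)), rep(0, 10))
  expect_equal(unname(apply(zc, 2, sd)), rep(1, 10))
  zr <- zscore_matrix(r, margin = 1)
  expect_equal(unname(rowMeans(zr)), rep(0, 6))
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 6))
})

test_that("participation follows the column z-score rule", {
  # a factor with all its sites in one module of 10: that cell's z is
  # (10 - 1)/sqrt(10) * ... computed directly below as the oracle
  col <- c(10, rep(0, 9))
  m <- cbind(F1 = col, F2 = rep(2, 10))
  part <- call_participation(m, z_cut = 1)
  z_expected <- (10 - mean(col)) / sd(col)
  expect_gt(z_expected, 1)
  expect_equal(unname(part[, "F1"]), c(TRUE, rep(FALSE, 9)))
  # uniform factor: constant column -> z 0 everywhere -> no calls
  expect_false(any(part[, "F2"]))
  # z_cut = -Inf calls everything
  expect_true(all(call_participation(m, z_cut = -Inf)))
})

test_that("main drivers are ranked by row z-score", {
  row1 <- c(A = 90, B = 60, setNames(rep(0, 18), paste0("F", 1:18)))
  row2 <- setNames(rep(5, 20), names(row1))
  m <- rbind(M1 = row1, M2 = row2)
  drv <- call_main_drivers(m, z_cut = 1)
  # oracle: direct row z-scores
  z1 <- (row1 - mean(row1)) / sd(row1)
  expect_equal(drv$drivers$M1, names(sort(z1[z1 > 1], decreasing = TRUE)))
  expect_equal(drv$drivers$M1, c("A", "B"))
  expect_equal(drv$labels[["M1"]], "A+B")
  # uniform module row: no drivers, fallback label
  expect_length(drv$drivers$M2, 0)
  expect_equal(drv$labels[["M2"]], "module_2")
  # driver order invariant to factor column order
  perm <- sample(ncol(m))
  drv2 <- call_main_drivers(m[, perm], z_cut = 1)
  expect_equal(drv2$drivers$M1, drv$drivers$M1)
})

test_that("a dominant-count factor can still fail the z>1 driver rule", {
  # counts (A:90, B:10, 18 zeros): B's row z is ~0.25, so A alone drives
  row <- c(A = 90, B = 10, setNames(rep(0, 18), paste0("F", 1:18)))
  m <- rbind(M1 = row, M2 = rev(row))
  drv <- call_main_drivers(m, z_cut = 1)
  expect_lt(((10 - mean(row)) / sd(row)), 1)
  expect_equal(drv$drivers$M1, "A")
})

test_that("region-module matrix summarizes the assignment table", {
  at <- data.frame(
    region_id = c("r1", "r1", "r1", "r2"),
    site_index = c(1L, 2L, 3L, 1L),
    factor = c("A", "A", "B", "C"),
    module = c(1L, 1L, 2L, 2L))
  rmm <- region_module_matrix(at, n_modules = 3)
  expect_equal(unname(rmm["r1", ]), c(2L, 1L, 0L))
  expect_equal(unname(rmm["r2", ]), c(0L, 1L, 0L))
  expect_equal(unname(rowSums(rmm)), c(3L, 1L))
  expect_identical(rmm, region_module_matrix(at, n_modules = 3))
})

test_that("module usage needs both the count and the z-score rule", {
  k10 <- function(...) {
    v <- c(...)
    matrix(c(v, rep(0, 10 - length(v))), 1, 10,
           dimnames = list("r1", sprintf("M%02d", 1:10)))
  }
  # (5,0,...,0): count >= 3 and z = (5 - 0.5)/sd > 1
  row <- k10(5)
  expect_gt((5 - mean(row)) / sd(row), 1)
  expect_equal(sum(call_module_usage(row)), 1L)
  # (2,1,0,...): count rule fails everywhere
  expect_equal(sum(call_module_usage(k10(2, 1))), 0L)
  # (3,3,3) over K=3: constant row -> z all 0 -> no usage
  m3 <- matrix(3, 1, 3, dimnames = list("r1", c("M01", "M02", "M03")))
  expect_equal(sum(call_module_usage(m3)), 0L)
})

test_that("usage calls are monotone in z_cut and min_sites", {
  set.seed(9)
  rmm <- matrix(rpois(200 * 6, 1.5), 200, 6,
                dimnames = list(sprintf("r%03d", 1:200),
                                sprintf("M%02d", 1:6)))
  base <- call_module_usage(rmm, min_sites = 3, z_cut = 1)
  expect_true(all(call_module_usage(rmm, 4, 1) <= base))
  expect_true(all(call_module_usage(rmm, 3, 1.5) <= base))
})

test_that("multi-module census counts regions by usage", {
  usage <- rbind(c(TRUE, FALSE, FALSE),
                 c(TRUE, TRUE, FALSE),
                 c(FALSE, FALSE, FALSE))
  census <- multi_module_census(usage)
  expect_equal(census, c("0" = 1L, "1" = 1L, "2" = 1L))
  expect_equal(sum(census), nrow(usage))
})

test_that("module grouping matches a brute-force average-linkage oracle", {
  base <- c(5, 1, 0, 0, 2, 0)
  m <- rbind(M1 = base, M2 = base * 3,          # distance 0 pair
             M3 = rev(base), M4 = c(0, 0, 5, 4, 0, 1))
  g <- group_modules(m, cutoff = 0.5)
  expect_equal(g$groups[["M1"]], g$groups[["M2"]])
  # anti-correlated rows (distance close to 2) split at cutoff 0.5
  expect_false(g$groups[["M1"]] == g$groups[["M3"]])

  set.seed(31)
  for (rep in 1:5) {
    mm <- matrix(rpois(6 * 8, 3) + runif(48), 6, 8,
                 dimnames = list(sprintf("M%02d", 1:6), LETTERS[1:8]))
    got <- group_modules(mm, cutoff = 0.5)$groups
    oracle <- brute_average_linkage_groups(1 - cor(t(mm)), 0.5)
    expect_true(same_partition(unname(got), oracle))
  }

  single <- m[1, , drop = FALSE]
  expect_equal(unname(group_modules(single)$groups), 1L)
})

test_that("module PCA satisfies its invariants", {
  set.seed(4)
  m <- matrix(rpois(5 * 12, 4), 5, 12,
              dimnames = list(sprintf("M%02d", 1:5), paste0("F", 1:12)))
  p <- pca_modules(m)
  expect_equal(sum(p$var_explained), 1)
  expect_true(all(p$var_explained >= 0 & p$var_explained <= 1))
  expect_equal(crossprod(p$loadings),
               diag(ncol(p$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 matrix: first component explains everything
  r1 <- outer(c(1, 2, 3), c(4, 0, 1, 2))
  dimnames(r1) <- list(paste0("M", 1:3), paste0("F", 1:4))
  expect_equal(pca_modules(r1)$var_explained[1], 1, ignore_attr = TRUE)
})

test_that("participation and driver calls survive label permutation", {
  set.seed(17)
  m <- matrix(rpois(6 * 10, 3), 6, 10,
              dimnames = list(sprintf("M%02d", 1:6), paste0("F", 1:10)))
  part <- call_participation(m)
  pr <- sample(nrow(m)); pc <- sample(ncol(m))
  expect_equal(call_participation(m[pr, pc]), part[pr, pc])
  drv <- call_main_drivers(m)
  drv2 <- call_main_drivers(m[pr, pc])
  expect_equal(drv2$drivers[rownames(m)[pr]], drv$drivers[rownames(m)[pr]])
})
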