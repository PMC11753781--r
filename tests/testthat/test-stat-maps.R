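random_maps <- function(n, dims, mean = 1, sd = 0.1) {
  lapply(seq_len(n), function(i) array(rnorm(prod(dims), mean, sd), dims))
}

test_that("identical constant groups give t = 0, p = 1 everywhere", {
  dims <- c(4, 4, 2)
  g <- lapply(1:3, function(i) array(2, dims))
  pm <- voxelwise_ttest(g, g)
  expect_true(all(pm$t == 0))
  expect_true(all(pm$p == 1))
  expect_equal(pm$df, 4)
})

test_that("swapping group labels negates t and preserves p", {
  set.seed(31)
  dims <- c(3, 3, 3)
  a <- random_maps(4, dims); b <- random_maps(4, dims, mean = 1.2)
  pm1 <- voxelwise_ttest(a, b)
  pm2 <- voxelwise_ttest(b, a)
  expect_equal(pm1$t, -pm2$t)
  expect_equal(pm1$p, pm2$p)
})

test_that("voxelwise t and p match a per-voxel t.test oracle to 1e-10", {
  set.seed(17)
  dims <- c(4, 3, 2)
  a <- random_maps(8, dims); b <- random_maps(8, dims, mean = 1.05)
  pm <- voxelwise_ttest(a, b)
  for (v in seq_len(prod(dims))) {
    xa <- vapply(a, function(m) m[v], numeric(1))
    xb <- vapply(b, function(m) m[v], numeric(1))
    tt <- t.test(xa, xb, var.equal = TRUE)
    expect_equal(pm$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pm$p[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance voxels are flagged", {
  dims <- c(2, 2, 1)
  a <- lapply(1:3, function(i) array(1, dims))
  b <- lapply(1:3, function(i) array(c(1, 2, 1, 1), dims))
  pm <- voxelwise_ttest(a, b)
  expect_equal(pm$p[1], 1)            # equal constants
  expect_equal(pm$p[2], 0)            # different constants, zero variance
  expect_true(pm$degenerate[2])
  expect_error(voxelwise_ttest(a[1], b[1]), "two maps")
  expect_error(voxelwise_ttest(a, lapply(1:3, function(i) array(1, c(2, 2, 2)))),
               "shape")
})

test_that("under the null the p < 0.05 fraction is binomially calibrated", {
  set.seed(77)
  dims <- c(10, 10, 4)
  fracs <- replicate(6, {
    pm <- voxelwise_ttest(random_maps(8, dims), random_maps(8, dims))
    mean(pm$p < 0.05)
  })
  n_tot <- 6 * prod(dims)
  expect_lt(abs(mean(fracs) - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("trilinear upsampling preserves nodes and interpolates linearly", {
  dims <- c(4, 4, 2)
  set.seed(5)
  a <- random_maps(3, dims); b <- random_maps(3, dims)
  pm <- voxelwise_ttest(a, b, voxel_spacing_mm = c(0.4, 0.4, 0.8))
  up <- upsample_pmap(pm, c(0.1, 0.1, 0.1))
  # source nodes live every 4th / 8th fine voxel
  expect_equal(up$p[seq(1, 13, by = 4), seq(1, 13, by = 4), c(1, 9)],
               pm$p, tolerance = 1e-12)
  # midpoint along x between nodes p = 0.2 and p = 0.4 must be 0.3
  pm2 <- pm
  pm2$p[] <- 0.2; pm2$p[2, 1, 1] <- 0.4
  up2 <- upsample_pmap(pm2, c(0.2, 0.4, 0.8))
  expect_equal(up2$p[2, 1, 1], 0.3)
})

test_that("upsampled values stay within their enclosing-node bounds", {
  set.seed(9)
  dims <- c(5, 4, 3)
  vols_a <- random_maps(3, dims); vols_b <- random_maps(3, dims)
  pm <- voxelwise_ttest(vols_a, vols_b, voxel_spacing_mm = c(0.4, 0.4, 0.8))
  up <- upsample_pmap(pm)
  sp <- c(0.4, 0.4, 0.8)
  d_up <- dim(up$p)
  coord <- function(i, ax) (i - 1) * 0.1 / sp[ax]
  for (v in sample(length(up$p), 200)) {
    ijk <- arrayInd(v, d_up)
    lo <- pmax(floor(c(coord(ijk[1], 1), coord(ijk[2], 2),
                       coord(ijk[3], 3)) + 1e-9) + 1, 1)
    hi <- pmin(lo + 1, dims)
    nodes <- pm$p[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    expect_gte(up$p[v], min(nodes) - 1e-9)
    expect_lte(up$p[v], max(nodes) + 1e-9)
  }
  expect_error(upsample_pmap(pm, c(0.5, 0.1, 0.1)), "<= source spacing")
})

test_that("upsampling never interpolates across the mask boundary", {
  dims <- c(4, 4, 2)
  a <- lapply(1:3, function(i) array(1 + 0.1 * i, dims))
  b <- lapply(1:3, function(i) array(1.2 - 0.1 * i, dims))
  mask <- array(TRUE, dims); mask[3, , ] <- FALSE
  pm <- voxelwise_ttest(a, b, mask = mask,
                        voxel_spacing_mm = c(0.4, 0.4, 0.8))
  up <- upsample_pmap(pm, c(0.2, 0.4, 0.8))
  # fine samples between defined nodes 2 and undefined node 3 are undefined
  expect_true(is.na(up$p[4, 1, 1]))   # x = 0.6 mm, between nodes 2 and 3
  expect_false(is.na(up$p[3, 1, 1]))  # exactly at defined node 2
})

test_that("define_vois labels 26-connected clusters with deterministic order", {
  dims <- c(8, 8, 4)
  p <- array(1, dims)
  pm <- list(p = p, t = array(0, dims), mask = array(TRUE, dims), df = 14,
             degenerate = array(FALSE, dims),
             voxel_spacing_mm = c(0.4, 0.4, 0.8))
  class(pm) <- "pvalue_map"
  expect_length(define_vois(pm), 0L)

  pm$p[2, 2, 2] <- 0.001
  one <- define_vois(pm, min_cluster = 1)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$voxel_indices), 1L)

  # two disjoint blobs: a 2x2x2 block and a diagonal-touching pair
  pm$p[] <- 1
  pm$p[1:2, 1:2, 1:2] <- 0.01           # 8 voxels
  pm$p[6, 6, 3] <- 0.01; pm$p[7, 7, 4] <- 0.01  # corner-connected pair
  vois <- define_vois(pm, min_cluster = 1)
  expect_length(vois, 2L)
  expect_equal(nrow(vois[[1]]$voxel_indices), 8L)  # largest first
  expect_equal(nrow(vois[[2]]$voxel_indices), 2L)
  expect_length(define_vois(pm, min_cluster = 3), 1L)
  expect_error(define_vois(pm, alpha = 1), "alpha")
})

test_that("voi_test agrees with the voxelwise test on single voxels", {
  set.seed(23)
  dims <- c(3, 3, 2)
  a <- random_maps(5, dims); b <- random_maps(5, dims, mean = 1.1)
  pm <- voxelwise_ttest(a, b)
  vt <- voi_test(a, b, voi(cbind(2, 2, 1)))
  expect_equal(vt$t, pm$t[2, 2, 1], tolerance = 1e-12)
  expect_equal(vt$p, pm$p[2, 2, 1], tolerance = 1e-12)

  same <- voi_test(a, a, voi(cbind(1, 1, 1)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  tab <- voi_test_table(a, b, list(voi(cbind(2, 2, 1), "x")))
  expect_named(tab, c("label", "n_voxels", "mean_a", "sem_a", "mean_b",
                      "sem_b", "t", "p"))
})
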