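test_that("Cn averaging leaves an already-symmetric map unchanged", {
  g <- make_cn_map(n = 8, axis_offset = 0, ring_radius = 70, noise_sd = 0)
  sym <- apply_cn(g$map, 8)
  expect_gt(map_correlation(g$map, sym), 0.999)
  # uniform map is unchanged for any parameters (within its support)
  u <- density_map(array(3.5, c(24, 24, 12)), 2)
  su <- apply_cn(u, 5, axis_offset = 4)
  expect_true(all(abs(su$values[attr(su, "support")] - 3.5) < 1e-9))
  expect_error(apply_cn(u, 1), "n must be")
})

test_that("a single off-axis blob symmetrized with C4 gives four quarter-height copies", {
  vox <- 2
  n <- 81
  vals <- array(0, c(n, n, 21))
  cen <- (n - 1) / 2 * vox
  xs <- (0:(n - 1)) * vox
  zs <- (0:20) * vox
  # blob at (cen + 40, cen), sd 6
  g3 <- outer(outer(exp(-(xs - cen - 40)^2 / 72), exp(-(xs - cen)^2 / 72)),
              exp(-(zs - 20)^2 / 72))
  m <- density_map(g3, vox)
  sym <- apply_cn(m, 4)
  # analytic oracle: copies at (cen+40, cen), (cen, cen+40), (cen-40, cen),
  # (cen, cen-40), each 1/4 the original height
  at <- function(map, x, y, z) {
    i <- round(x / vox) + 1; j <- round(y / vox) + 1; k <- round(z / vox) + 1
    map$values[i, j, k]
  }
  expect_equal(at(sym, cen + 40, cen, 20), 0.25, tolerance = 0.02)
  expect_equal(at(sym, cen, cen + 40, 20), 0.25, tolerance = 0.02)
  expect_equal(at(sym, cen - 40, cen, 20), 0.25, tolerance = 0.02)
  expect_equal(at(sym, cen, cen - 40, 20), 0.25, tolerance = 0.02)
  expect_lt(at(sym, cen + 28, cen + 28, 20), 0.05)  # between copies
})

test_that("Cn averaging is idempotent", {
  g <- make_cn_map(n = 9, axis_offset = 20, ring_radius = 70, noise_sd = 0.1,
                   seed = 4)
  once <- apply_cn(g$map, 9, axis_offset = 20)
  twice <- apply_cn(once, 9, axis_offset = 20)
  expect_gt(map_correlation(once, twice), 0.995)
})

test_that("map correlation matches a direct two-pass computation", {
  set.seed(41)
  a <- density_map(array(rnorm(4000), c(20, 20, 10)), 2)
  b <- density_map(array(rnorm(4000), c(20, 20, 10)), 2)
  # direct formula oracle
  av <- as.numeric(a$values); bv <- as.numeric(b$values)
  direct <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(map_correlation(a, b), direct, tolerance = 1e-10)
  expect_equal(map_correlation(a, a), 1.0)
  neg <- density_map(-a$values, 2)
  expect_equal(map_correlation(a, neg), -1.0)
  flat <- density_map(array(1, c(20, 20, 10)), 2)
  expect_error(map_correlation(a, flat), "constant")
})

test_that("symmetry search finds a full centered ring with a clear margin", {
  g <- make_cn_map(n = 12, axis_offset = 0, ring_radius = 80, noise_sd = 0)
  r <- search_symmetry(g$map, n_range = 10:14, offset_range = c(0, 30))
  expect_equal(r$best$n, 12)
  expect_lte(abs(r$best$axis_offset), 1)
  expect_false(r$low_confidence)
  agg <- tapply(r$offset_scan$correlation, r$offset_scan$n, max)
  margin <- agg[["12"]] - max(agg[names(agg) != "12"])
  expect_gt(margin, 0.2)
  # the reported best attains the maximum of its scan table
  expect_equal(r$best$correlation, max(r$offset_scan$correlation))
  expect_error(search_symmetry(g$map, offset_range = c(5, 1)), "offset_range")
})

test_that("plain search correlation agrees with apply_cn + map_correlation", {
  g <- make_cn_map(n = 10, axis_offset = 0, ring_radius = 70, noise_sd = 0)
  r <- search_symmetry(g$map, n_range = 10, offset_range = c(0, 0),
                       noise_robust = FALSE)
  direct <- map_correlation(g$map, apply_cn(g$map, 10))
  expect_equal(r$best$correlation, direct, tolerance = 0.05)
})

test_that("search result is invariant to density scale and offset", {
  g <- make_cn_map(n = 20, axis_offset = 110, patch_wedge = 150, blob_sd = 4,
                   noise_sd = 0.125, seed = 2, voxel_size = 2.5)
  r1 <- search_symmetry(g$map, n_range = 18:22, offset_range = c(100, 120))
  scaled <- density_map(3 * g$map$values + 7, g$map$voxel_size, g$map$origin)
  r2 <- search_symmetry(scaled, n_range = 18:22, offset_range = c(100, 120))
  expect_equal(r1$best$n, r2$best$n)
  expect_equal(r1$best$axis_offset, r2$best$axis_offset)
  expect_equal(r1$best$correlation, r2$best$correlation, tolerance = 1e-8)
})

test_that("an off-axis wedge patch is recovered with its axis offset", {
  g <- make_cn_map(n = 20, axis_offset = 110, patch_wedge = 90, blob_sd = 4,
                   noise_sd = 0, seed = 7, voxel_size = 2.5)
  r <- search_symmetry(g$map, n_range = 18:22, offset_range = c(90, 130))
  expect_equal(r$best$n, 20)
  expect_lte(abs(r$best$axis_offset - 110), 1)
})
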