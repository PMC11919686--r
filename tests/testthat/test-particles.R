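test_that("minimum interparticle distance is enforced greedily at 15 A", {
  tb <- particle_table(data.frame(x = c(0, 14), y = 0, z = 0))
  out <- enforce_min_distance(tb, 15)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 0)  # greedy in input order keeps the first

  g <- expand.grid(x = seq(0, 100, 20), y = seq(0, 100, 20), z = 0)
  out <- enforce_min_distance(particle_table(g), 15)
  expect_equal(nrow(out), nrow(g))
})

test_that("min-distance thinning passes the brute-force and maximality oracles", {
  set.seed(31)
  pts <- matrix(runif(3 * 3000, 0, 300), ncol = 3)
  tb <- particle_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  out <- enforce_min_distance(tb, 15)
  keep <- seq_len(nrow(pts)) %in% as.integer(rownames(out))
  chk <- check_min_dist(pts, keep, 15)
  expect_true(chk$separated)
  expect_true(chk$maximal)
  # appending duplicates of retained points changes nothing
  tb2 <- particle_table(rbind(as.data.frame(tb), as.data.frame(out)))
  out2 <- enforce_min_distance(tb2, 15)
  expect_equal(nrow(out2), nrow(out))
  expect_equal(out2$x, out$x)
})

test_that("orientation priors carry the reference z axis onto the normal", {
  tb <- particle_table(data.frame(x = 0, y = 0, z = 0,
                                  nx = c(0, 1, 0), ny = c(0, 0, 1),
                                  nz = c(1, 0, 0)))
  out <- orientations_from_normals(tb)
  expect_equal(out$euler_alpha[1], 0)
  expect_equal(out$euler_beta[1], 0)   # normal (0,0,1) -> identity
  expect_equal(out$euler_beta[2], 90)  # normal (1,0,0)
  rots <- particle_rotations(out)
  for (i in 1:3) {
    n <- c(out$nx[i], out$ny[i], out$nz[i])
    expect_lt(max(abs(rots[[i]] %*% c(0, 0, 1) - n)), 1e-6)
  }
})

test_that("orientation round trip holds for random normals", {
  set.seed(32)
  n <- matrix(rnorm(3 * 200), ncol = 3)
  n <- n / sqrt(rowSums(n^2))
  tb <- particle_table(data.frame(x = 0, y = 0, z = 0,
                                  nx = n[, 1], ny = n[, 2], nz = n[, 3]))
  out <- orientations_from_normals(tb)
  rots <- particle_rotations(out)
  err <- vapply(seq_len(nrow(n)), function(i)
    max(abs(rots[[i]] %*% c(0, 0, 1) - n[i, ])), numeric(1))
  expect_lt(max(err), 1e-6)
  # zero-length normal is a per-row error
  bad <- particle_table(data.frame(x = 0, y = 0, z = 0, nx = 0, ny = 0, nz = 0))
  expect_error(orientations_from_normals(bad), "row")
})

test_that("curvature clustering is optimal in 1-D and deterministic", {
  set.seed(33)
  v <- c(rnorm(30, 0.02, 0.002), rnorm(20, 0.06, 0.002))
  tb <- particle_table(data.frame(x = seq_along(v), y = 0, z = 0,
                                  curvedness = v))
  out <- cluster_by_curvature(tb, 2)
  # well-separated values: perfect split, ids ordered by cluster mean
  expect_equal(out$cluster_id, rep(c(1L, 2L), c(30, 20)))

  out1 <- cluster_by_curvature(tb, 1)
  expect_equal(unique(out1$cluster_id), 1L)
  expect_equal(attr(out1, "cluster_means"), mean(v))

  # k-means cost equals the dynamic-programming optimum on 50 points, k = 3
  v3 <- runif(50, 0, 0.1)
  tb3 <- particle_table(data.frame(x = seq_along(v3), y = 0, z = 0,
                                   curvedness = v3))
  out3 <- cluster_by_curvature(tb3, 3)
  expect_equal(assignment_cost(v3, out3$cluster_id), dp_kmeans_cost(v3, 3),
               tolerance = 1e-8)

  expect_warning(cluster_by_curvature(
    particle_table(data.frame(x = 1:3, y = 0, z = 0,
                              curvedness = c(0.1, 0.1, 0.2))), 3), "reduced")
})

test_that("orientation outliers are excluded against the local median direction", {
  set.seed(34)
  g <- expand.grid(x = seq(0, 200, 20), y = seq(0, 200, 20))
  tb <- particle_table(data.frame(x = g$x, y = g$y, z = 0,
                                  nx = 0, ny = 0, nz = 1))
  tb$nz[25] <- -1  # one flipped normal
  out <- filter_orientation_outliers(tb, radius = 50, max_angle = 30)
  expect_equal(attr(out, "n_removed"), 1)
  expect_false(any(out$nz < 0))

  # smoothly varying normals on a sphere surface: nothing removed at defaults
  fx <- make_shape_volume("sphere", radius = 300, voxel = 10, solid = TRUE)
  s <- extract_surface(fx$vol, "membrane")
  pt <- as_particle_table(s)
  out <- filter_orientation_outliers(pt)
  expect_equal(attr(out, "n_removed"), 0)

  # isolated particle: retained and flagged
  iso <- particle_table(data.frame(x = c(0, 1000), y = 0, z = 0,
                                   nx = 0, ny = 0, nz = c(1, -1)))
  out <- filter_orientation_outliers(iso, radius = 50, min_neighbors = 3)
  expect_equal(nrow(out), 2)
  expect_true(all(out$low_neighbors))
})

test_that("injected-flip removal fraction stays near the injected fraction", {
  set.seed(35)
  for (seed in 1:4) {
    g <- expand.grid(x = seq(0, 300, 15), y = seq(0, 300, 15))
    n <- nrow(g)
    flip <- sample(n, round(0.05 * n))
    nz <- rep(1, n); nz[flip] <- -1
    tb <- particle_table(data.frame(x = g$x, y = g$y, z = 0,
                                    nx = 0, ny = 0, nz = nz))
    out <- filter_orientation_outliers(tb, radius = 50)
    removed_frac <- attr(out, "n_removed") / n
    expect_lte(removed_frac, 0.05 + 0.01)
  }
})
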