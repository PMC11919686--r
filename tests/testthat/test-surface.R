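test_that("small components are removed strictly below the voxel threshold", {
  lab <- array(0L, c(40, 40, 40))
  lab[2:7, 2:7, 2:5] <- 1L            # 6*6*4 = 144 voxels < 150 -> removed
  lab[12:17, 12:17, 12:16] <- 1L      # 6*6*5 = 180 voxels >= 150 -> retained
  lv <- label_volume(lab, 10, c(background = 0L, membrane = 1L))
  out <- remove_small_components(lv, 150)
  expect_equal(sum(out$labels == 1L), 180)

  # exactly 149 and exactly 150
  lab <- array(0L, c(40, 40, 40))
  lab[1:149] <- 1L                     # one 26-connected run of 149 voxels
  lv <- label_volume(lab, 10, c(background = 0L, membrane = 1L))
  expect_equal(sum(remove_small_components(lv, 150)$labels), 0)
  lab[150] <- 1L
  lv <- label_volume(lab, 10, c(background = 0L, membrane = 1L))
  expect_equal(sum(remove_small_components(lv, 150)$labels == 1L), 150)
})

test_that("component filtering is per class: a small coat island inside a large membrane", {
  lab <- array(0L, c(40, 40, 40))
  lab[5:30, 5:30, 5:30] <- 1L                       # large membrane block
  lab[15:19, 15:19, 15:18] <- 2L                    # 5*5*4 = 100-voxel coat island
  ct <- c(background = 0L, membrane = 1L, coat = 2L)
  lv <- label_volume(lab, 10, ct)
  # oracle: per-class component counts
  n_mem_before <- sum(lab == 1L)
  out <- remove_small_components(lv, 150)
  expect_equal(sum(out$labels == 2L), 0)            # coat island removed
  expect_equal(sum(out$labels == 1L), n_mem_before) # membrane untouched
})

test_that("surface extraction recovers a sphere to sub-voxel accuracy", {
  fx <- make_shape_volume("sphere", radius = 400, voxel = 10, solid = TRUE)
  s <- extract_surface(fx$vol, "membrane")
  d <- sqrt((s$x - fx$center[1])^2 + (s$y - fx$center[2])^2 +
              (s$z - fx$center[3])^2)
  # solid sphere of radius 40 voxels: distances within one voxel of 400 A
  expect_gt(nrow(s), 1000)
  expect_true(all(abs(d - 400) < 10))
  expect_lt(abs(median(d) - 400), 3)
  expect_error(extract_surface(fx$vol, "coat"), "not in class_table")
})

test_that("slab normals align with the slab axis and edges are flagged", {
  fx <- make_shape_volume("slab", radius = 200, voxel = 10, thickness = 40)
  s <- extract_surface(fx$vol, "membrane", edge_margin = 50)
  inner <- !s$near_edge
  # away from the rim, normals are within 5 degrees of +-z
  ang <- acos(pmin(abs(s$nz[inner]), 1)) * 180 / pi
  expect_lt(max(ang), 5)
  # near_edge by definition: any point within the margin of a volume face
  lo <- 0; hi <- (dim(fx$vol$labels)[1] - 1) * 10
  near <- s$x < lo + 50 | s$x > hi - 50 | s$y < lo + 50 | s$y > hi - 50 |
    s$z < lo + 50 | s$z > hi - 50
  expect_equal(s$near_edge, near)
})

test_that("curvedness matches closed forms on analytic surfaces", {
  # sphere, 50 nm radius: C = 1/r = 0.020 1/nm
  fx <- make_shape_volume("sphere", radius = 500, voxel = 10)
  s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
  d <- sqrt((s$x - fx$center[1])^2 + (s$y - fx$center[2])^2 +
              (s$z - fx$center[3])^2)
  outer_face <- d > 500 - 20
  med <- median(s$curvedness[outer_face & s$reliable])
  expect_lt(abs(med / 0.020 - 1), 0.05)

  # cylinder, r = 176.8 A: C = 1/(r sqrt(2)) = 0.040 1/nm
  fx <- make_shape_volume("cylinder", radius = 176.8, voxel = 10)
  s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
  d <- sqrt((s$x - fx$center[1])^2 + (s$y - fx$center[2])^2)
  outer_face <- d > 176.8 - 20
  med <- median(s$curvedness[outer_face & s$reliable])
  expect_lt(abs(med / 0.040 - 1), 0.05)
  # one principal curvature is ~0 on a cylinder
  expect_lt(median(abs(pmin(abs(s$k1), abs(s$k2))[outer_face & s$reliable])), 0.004)

  # plane: C = 0 +- 0.002
  fx <- make_shape_volume("slab", radius = 200, voxel = 10, thickness = 40)
  s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
  expect_lt(median(abs(s$curvedness[s$reliable])), 0.002)
})

test_that("curvedness scales inversely with voxel size", {
  meds <- vapply(c(10, 20), function(vox) {
    fx <- make_shape_volume("sphere", radius = 40 * vox, voxel = vox,
                            thickness = 4 * vox)
    s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
    d <- sqrt((s$x - fx$center[1])^2 + (s$y - fx$center[2])^2 +
                (s$z - fx$center[3])^2)
    median(s$curvedness[d > 40 * vox - 2 * vox & s$reliable])
  }, numeric(1))
  # same 40-voxel sphere at twice the voxel size has half the curvedness
  expect_lt(abs(meds[1] / meds[2] - 2), 0.1)
})

test_that("curvedness is invariant under rotation of the cylinder axis", {
  meds <- vapply(c(0, 30), function(tilt) {
    fx <- make_shape_volume("cylinder", radius = 150, voxel = 10,
                            axis_tilt = tilt)
    s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
    d_ax <- cbind(s$x - fx$center[1], s$y - fx$center[2], s$z - fx$center[3])
    u <- c(sin(tilt * pi / 180), 0, cos(tilt * pi / 180))
    proj <- d_ax %*% u
    rad <- sqrt(rowSums((d_ax - proj %*% t(u))^2))
    median(s$curvedness[rad > 130 & s$reliable])
  }, numeric(1))
  expect_lt(abs(meds[2] / meds[1] - 1), 0.05)
})

test_that("sphere curvedness error shrinks as the radius-to-voxel ratio grows", {
  errs <- vapply(c(10, 20, 40), function(rvox) {
    fx <- make_shape_volume("sphere", radius = 10 * rvox, voxel = 10)
    s <- estimate_curvature(exclude_edges(extract_surface(fx$vol, "membrane")))
    d <- sqrt((s$x - fx$center[1])^2 + (s$y - fx$center[2])^2 +
                (s$z - fx$center[3])^2)
    med <- median(s$curvedness[d > 10 * rvox - 20 & s$reliable])
    abs(med / (10 / (10 * rvox)) - 1)
  }, numeric(1))
  # decreasing trend; half a percent of slack once errors reach the
  # sub-percent floor where discretization no longer dominates
  expect_true(all(diff(errs) < 0.005))
  expect_lt(errs[3], errs[1])
})
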