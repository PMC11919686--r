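# Programmatic fixtures and independent oracles shared across the test files.

# Rasterized analytic shapes in label space. `radius` in Angstrom; shells are
# `thickness` thick ending at `radius` (outer radius = radius).
make_shape_volume <- function(kind = c("sphere", "cylinder", "slab"),
                              radius = 200, voxel = 10, thickness = 40,
                              pad = 6, solid = FALSE, axis_tilt = 0) {
  kind <- match.arg(kind)
  n <- 2L * as.integer(ceiling((radius + pad * voxel) / voxel)) + 1L
  ax <- (0:(n - 1)) * voxel
  cen <- rep(ax[(n + 1) / 2], 3)
  if (kind == "sphere") {
    d <- sqrt(outer(outer((ax - cen[1])^2, (ax - cen[2])^2, "+"),
                    (ax - cen[3])^2, "+"))
  } else if (kind == "cylinder") {
    # axis through the center, tilted by axis_tilt degrees about y
    t <- axis_tilt * pi / 180
    u <- c(sin(t), 0, cos(t))  # axis direction
    px <- outer(outer(ax - cen[1], rep(1, n)), rep(1, n))
    py <- outer(outer(rep(1, n), ax - cen[2]), rep(1, n))
    pz <- outer(outer(rep(1, n), rep(1, n)), ax - cen[3])
    dot <- px * u[1] + py * u[2] + pz * u[3]
    d <- sqrt(pmax((px - dot * u[1])^2 + (py - dot * u[2])^2 +
                     (pz - dot * u[3])^2, 0))
  } else {
    d <- NULL
  }
  lab <- array(0L, c(n, n, n))
  if (kind == "slab") {
    k0 <- (n + 1) / 2
    half <- max(1L, round(thickness / 2 / voxel))
    lab[, , (k0 - half):(k0 + half)] <- 1L
  } else if (solid) {
    lab[d <= radius] <- 1L
  } else {
    lab[d <= radius & d > radius - thickness] <- 1L
  }
  list(vol = label_volume(lab, voxel, c(background = 0L, membrane = 1L)),
       center = cen, n = n)
}

# brute-force proximity oracle: any reference point within cutoff?
brute_proximal <- function(query, ref, cutoff) {
  apply(query, 1, function(p) {
    d2 <- (ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2 + (ref[, 3] - p[3])^2
    any(d2 <= cutoff^2)
  })
}

# brute-force checks for a minimum-distance thinning result
check_min_dist <- function(all_pts, keep, min_dist) {
  kept <- all_pts[keep, , drop = FALSE]
  dk <- as.matrix(dist(kept))
  diag(dk) <- Inf
  sep_ok <- all(dk >= min_dist)
  excl <- all_pts[!keep, , drop = FALSE]
  max_ok <- TRUE
  if (nrow(excl) > 0) {
    for (i in seq_len(nrow(excl))) {
      d2 <- (kept[, 1] - excl[i, 1])^2 + (kept[, 2] - excl[i, 2])^2 +
        (kept[, 3] - excl[i, 3])^2
      if (min(d2) >= min_dist^2) { max_ok <- FALSE; break }
    }
  }
  list(separated = sep_ok, maximal = max_ok)
}

# exact 1-D k-means by dynamic programming (optimal within-cluster SS)
dp_kmeans_cost <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cx <- cumsum(x)
  cx2 <- cumsum(x^2)
  ss <- function(i, j) {  # within-SS of x[i..j]
    s <- cx[j] - if (i > 1) cx[i - 1] else 0
    s2 <- cx2[j] - if (i > 1) cx2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- ss(1, j)
  if (k > 1) for (q in 2:k) for (j in q:n)
    D[q, j] <- min(vapply(q:j, function(i)
      (if (i > 1) D[q - 1, i - 1] else Inf) + ss(i, j), numeric(1)))
  D[k, n]
}

# within-cluster SS of an assignment
assignment_cost <- function(x, cl) {
  sum(vapply(unique(cl), function(g) {
    v <- x[cl == g]
    sum((v - mean(v))^2)
  }, numeric(1)))
}

# fake surface_points object for unit tests that do not need extraction
fake_surface <- function(df, voxel = 10, step = 10, edge_margin = 50) {
  for (col in c("nx", "ny", "nz"))
    if (is.null(df[[col]])) df[[col]] <- ifelse(col == "nz", 1, 0)
  if (is.null(df$near_edge)) df$near_edge <- FALSE
  if (is.null(df$area_weight)) df$area_weight <- step^2
  if (is.null(df$reliable) && !is.null(df$curvedness)) df$reliable <- TRUE
  class(df) <- c("surface_points", class(df))
  attr(df, "voxel_size") <- voxel
  attr(df, "step") <- step
  attr(df, "edge_margin") <- edge_margin
  df
}
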