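# Subtomogram-style particle preparation: minimum-spacing enforcement,
# normal-derived orientation priors, curvature clustering and local
# orientation-consensus outlier rejection.

#' Enforce a minimal interparticle distance
#'
#' Greedy thinning in input order: a particle is retained iff no previously
#' retained particle lies within `min_dist`. The retained set has all pairwise
#' distances >= `min_dist` and every excluded particle lies within `min_dist`
#' of a retained one (maximality). The default 15 Angstrom avoids excessive
#' overlap of extracted subvolumes.
#'
#' @param particles a [particle_table()].
#' @param min_dist minimal pairwise distance, Angstrom.
#' @return The retained subset of `particles`.
#' @export
enforce_min_distance <- function(particles, min_dist = 15) {
  particles <- particle_table(as.data.frame(particles))
  pts <- as.matrix(particles[, c("x", "y", "z")])
  keep <- as.logical(cpp_min_dist_filter(pts, min_dist))
  out <- particles[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# rotation matrix for ZYZ Euler angles (degrees): R = Rz(alpha) Ry(beta) Rz(gamma)
.euler_zyz_matrix <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

#' Assign orientation priors from membrane normals
#'
#' Sets ZYZ Euler angles (degrees) such that the rotation carries the
#' reference +z axis onto the particle's membrane normal:
#' `beta = acos(nz)`, `alpha = atan2(ny, nx)`. The in-plane (third) angle is
#' unconstrained by the normal; it is set to 0 by default or randomized.
#'
#' @param particles a [particle_table()] with unit-normal columns
#'   `nx`, `ny`, `nz`.
#' @param randomize_inplane randomize the third angle uniformly in
#'   `[0, 360)` degrees instead of 0.
#' @param seed seed used when `randomize_inplane = TRUE`.
#' @return The table with `euler_alpha`, `euler_beta`, `euler_gamma` set.
#' @export
orientations_from_normals <- function(particles, randomize_inplane = FALSE,
                                      seed = 1) {
  particles <- particle_table(as.data.frame(particles))
  need <- c("nx", "ny", "nz")
  if (!all(need %in% names(particles)))
    stop("particles need normal columns nx, ny, nz", call. = FALSE)
  n <- as.matrix(particles[, need])
  len <- sqrt(rowSums(n^2))
  bad <- which(!is.finite(len) | len < 1e-8)
  if (length(bad))
    stop("zero-length normal in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  n <- n / len
  particles$euler_beta <- acos(pmin(pmax(n[, 3], -1), 1)) * 180 / pi
  particles$euler_alpha <- ifelse(abs(n[, 1]) + abs(n[, 2]) < 1e-12, 0,
                                  atan2(n[, 2], n[, 1]) * 180 / pi)
  particles$euler_gamma <- if (randomize_inplane)
    .with_seed(seed, runif(nrow(particles), 0, 360)) else 0
  particles
}

#' Rotation matrices from particle Euler angles
#'
#' Returns the 3x3 rotation matrix (ZYZ convention) for each row; applying it
#' to `c(0, 0, 1)` reproduces the orientation prior's normal.
#'
#' @param particles a [particle_table()] with Euler angle columns.
#' @return List of 3x3 matrices.
#' @export
particle_rotations <- function(particles) {
  lapply(seq_len(nrow(particles)), function(i)
    .euler_zyz_matrix(particles$euler_alpha[i], particles$euler_beta[i],
                      particles$euler_gamma[i]))
}

# normals implied by the stored ZYZ angles (third column of R)
.normals_from_angles <- function(particles) {
  a <- particles$euler_alpha * pi / 180
  b <- particles$euler_beta * pi / 180
  cbind(cos(a) * sin(b), sin(a) * sin(b), cos(b))
}

#' Cluster particles by membrane curvedness
#'
#' 1-D k-means partition of the curvedness values (within-cluster squared
#' deviation minimized); cluster ids are relabeled in order of ascending
#' cluster mean so the labeling is deterministic.
#'
#' @param particles a [particle_table()] with a `curvedness` column.
#' @param k number of clusters (>= 1).
#' @param seed RNG seed for the k-means starts.
#' @param nstart number of random starts.
#' @return The table with `cluster_id` set; cluster means in attribute
#'   `cluster_means`.
#' @export
cluster_by_curvature <- function(particles, k, seed = 1, nstart = 25) {
  particles <- particle_table(as.data.frame(particles))
  if (is.null(particles$curvedness) || any(!is.finite(particles$curvedness)))
    stop("particles need finite curvedness values", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  v <- particles$curvedness
  ndist <- length(unique(v))
  if (k > ndist) {
    warning("k reduced from ", k, " to ", ndist, " (number of distinct values)")
    k <- ndist
  }
  if (k == 1) {
    particles$cluster_id <- 1L
    attr(particles, "cluster_means") <- mean(v)
    return(particles)
  }
  km <- .with_seed(seed, kmeans(v, centers = k, nstart = nstart, iter.max = 100))
  ord <- order(km$centers)
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  particles$cluster_id <- relab[km$cluster]
  attr(particles, "cluster_means") <- as.numeric(km$centers[ord])
  attr(particles, "cluster_withinss") <- sum(km$withinss)
  particles
}

#' Exclude particles whose orientation diverges from their neighborhood
#'
#' For each particle, the consensus direction of its neighbors within
#' `radius` is the component-wise median of their normals, renormalized. A
#' particle is excluded when its own normal deviates from the consensus by
#' more than `max_angle`. Particles with fewer than `min_neighbors` neighbors
#' are retained and flagged (`low_neighbors`).
#'
#' @param particles a [particle_table()] with normals (`nx, ny, nz`) or Euler
#'   angles from which normals are reconstructed.
#' @param radius neighborhood radius, Angstrom.
#' @param max_angle maximal deviation from the consensus direction, degrees.
#' @param min_neighbors minimal neighbor count for the consensus to apply.
#' @return The retained table with a `low_neighbors` flag column; the number
#'   removed in attribute `n_removed`.
#' @export
filter_orientation_outliers <- function(particles, radius = 100, max_angle = 30,
                                        min_neighbors = 3) {
  particles <- particle_table(as.data.frame(particles))
  if (all(c("nx", "ny", "nz") %in% names(particles))) {
    nrm <- as.matrix(particles[, c("nx", "ny", "nz")])
  } else if (all(c("euler_alpha", "euler_beta") %in% names(particles))) {
    nrm <- .normals_from_angles(particles)
  } else stop("particles need normals or Euler angles", call. = FALSE)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  pts <- as.matrix(particles[, c("x", "y", "z")])
  med <- cpp_median_normal(pts, nrm, radius)
  nn <- med[, 4]
  cosang <- rowSums(nrm * med[, 1:3])
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  low <- nn < min_neighbors
  keep <- low | (is.finite(ang) & ang <= max_angle)
  out <- particles[keep, , drop = FALSE]
  out$low_neighbors <- low[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
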