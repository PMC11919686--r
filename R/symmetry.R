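# Cyclic-symmetry determination by self-correlation maximization: the map is
# compared with symmetry-averaged versions of itself over symmetry order n,
# axis offset along x, and rotation about the axis; the parameters maximizing
# the correlation are reported.

.map_center <- function(map) {
  map$origin + (dim(map$values) - 1) / 2 * map$voxel_size
}

#' Apply Cn symmetry to a density map
#'
#' Averages the `n` copies of the input rotated by `rotation + k * 360/n`
#' (k = 0..n-1) about the axis parallel to z at
#' `(center_x + axis_offset, center_y)`, with trilinear interpolation. Voxels
#' whose pre-image falls outside the grid under any of the rotations are
#' excluded via the support mask (attribute `support`; excluded voxels are
#' written as 0).
#'
#' @param map a [density_map()].
#' @param n symmetry order (>= 2).
#' @param axis_offset axis offset along x from the map center, Angstrom.
#' @param rotation global rotation offset, degrees.
#' @return The symmetrized [density_map()] with a logical `support` attribute.
#' @export
apply_cn <- function(map, n, axis_offset = 0, rotation = 0) {
  stopifnot(inherits(map, "density_map"))
  if (!is.numeric(n) || n < 2) stop("symmetry order n must be >= 2", call. = FALSE)
  cen <- .map_center(map)
  res <- cpp_apply_cn(as.numeric(map$values), dim(map$values), map$voxel_size,
                      map$origin, as.integer(n), cen[1] + axis_offset, cen[2],
                      rotation)
  vals <- array(res$values, dim(map$values))
  support <- array(res$support, dim(map$values))
  vals[!support] <- 0
  out <- density_map(vals, map$voxel_size, map$origin)
  attr(out, "support") <- support
  out
}

#' Rotate a map about the z axis through its center
#'
#' @param map a [density_map()].
#' @param degrees rotation angle.
#' @return The rotated [density_map()] (out-of-grid regions 0, support mask
#'   attached).
#' @export
rotate_map_z <- function(map, degrees) {
  stopifnot(inherits(map, "density_map"))
  cen <- .map_center(map)
  res <- cpp_rotate_z(as.numeric(map$values), dim(map$values), map$voxel_size,
                      map$origin, degrees, cen[1], cen[2])
  vals <- array(res$values, dim(map$values))
  support <- array(res$support, dim(map$values))
  vals[!support] <- 0
  out <- density_map(vals, map$voxel_size, map$origin)
  attr(out, "support") <- support
  out
}

#' Pearson correlation between two maps
#'
#' Computed over the voxels where `mask` is true, intersected with the
#' support masks of both maps (attached by [apply_cn()]) when present.
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @param mask optional logical array.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
map_correlation <- function(map_a, map_b, mask = NULL) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop("maps must share identical grids", call. = FALSE)
  m <- rep(TRUE, length(map_a$values))
  if (!is.null(mask)) m <- m & as.logical(mask)
  for (s in list(attr(map_a, "support"), attr(map_b, "support")))
    if (!is.null(s)) m <- m & as.logical(s)
  a <- as.numeric(map_a$values)[m]
  b <- as.numeric(map_b$values)[m]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined: map constant within mask", call. = FALSE)
  stats::cor(a, b)
}

# circularly interpolated lookup of an autocovariance vector at real lags
.acov_at <- function(acov, lags) {
  n <- length(acov)
  l <- lags %% n
  i0 <- floor(l)
  f <- l - i0
  a0 <- acov[(i0 %% n) + 1]
  a1 <- acov[((i0 + 1) %% n) + 1]
  a0 * (1 - f) + a1 * f
}

# Pearson correlation between the map and its Cn-symmetrized copy over the
# full cylindrical domain, from the azimuthal autocovariance:
# corr = sqrt(mean_k R(k * ntheta/n) / R(0)), a consequence of
# Cov(C, S_n) = Var(S_n) for the circular-shift average S_n. Matches
# map_correlation(map, apply_cn(map, ...)) up to discretization; used by the
# noise_robust = FALSE search path.
.corr_from_acov <- function(acov, n, robust = FALSE) {
  ntheta <- length(acov)
  if (acov[1] <= 0) return(0)
  lags <- (seq_len(n) - 1) * ntheta / n
  sqrt(max(mean(.acov_at(acov, lags)), 0) / acov[1])
}

#' Search cyclic symmetry parameters of a map
#'
#' Two-stage search mirroring subtomogram practice: first a translational scan
#' of the symmetry-axis offset along x (1-Angstrom steps by default) for each
#' candidate order n, maximizing the correlation of the map with its
#' Cn-symmetrized copy; then, at the best (n, offset), a rotational scan.
#'
#' The score is a weighted Pearson correlation between the map and the
#' average of its symmetry copies, evaluated on a cylindrical resampling
#' about the candidate axis (annulus-area weighting; samples outside the grid
#' count as zero density, valid when the particle is fully contained in the
#' box). The axisymmetric component (per-ring azimuthal mean) is removed
#' first: it is invariant under every candidate symmetry and carries no
#' information. In the default noise-robust mode the identity copy is
#' excluded from the average (it carries the full voxel noise and would bias
#' the score toward small n) and the correlation is restricted to a
#' data-driven mask: rings with residual variance above twice the median
#' (excluding empty solvent) and azimuths holding signal energy (so an
#' off-axis patch covering only part of the ring is compared where it has
#' data).
#'
#' @param map a [density_map()] with the ring axis parallel to z and the patch
#'   along +x (use [rotate_map_z()] to pre-align).
#' @param n_range candidate symmetry orders, e.g. `18:22`.
#' @param offset_range numeric length-2: axis-offset search interval along x,
#'   Angstrom; defaults to `c(0, half x extent)`.
#' @param offset_step offset scan step, Angstrom.
#' @param rotation_step rotation scan step, degrees.
#' @param ntheta azimuthal samples of the cylindrical resampling.
#' @param z_range optional physical z interval to include (defaults to all).
#' @param min_correlation best correlations below this raise the
#'   `low_confidence` flag (e.g. the true order lies outside `n_range`).
#' @param noise_robust use the masked, identity-excluded score (recommended
#'   for noisy data and patches). Set `FALSE` for the plain Pearson
#'   correlation between the map and its full symmetrized copy over the whole
#'   cylindrical domain, which matches [map_correlation()] of the map with
#'   [apply_cn()] up to discretization.
#' @return A `symmetry_result` list: `best` (n, axis_offset, rotation,
#'   correlation), `offset_scan` and `rotation_scan` tables, `low_confidence`,
#'   and the search parameters.
#' @export
search_symmetry <- function(map, n_range = 18:22, offset_range = NULL,
                            offset_step = 1.0, rotation_step = 0.5,
                            ntheta = 360, z_range = NULL,
                            min_correlation = 0.5, noise_robust = TRUE) {
  stopifnot(inherits(map, "density_map"))
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 2)) stop("symmetry orders must be >= 2", call. = FALSE)
  d <- dim(map$values)
  cen <- .map_center(map)
  if (is.null(offset_range))
    offset_range <- c(0, (d[1] - 1) / 2 * map$voxel_size * 0.9)
  if (length(offset_range) != 2 || offset_range[2] < offset_range[1])
    stop("`offset_range` must be c(lo, hi) with lo <= hi", call. = FALSE)
  offsets <- seq(offset_range[1], offset_range[2], by = offset_step)
  if (!length(offsets)) stop("empty offset range", call. = FALSE)
  # remove the ambient level so that out-of-grid zero padding matches the
  # background; makes the search invariant to a global additive offset
  vals <- as.numeric(map$values) - median(map$values)
  zs <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel_size
  z_idx <- if (is.null(z_range)) seq_len(d[3]) - 1L else
    which(zs >= z_range[1] & zs <= z_range[2]) - 1L
  if (!length(z_idx)) stop("empty z range", call. = FALSE)
  dr <- map$voxel_size
  scan <- matrix(NA_real_, length(offsets), length(n_range),
                 dimnames = list(NULL, paste0("C", n_range)))
  geom <- function(off) {
    ax <- cen[1] + off
    xc <- map$origin[1] + c(0, d[1] - 1) * map$voxel_size
    yc <- map$origin[2] + c(0, d[2] - 1) * map$voxel_size
    # cover every radius from the axis to the farthest xy grid corner
    rmax <- sqrt(max(outer((xc - ax)^2, (yc - cen[2])^2, "+")))
    list(ax = ax, nr = max(2L, as.integer(ceiling(rmax / dr))))
  }
  for (io in seq_along(offsets)) {
    g <- geom(offsets[io])
    if (noise_robust) {
      scan[io, ] <- cpp_cyl_symscore(vals, d, map$voxel_size,
                                     map$origin, g$ax, cen[2], dr, g$nr,
                                     as.integer(ntheta), as.integer(z_idx),
                                     as.integer(n_range), 0.0, TRUE, 1.0, 0.15)
    } else {
      cy <- cpp_cyl_autocov(vals, d, map$voxel_size,
                            map$origin, g$ax, cen[2], dr, g$nr,
                            as.integer(ntheta), as.integer(z_idx), FALSE, 2.0)
      for (im in seq_along(n_range))
        scan[io, im] <- .corr_from_acov(cy$acov, n_range[im], robust = FALSE)
    }
  }
  ibest <- arrayInd(which.max(scan), dim(scan))
  best_n <- n_range[ibest[2]]
  best_off <- offsets[ibest[1]]
  # rotational scan at the best (n, offset)
  rots <- seq(0, 360 / best_n - rotation_step, by = rotation_step)
  g <- geom(best_off)
  if (noise_robust) {
    rot_corr <- vapply(rots, function(rho) {
      cpp_cyl_symscore(vals, d, map$voxel_size, map$origin,
                       g$ax, cen[2], dr, g$nr, as.integer(ntheta),
                       as.integer(z_idx), as.integer(best_n), rho,
                       TRUE, 1.0, 0.15)[1]
    }, numeric(1))
  } else {
    cy <- cpp_cyl_autocov(vals, d, map$voxel_size,
                          map$origin, g$ax, cen[2], dr, g$nr,
                          as.integer(ntheta), as.integer(z_idx), FALSE, 2.0)
    Delta <- ntheta / best_n
    varS <- max(mean(.acov_at(cy$acov, (seq_len(best_n) - 1) * Delta)), 1e-300)
    rot_corr <- vapply(rots, function(rho) {
      lag0 <- rho / 360 * ntheta
      mean(.acov_at(cy$acov, lag0 + (seq_len(best_n) - 1) * Delta)) /
        sqrt(cy$acov[1] * varS)
    }, numeric(1))
  }
  irot <- which.max(rot_corr)
  offset_scan <- data.frame(offset = rep(offsets, length(n_range)),
                            n = rep(n_range, each = length(offsets)),
                            correlation = as.vector(scan))
  out <- list(best = list(n = best_n, axis_offset = best_off,
                          rotation = rots[irot],
                          correlation = unname(scan[ibest[1], ibest[2]])),
              offset_scan = offset_scan,
              rotation_scan = data.frame(rotation = rots, correlation = rot_corr),
              low_confidence = scan[ibest[1], ibest[2]] < min_correlation,
              params = list(n_range = n_range, offset_step = offset_step,
                            rotation_step = rotation_step, ntheta = ntheta,
                            mask = "cylindrical domain, zero-padded outside grid",
                            min_correlation = min_correlation))
  class(out) <- "symmetry_result"
  out
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("<symmetry_result> best C%d at axis offset %.1f A, rotation %.1f deg (corr %.3f)%s\n",
              x$best$n, x$best$axis_offset, x$best$rotation, x$best$correlation,
              if (x$low_confidence) "  [LOW CONFIDENCE]" else ""))
  agg <- tapply(x$offset_scan$correlation, x$offset_scan$n, max)
  for (nm in names(agg))
    cat(sprintf("  C%-3s best correlation %.3f\n", nm, agg[[nm]]))
  invisible(x)
}

#' Write symmetry scan tables as TSV
#' @param result a `symmetry_result`.
#' @param path output path (offset scan; rotation scan goes to
#'   `<path>.rotation.tsv`).
#' @export
write_symmetry_tsv <- function(result, path) {
  stopifnot(inherits(result, "symmetry_result"))
  write.table(result$offset_scan, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$rotation_scan, paste0(path, ".rotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
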