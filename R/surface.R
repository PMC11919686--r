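# Membrane surface extraction and curvature estimation from label volumes.
#
# Surfaces are represented as point sets on the 0.5 level of the Gaussian-
# smoothed class mask: boundary voxels seed the set and each seed is moved
# along the local field gradient to the level crossing by bisection, giving
# sub-voxel positions. Normals are the (negated, i.e. outward) normalized
# field gradient; for closed components this orients them away from the
# enclosed interior automatically.

#' Remove small connected components per class
#'
#' For each non-background class independently, connected components (26-
#' connectivity by default) with fewer than `min_voxels` voxels are reset to
#' background. The threshold is strict: components of exactly `min_voxels`
#' survive.
#'
#' @param vol a [label_volume()].
#' @param min_voxels minimal surviving component size in voxels.
#' @param connectivity 6 or 26.
#' @return The cleaned [label_volume()].
#' @export
remove_small_components <- function(vol, min_voxels = 150, connectivity = 26) {
  stopifnot(inherits(vol, "label_volume"))
  lab <- vol$labels
  for (nm in setdiff(names(vol$class_table), "background")) {
    cl <- vol$class_table[[nm]]
    mask <- array(0L, dim(lab))
    mask[lab == cl] <- 1L
    if (!any(mask == 1L)) next
    comp <- cpp_label_components(mask, dim(lab), as.integer(connectivity))
    counts <- tabulate(comp)
    small <- which(counts < min_voxels)
    if (length(small)) {
      drop <- array(comp, dim(lab)) %in% small & mask == 1L
      lab[drop] <- 0L
    }
  }
  label_volume(lab, vol$voxel_size, vol$class_table, vol$origin)
}

# trilinear sample of `field` (array) at fractional 0-based index positions
.sample_field <- function(field, idx) {
  cpp_trilinear(as.numeric(field), dim(field), idx, NA_real_)
}

# central-difference gradient of the field at fractional index positions
.sample_gradient <- function(field, idx, h = 0.5) {
  g <- matrix(NA_real_, nrow(idx), 3)
  for (a in 1:3) {
    lo <- idx; hi <- idx
    lo[, a] <- lo[, a] - h
    hi[, a] <- hi[, a] + h
    g[, a] <- (.sample_field(field, hi) - .sample_field(field, lo)) / (2 * h)
  }
  g
}

#' Extract a class surface as an oriented point set
#'
#' Samples the 0.5 isolevel of the Gaussian-smoothed binary mask of
#' `class_name`. Boundary voxels seed the point set; each point is refined to
#' the level crossing along its normal by bisection and carries the outward
#' unit normal (away from the component interior), an area weight, and a
#' `near_edge` flag for points within `edge_margin` of any volume face.
#'
#' @param vol a [label_volume()].
#' @param class_name class to extract (e.g. "membrane").
#' @param step target point spacing, Angstrom; defaults to the voxel size.
#'   Larger values thin the set to approximately uniform spacing.
#' @param edge_margin distance to a volume face (Angstrom) below which a point
#'   is flagged `near_edge`.
#' @param smooth_sigma Gaussian smoothing of the mask, voxels.
#' @return A `surface_points` data frame: `x, y, z` (Angstrom), `nx, ny, nz`
#'   (unit outward normal), `area_weight` (Angstrom^2), `near_edge`;
#'   curvature columns are added by [estimate_curvature()].
#' @export
extract_surface <- function(vol, class_name = "membrane", step = NULL,
                            edge_margin = 50, smooth_sigma = 1) {
  stopifnot(inherits(vol, "label_volume"))
  mask <- class_mask(vol, class_name)
  if (!any(mask == 1L))
    stop("class '", class_name, "' has no voxels (empty-set error)", call. = FALSE)
  if (is.null(step)) step <- vol$voxel_size
  field <- array(cpp_blur3(as.numeric(mask), dim(mask), smooth_sigma), dim(mask))
  seeds <- cpp_boundary_voxels(mask, dim(mask))
  idx <- matrix(as.numeric(seeds), ncol = 3)
  g <- .sample_gradient(field, idx)
  gn <- sqrt(rowSums(g^2))
  ok <- is.finite(gn) & gn > 1e-8
  idx <- idx[ok, , drop = FALSE]
  nrm <- -g[ok, , drop = FALSE] / gn[ok]          # outward: field decreases outward
  # bracket the 0.5 crossing along the normal, then bisect
  tlo <- rep(-2, nrow(idx)); thi <- rep(2, nrow(idx))
  f_at <- function(t) .sample_field(field, idx + nrm * t)
  flo <- f_at(tlo); fhi <- f_at(thi)
  br <- is.finite(flo) & is.finite(fhi) & flo >= 0.5 & fhi <= 0.5
  idx <- idx[br, , drop = FALSE]; nrm <- nrm[br, , drop = FALSE]
  tlo <- tlo[br]; thi <- thi[br]
  for (it in 1:30) {
    tm <- (tlo + thi) / 2
    fm <- .sample_field(field, idx + nrm * tm)
    up <- !is.na(fm) & fm >= 0.5
    tlo[up] <- tm[up]
    thi[!up] <- tm[!up]
  }
  idx <- idx + nrm * ((tlo + thi) / 2)
  # recompute normals at the refined positions
  g <- .sample_gradient(field, idx)
  gn <- sqrt(rowSums(g^2))
  ok <- is.finite(gn) & gn > 1e-8
  idx <- idx[ok, , drop = FALSE]
  nrm <- -g[ok, , drop = FALSE] / gn[ok]
  pts <- voxel_to_phys(idx, vol$voxel_size, vol$origin)
  if (step > vol$voxel_size) {
    keep <- cpp_min_dist_filter(pts, 0.9 * step)
    pts <- pts[keep, , drop = FALSE]
    nrm <- nrm[keep, , drop = FALSE]
  }
  lo <- vol$origin
  hi <- vol$origin + (dim(mask) - 1) * vol$voxel_size
  near_edge <- rep(FALSE, nrow(pts))
  for (a in 1:3)
    near_edge <- near_edge | pts[, a] - lo[a] < edge_margin | hi[a] - pts[, a] < edge_margin
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                    area_weight = rep(step^2, nrow(pts)),
                    near_edge = near_edge)
  class(out) <- c("surface_points", class(out))
  attr(out, "voxel_size") <- vol$voxel_size
  attr(out, "step") <- step
  attr(out, "edge_margin") <- edge_margin
  out
}

#' Estimate principal curvatures and curvedness per surface point
#'
#' Fits a quadric height function (Monge patch) over the neighbors of each
#' point in its normal-aligned local frame and takes the principal curvatures
#' from the shape operator of the fit. Curvedness is
#' `sqrt((k1^2 + k2^2)/2)`, reported in 1/nm. Points with fewer than
#' `min_neighbors` neighbors are flagged unreliable (`reliable = FALSE`,
#' curvature NA) and are excluded from downstream binning.
#'
#' @param surface a `surface_points` data frame from [extract_surface()].
#' @param neighborhood_radius fit neighborhood radius, Angstrom; defaults to
#'   4.5 x the point spacing (large enough to average out voxelization noise
#'   while the normal gate keeps opposite shell faces apart).
#' @param min_neighbors minimal neighbor count (self excluded) for a reliable
#'   fit.
#' @param min_normal_dot neighbors whose normal's dot product with the center
#'   point's normal is at or below this value are excluded from the fit, so
#'   the two faces of a thin membrane shell never mix in one neighborhood.
#' @return The input with columns `k1`, `k2` (1/nm, `k1 >= k2`), `curvedness`
#'   (1/nm) and `reliable` added.
#' @export
estimate_curvature <- function(surface, neighborhood_radius = NULL,
                               min_neighbors = 6, min_normal_dot = 0.2) {
  stopifnot(inherits(surface, "surface_points"))
  step <- attr(surface, "step")
  if (is.null(neighborhood_radius)) neighborhood_radius <- 4.5 * step
  pts <- as.matrix(surface[, c("x", "y", "z")])
  nrm <- as.matrix(surface[, c("nx", "ny", "nz")])
  fit <- cpp_fit_curvature(pts, nrm, neighborhood_radius,
                           as.integer(min_neighbors + 1),  # count includes self
                           min_normal_dot)
  # average the rotation-invariant curvature measures (mean curvature H and
  # Gaussian curvature K, both linear/bilinear in the shape tensor) over the
  # neighborhood before forming curvedness: averaging sorted eigenvalues or
  # taking the square root per point would turn zero-mean fit noise into a
  # positive curvedness bias
  HK <- cbind((fit[, 1] + fit[, 2]) / 2, fit[, 1] * fit[, 2])
  HKs <- cpp_neighbor_mean(pts, nrm, HK, neighborhood_radius, min_normal_dot)
  H <- HKs[, 1] * 10  # 1/A -> 1/nm
  K <- HKs[, 2] * 100
  disc <- sqrt(pmax(H^2 - K, 0))
  surface$k1 <- H + disc
  surface$k2 <- H - disc
  surface$curvedness <- sqrt(pmax(2 * H^2 - K, 0))
  surface$reliable <- (fit[, 3] - 1) >= min_neighbors & is.finite(H)
  attr(surface, "neighborhood_radius") <- neighborhood_radius
  surface
}

#' Write surface points as TSV (all fields)
#' @param surface a `surface_points` data frame.
#' @param path output path.
#' @export
write_surface_tsv <- function(surface, path) {
  write.table(as.data.frame(surface), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write surface points as ASCII PLY (positions and normals)
#' @param surface a `surface_points` data frame.
#' @param path output path.
#' @export
write_surface_ply <- function(surface, path) {
  n <- nrow(surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               "end_header"), con)
  write.table(format(surface[, c("x", "y", "z", "nx", "ny", "nz")],
                     trim = TRUE, digits = 7),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
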