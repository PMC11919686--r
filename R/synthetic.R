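# Synthetic phantoms with ground truth: vesicle fields in label space, bilayer
# tube maps and Cn-symmetric ring/patch maps in density space. Scene geometry
# is controlled by `geometry_seed` and is independent of `seed`, which drives
# only the stochastic degradation (label flips, additive noise); the same seed
# therefore reproduces a scene bit-exactly while different seeds share
# identical truth geometry.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# squared distance field to `center` over the sub-box index ranges (0-based)
.dist2_grid <- function(ix, iy, iz, center, voxel_size, origin) {
  dx <- origin[1] + ix * voxel_size - center[1]
  dy <- origin[2] + iy * voxel_size - center[2]
  dz <- origin[3] + iz * voxel_size - center[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  d2
}

#' Curvedness of ideal shapes
#'
#' Closed forms of the Koenderink curvedness `C = sqrt((k1^2 + k2^2)/2)`:
#' `1/r` for a sphere of radius r, `1/(r*sqrt(2))` for a cylinder, 0 for a
#' plane. Radii in Angstrom, curvedness in 1/nm.
#'
#' @param kind one of "sphere", "cylinder", "plane".
#' @param radius_A radius in Angstrom (ignored for "plane").
#' @return curvedness in 1/nm.
#' @export
shape_curvedness <- function(kind, radius_A) {
  switch(kind,
         sphere = 10 / radius_A,
         cylinder = 10 / (radius_A * sqrt(2)),
         plane = 0,
         stop("unknown shape kind: ", kind, call. = FALSE))
}

#' Curvature-dependent coat coverage model
#'
#' Linear ramp between two curvedness bounds, then plateau:
#' `clamp((C - c_lo) / (c_hi - c_lo), 0, 1)`.
#'
#' @param curvedness curvedness values, 1/nm.
#' @param c_lo,c_hi ramp foot and saturation curvedness, 1/nm (`c_lo < c_hi`).
#' @return target coverage fraction in `[0, 1]`.
#' @export
coverage_model <- function(curvedness, c_lo = 0.02, c_hi = 0.06) {
  if (c_lo >= c_hi) stop("coverage model requires c_lo < c_hi", call. = FALSE)
  pmin(pmax((curvedness - c_lo) / (c_hi - c_lo), 0), 1)
}

# Draw cap directions and half-angles realizing total coverage `f` with up to
# n_patches equal-area non-overlapping spherical caps. Falls back to fewer
# patches (down to a single cap, which is exact for any f) when non-overlapping
# placement fails within the retry budget.
.draw_caps <- function(f, n_patches, max_tries = 400) {
  if (f <= 0) return(list(dirs = matrix(0, 0, 3), cos_alpha = numeric(0)))
  if (f >= 1) return(list(dirs = matrix(c(0, 0, 1), 1, 3), cos_alpha = -1))
  for (np in seq(n_patches, 1)) {
    cos_a <- 1 - 2 * f / np
    alpha <- acos(pmin(pmax(cos_a, -1), 1))
    if (np == 1)
      return(list(dirs = matrix(.rand_dirs(1), 1, 3), cos_alpha = cos_a))
    if (2 * alpha + 0.1 > pi) next  # caps too large to separate
    for (try in seq_len(max_tries)) {
      dirs <- .rand_dirs(np)
      ang <- acos(pmin(pmax(tcrossprod(dirs), -1), 1))
      diag(ang) <- pi
      if (min(ang) > 2 * alpha + 0.1)
        return(list(dirs = dirs, cos_alpha = rep(cos_a, np)))
    }
  }
  list(dirs = matrix(.rand_dirs(1), 1, 3), cos_alpha = 1 - 2 * f)
}

.rand_dirs <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Generate a synthetic vesicle scene in label space
#'
#' Renders spherical vesicles as membrane shells of the given thickness, with
#' protein-coat patches layered immediately outside the shell. Each vesicle's
#' total coat area fraction follows [coverage_model()] evaluated at the
#' vesicle's true curvedness (`10 / radius` 1/nm, radius = outer membrane
#' radius in Angstrom). Coverage is realized as a small number of contiguous
#' spherical-cap patches. A stated fraction of membrane-shell voxels is flipped
#' to background to emulate segmentation error.
#'
#' @param radii vesicle outer membrane radii, Angstrom (each >= 4 voxel sizes).
#' @param c_lo,c_hi coverage-model ramp bounds, 1/nm.
#' @param voxel_size Angstrom per voxel.
#' @param shell_thickness membrane shell thickness, Angstrom (radially inward).
#' @param coat_thickness coat layer thickness, Angstrom (radially outward).
#' @param n_patches maximum number of contiguous coat patches per vesicle.
#' @param noise_fraction fraction of membrane voxels flipped to background.
#' @param seed integer seed for the label noise.
#' @param geometry_seed integer seed for placement and patch directions (kept
#'   separate so the truth geometry is invariant across noise seeds).
#' @param dim optional grid dimensions (3 integers); computed from the radii
#'   when omitted.
#' @param margin minimal clearance between vesicles (coat included) and to the
#'   volume faces, Angstrom.
#' @param max_tries placement retry budget per vesicle before a placement
#'   error is raised.
#' @return List with `labels` (a [label_volume()]) and `truth` (a data frame
#'   with one row per vesicle: center, radius, `true_curvedness` (1/nm),
#'   `target_coverage`, `realized_coverage`; coverage-model parameters and
#'   seeds as attributes).
#' @export
make_vesicle_scene <- function(radii, c_lo = 0.02, c_hi = 0.06, voxel_size = 10,
                               shell_thickness = 40, coat_thickness = 30,
                               n_patches = 3, noise_fraction = 0.02, seed = 1,
                               geometry_seed = 1000003, dim = NULL, margin = 30,
                               max_tries = 2000) {
  stopifnot(length(radii) >= 1, all(is.finite(radii)))
  if (any(radii < 4 * voxel_size))
    stop("all radii must be >= 4 * voxel_size", call. = FALSE)
  if (any(radii <= shell_thickness))
    stop("radii must exceed shell_thickness", call. = FALSE)
  pad <- coat_thickness + margin
  if (is.null(dim)) {
    edge <- max(2.6 * (max(radii) + pad), sum((2.9 * (radii + pad))^3)^(1 / 3))
    nvox <- ceiling(edge / voxel_size)
    dim <- rep(as.integer(nvox), 3)
  }
  dim <- as.integer(dim)
  origin <- c(0, 0, 0)
  ext <- (dim - 1) * voxel_size

  geom <- .with_seed(geometry_seed, {
    ord <- order(radii, decreasing = TRUE)  # place large vesicles first
    centers <- matrix(NA_real_, length(radii), 3)
    for (ii in ord) {
      r_excl <- radii[ii] + pad
      if (any(ext - 2 * r_excl < 0))
        stop("volume too small to place a vesicle of radius ", radii[ii],
             " A (placement error)", call. = FALSE)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- runif(3, min = r_excl, max = ext - r_excl)
        ok <- TRUE
        for (jj in which(!is.na(centers[, 1]))) {
          if (sqrt(sum((cand - centers[jj, ])^2)) <
              radii[ii] + radii[jj] + 2 * pad) { ok <- FALSE; break }
        }
        if (ok) { centers[ii, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place all vesicles after ", max_tries,
             " tries per vesicle (placement error); enlarge `dim`", call. = FALSE)
    }
    true_c <- shape_curvedness("sphere", radii)
    target <- coverage_model(true_c, c_lo, c_hi)
    caps <- lapply(target, .draw_caps, n_patches = n_patches)
    list(centers = centers, true_c = true_c, target = target, caps = caps)
  })

  lab <- array(0L, dim)
  ct <- default_class_table()
  realized <- numeric(length(radii))
  for (ii in seq_along(radii)) {
    r <- radii[ii]
    cen <- geom$centers[ii, ]
    r_out_all <- r + coat_thickness
    i0 <- pmax(0L, floor((cen - r_out_all - voxel_size) / voxel_size))
    i1 <- pmin(dim - 1L, ceiling((cen + r_out_all + voxel_size) / voxel_size))
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    d2 <- .dist2_grid(ix, iy, iz, cen, voxel_size, origin)
    d <- sqrt(d2)
    mem <- d <= r & d > r - shell_thickness
    coat_shell <- d > r & d <= r_out_all
    sub <- lab[ix + 1L, iy + 1L, iz + 1L]
    sub[mem] <- ct[["membrane"]]
    caps <- geom$caps[[ii]]
    if (nrow(caps$dirs) > 0) {
      # cosine of angle between voxel direction and each cap center
      dx <- origin[1] + ix * voxel_size - cen[1]
      dy <- origin[2] + iy * voxel_size - cen[2]
      dz <- origin[3] + iz * voxel_size - cen[3]
      incap <- array(FALSE, base::dim(d))
      for (pc in seq_len(nrow(caps$dirs))) {
        u <- caps$dirs[pc, ]
        dot <- outer(outer(dx * u[1], dy * u[2], "+"), dz * u[3], "+")
        incap <- incap | (dot >= caps$cos_alpha[pc] * d)
      }
      sub[coat_shell & incap] <- ct[["coat"]]
      realized[ii] <- sum(coat_shell & incap) / max(1L, sum(coat_shell))
    } else realized[ii] <- 0
    lab[ix + 1L, iy + 1L, iz + 1L] <- sub
  }

  if (noise_fraction > 0) {
    .with_seed(seed, {
      memv <- which(lab == ct[["membrane"]])
      nflip <- round(noise_fraction * length(memv))
      if (nflip > 0) lab[sample(memv, nflip)] <- 0L
    })
  }

  truth <- data.frame(kind = "sphere",
                      cx = geom$centers[, 1], cy = geom$centers[, 2],
                      cz = geom$centers[, 3], radius = radii,
                      true_curvedness = geom$true_c,
                      target_coverage = geom$target,
                      realized_coverage = realized)
  attr(truth, "c_lo") <- c_lo
  attr(truth, "c_hi") <- c_hi
  attr(truth, "rng_seed") <- seed
  attr(truth, "geometry_seed") <- geometry_seed
  list(labels = label_volume(lab, voxel_size, ct, origin), truth = truth)
}

#' Generate a synthetic membrane tube density map
#'
#' Density is a sum of Gaussian annular shells about the z axis at the two
#' bilayer leaflet radii and the protein shell radius, plus optional Gaussian
#' noise. An optional constriction bends all shells as
#' `r(z) = r + slope * |z - z0|` to emulate an hourglass membrane profile; the
#' analytic kink angle between the two flanks is `2 * atan(1/slope)`.
#'
#' @param r_inner_leaflet,r_outer_leaflet,r_protein shell radii, Angstrom
#'   (strictly increasing).
#' @param leaflet_sd radial Gaussian width of each leaflet shell, Angstrom.
#' @param protein_sd radial width of the protein shell, Angstrom.
#' @param amplitudes peak densities of the three shells.
#' @param voxel_size Angstrom per voxel.
#' @param length tube length along z, Angstrom.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed seed for the noise.
#' @param constriction optional `list(z0 = <A>, slope = <dr/dz>)`.
#' @param xy_extent optional xy grid extent in Angstrom (computed when omitted).
#' @return List with `map` (a [density_map()]) and `truth` (radii, thickness
#'   `r_outer_leaflet - r_inner_leaflet`, and kink angle when constricted).
#' @export
make_tube_map <- function(r_inner_leaflet, r_outer_leaflet, r_protein,
                          leaflet_sd = 5, protein_sd = 10,
                          amplitudes = c(1, 1, 0.9), voxel_size = 3,
                          length = 210, noise_sd = 0, seed = 1,
                          constriction = NULL, xy_extent = NULL) {
  if (!(r_inner_leaflet < r_outer_leaflet && r_outer_leaflet < r_protein))
    stop("need r_inner_leaflet < r_outer_leaflet < r_protein", call. = FALSE)
  max_shift <- 0
  if (!is.null(constriction))
    max_shift <- constriction$slope * length / 2
  if (is.null(xy_extent))
    xy_extent <- 2 * (r_protein + max_shift + 4 * protein_sd + 2 * voxel_size)
  nxy <- as.integer(ceiling(xy_extent / voxel_size))
  nz <- as.integer(ceiling(length / voxel_size))
  if (r_protein + max_shift + 3 * protein_sd > xy_extent / 2)
    stop("shell radii exceed half the grid extent (geometry error)", call. = FALSE)
  cx <- (nxy - 1) / 2 * voxel_size
  zphys <- (seq_len(nz) - 1) * voxel_size
  xg <- (seq_len(nxy) - 1) * voxel_size - cx
  rmat <- sqrt(outer(xg^2, xg^2, "+"))
  radii <- c(r_inner_leaflet, r_outer_leaflet, r_protein)
  sds <- c(leaflet_sd, leaflet_sd, protein_sd)
  vals <- array(0, c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    shift <- if (is.null(constriction)) 0 else
      constriction$slope * abs(zphys[k] - constriction$z0)
    sl <- 0
    for (s in 1:3)
      sl <- sl + amplitudes[s] * exp(-(rmat - (radii[s] + shift))^2 / (2 * sds[s]^2))
    vals[, , k] <- sl
  }
  if (noise_sd > 0)
    vals <- .with_seed(seed, vals + array(rnorm(base::length(vals), sd = noise_sd),
                                          base::dim(vals)))
  truth <- list(r_inner_leaflet = r_inner_leaflet,
                r_outer_leaflet = r_outer_leaflet, r_protein = r_protein,
                thickness = r_outer_leaflet - r_inner_leaflet,
                leaflet_sd = leaflet_sd, protein_sd = protein_sd,
                constriction = constriction,
                kink_angle = if (is.null(constriction)) 180 else
                  2 * atan(1 / constriction$slope) * 180 / pi,
                noise_sd = noise_sd, seed = seed)
  list(map = density_map(vals, voxel_size), truth = truth)
}

#' Generate a Cn-symmetric ring or patch density map
#'
#' Places `n` copies of a two-blob Gaussian motif by rotating a seed motif
#' about an axis parallel to z, offset along x from the map center. With
#' `patch_wedge < 360` only motifs within the wedge (centered on the map
#' center as seen from the axis) are rendered, emulating a subtomogram-average
#' patch cut from a larger ring.
#'
#' @param n symmetry order (>= 2).
#' @param axis_offset axis offset along x from the map center, Angstrom.
#' @param rotation global rotation of the motif ring about the axis, degrees.
#' @param ring_radius motif ring radius about the axis, Angstrom; defaults to
#'   `max(axis_offset, 60)` so the seed motif sits near the map center.
#' @param patch_wedge rendered wedge in degrees (360 = full ring).
#' @param blob_sd Gaussian blob width, Angstrom.
#' @param noise_sd additive Gaussian noise standard deviation (motif peak
#'   amplitude is 1, so `1/noise_sd` is the voxel-level SNR).
#' @param seed seed for the noise.
#' @param voxel_size Angstrom per voxel.
#' @param half_extent optional xy half extent of the grid, Angstrom.
#' @return List with `map` (a [density_map()]) and `truth` (n, axis position,
#'   rotation, ring radius, wedge, noise parameters).
#' @export
make_cn_map <- function(n, axis_offset = 0, rotation = 0, ring_radius = NULL,
                        patch_wedge = 360, blob_sd = 8, noise_sd = 0, seed = 1,
                        voxel_size = 2, half_extent = NULL) {
  if (n < 2) stop("symmetry order n must be >= 2", call. = FALSE)
  if (is.null(ring_radius)) ring_radius <- max(axis_offset, 60)
  # motif blob table relative to the axis: (radius, dtheta deg, dz, amp, sd).
  # The blobs span ~50 A radially and ~25 A axially, mimicking a protein
  # subunit with features at several radii; a radially extended unit is what
  # makes the symmetry order identifiable on a partial-ring patch (point-like
  # units leave the arc-spacing degeneracy n/d ~ const unbroken).
  motif <- data.frame(radius = ring_radius + c(0, -14, 12, -26, 22),
                      dtheta = c(0, 4, -3, -6, 5),
                      dz = c(0, 10, 8, -9, -12),
                      amp = c(1, 0.8, 0.7, 0.75, 0.65),
                      sd = blob_sd * c(1, 0.9, 0.8, 0.9, 0.8))
  base_ang <- 180 + rotation  # unit 0 toward the map center
  units <- (seq_len(n) - 1) * 360 / n
  keep <- rep(TRUE, n)
  if (patch_wedge < 360) {
    dang <- ((units + rotation + 180) %% 360) - 180  # angular distance to unit 0
    keep <- abs(dang) <= patch_wedge / 2
  }
  ang_all <- base_ang + units[keep]
  blobs <- do.call(rbind, lapply(ang_all, function(a) {
    th <- (a + motif$dtheta) * pi / 180
    data.frame(bx = motif$radius * cos(th), by = motif$radius * sin(th),
               bz = motif$dz, amp = motif$amp, sd = motif$sd)
  }))
  if (is.null(half_extent)) {
    half_extent <- max(abs(axis_offset + blobs$bx), abs(blobs$by),
                       abs(axis_offset) + 2 * voxel_size) + 5 * blob_sd
  }
  nxy <- 2L * as.integer(ceiling(half_extent / voxel_size)) + 1L
  zext <- max(abs(blobs$bz)) + 5 * blob_sd
  nz <- 2L * as.integer(ceiling(zext / voxel_size)) + 1L
  cx <- (nxy - 1) / 2 * voxel_size
  cz <- (nz - 1) / 2 * voxel_size
  ax <- cx + axis_offset
  vals <- array(0, c(nxy, nxy, nz))
  xs <- (seq_len(nxy) - 1) * voxel_size
  zs <- (seq_len(nz) - 1) * voxel_size
  for (b in seq_len(nrow(blobs))) {
    px <- ax + blobs$bx[b]; py <- cx + blobs$by[b]; pz <- cz + blobs$bz[b]
    s <- blobs$sd[b]
    ixr <- which(abs(xs - px) <= 4 * s); iyr <- which(abs(xs - py) <= 4 * s)
    izr <- which(abs(zs - pz) <= 4 * s)
    if (!length(ixr) || !length(iyr) || !length(izr)) next
    g <- outer(outer(exp(-(xs[ixr] - px)^2 / (2 * s^2)),
                     exp(-(xs[iyr] - py)^2 / (2 * s^2)), "*"),
               exp(-(zs[izr] - pz)^2 / (2 * s^2)), "*")
    vals[ixr, iyr, izr] <- vals[ixr, iyr, izr] + blobs$amp[b] * g
  }
  if (noise_sd > 0)
    vals <- .with_seed(seed, vals + array(rnorm(length(vals), sd = noise_sd),
                                          dim(vals)))
  truth <- list(n = n, axis_offset = axis_offset, rotation = rotation,
                ring_radius = ring_radius, patch_wedge = patch_wedge,
                blob_sd = blob_sd, noise_sd = noise_sd, seed = seed,
                axis_x = ax, axis_y = cx)
  list(map = density_map(vals, voxel_size), truth = truth)
}
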