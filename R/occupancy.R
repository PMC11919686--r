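# Coat-occupancy analysis: proximity labeling of membrane surface points
# against the coat segmentation, curvedness binning, and the ramp-plateau
# (saturation) fit of occupancy against curvedness.

#' Label surface points proximal to a coat segmentation
#'
#' A point is proximal iff the Euclidean distance from the point to the
#' nearest coat-voxel center is at most `max_distance` (50 Angstrom by
#' default, the acceptance distance for an adjacent coat).
#'
#' @param surface a `surface_points` data frame.
#' @param coat a [label_volume()] containing a coat class, or a 0/1 mask array
#'   sharing the surface's physical frame.
#' @param max_distance proximity threshold, Angstrom.
#' @param coat_class class name of the coat when `coat` is a label volume.
#' @return Logical vector, one element per surface point. When the coat class
#'   is empty, all `FALSE` with a warning.
#' @export
label_proximal <- function(surface, coat, max_distance = 50,
                           coat_class = "coat") {
  stopifnot(inherits(surface, "surface_points"))
  if (inherits(coat, "label_volume")) {
    mask <- class_mask(coat, coat_class)
    voxel <- coat$voxel_size
    origin <- coat$origin
  } else stop("`coat` must be a label_volume", call. = FALSE)
  vox_idx <- which(mask == 1L)
  if (!length(vox_idx)) {
    warning("coat class '", coat_class, "' is empty; no point is proximal")
    return(rep(FALSE, nrow(surface)))
  }
  d <- dim(mask)
  idx0 <- arrayInd(vox_idx, d) - 1L
  centers <- voxel_to_phys(idx0, voxel, origin)
  pts <- as.matrix(surface[, c("x", "y", "z")])
  as.logical(cpp_has_neighbor_within(pts, centers, max_distance))
}

#' Exclude surface points near the tomogram edges
#'
#' Removes points flagged `near_edge` at extraction time (curvature and
#' segmentation are unreliable near reconstruction boundaries).
#'
#' @param surface a `surface_points` data frame with `near_edge` set.
#' @return The filtered surface; errors if nothing remains.
#' @export
exclude_edges <- function(surface) {
  stopifnot(inherits(surface, "surface_points"))
  keep <- !surface$near_edge
  if (!any(keep))
    stop("all surface points are near a volume edge; reduce `edge_margin`",
         call. = FALSE)
  out <- surface[keep, , drop = FALSE]
  attr(out, "n_edge_excluded") <- sum(!keep)
  out
}

#' Bin occupancy by curvedness
#'
#' Sorts reliable surface points into fixed-width curvedness bins and reports,
#' per bin, the fraction of points with a proximal coat (the occupancy, in
#' `[0, 1]`).
#'
#' @param surface a `surface_points` data frame with curvedness estimates.
#' @param proximal logical vector from [label_proximal()] (same length).
#' @param bin_width curvedness bin width, 1/nm.
#' @param c_max upper end of the binned range, 1/nm; defaults to the smallest
#'   bin multiple covering the data.
#' @return An `occupancy_profile` data frame: `curvedness_lo`, `curvedness_hi`,
#'   `n_points`, `n_proximal`, `occupancy` (NA for empty bins).
#' @export
bin_occupancy <- function(surface, proximal, bin_width = 0.004, c_max = NULL) {
  stopifnot(inherits(surface, "surface_points"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  if (length(proximal) != nrow(surface))
    stop("`proximal` must have one entry per surface point", call. = FALSE)
  if (is.null(surface$curvedness))
    stop("surface has no curvedness; run estimate_curvature() first", call. = FALSE)
  ok <- if (is.null(surface$reliable)) is.finite(surface$curvedness) else
    surface$reliable & is.finite(surface$curvedness)
  cv <- surface$curvedness[ok]
  pr <- proximal[ok]
  if (is.null(c_max)) c_max <- max(bin_width, ceiling(max(cv) / bin_width) * bin_width)
  nb <- as.integer(round(c_max / bin_width))
  bin <- pmin(pmax(floor(cv / bin_width), 0), nb - 1) + 1L
  inside <- cv <= c_max
  n_points <- tabulate(bin[inside], nbins = nb)
  n_prox <- tabulate(bin[inside & pr], nbins = nb)
  occ <- ifelse(n_points > 0, n_prox / n_points, NA_real_)
  out <- data.frame(curvedness_lo = (seq_len(nb) - 1) * bin_width,
                    curvedness_hi = seq_len(nb) * bin_width,
                    n_points = n_points, n_proximal = n_prox, occupancy = occ)
  class(out) <- c("occupancy_profile", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "n_outside_range") <- sum(!inside)
  out
}

#' Fit a ramp-plateau (saturation) model to an occupancy profile
#'
#' Weighted least-squares fit of a continuous piecewise model -- a line up to
#' a breakpoint, constant beyond -- to occupancy against bin-center
#' curvedness, with weights `n_points`. The breakpoint is chosen by a 1-D scan
#' over bin edges minimizing the residual sum of squares. The saturation
#' summary quantifies the transition from the linear binding regime to the
#' plateau of full coverage.
#'
#' @param profile an `occupancy_profile` from [bin_occupancy()].
#' @param min_bins minimal number of nonempty bins.
#' @return A `saturation_fit` list: `slope` and `intercept` of the linear
#'   regime (occupancy per 1/nm), `breakpoint` curvedness c* (1/nm),
#'   `plateau` level in `[0, 1]`, `ramp_onset` (curvedness where the fitted
#'   line crosses zero occupancy), `rss`, and per-bin `residuals`.
#' @export
fit_saturation <- function(profile, min_bins = 6) {
  stopifnot(inherits(profile, "occupancy_profile"))
  use <- profile$n_points > 0
  if (sum(use) < min_bins)
    stop("need at least ", min_bins, " nonempty bins for the saturation fit",
         call. = FALSE)
  cc <- (profile$curvedness_lo + profile$curvedness_hi)[use] / 2
  y <- profile$occupancy[use]
  w <- profile$n_points[use]
  edges <- sort(unique(c(profile$curvedness_lo[use], profile$curvedness_hi[use])))
  best <- NULL
  for (cstar in edges) {
    u <- pmin(cc, cstar)
    if (diff(range(u)) < 1e-12) {           # pure constant model
      a <- weighted.mean(y, w); b <- 0
      fitv <- rep(a, length(y))
    } else {
      fit <- stats::lm.wfit(cbind(1, u), y, w)
      a <- fit$coefficients[1]; b <- fit$coefficients[2]
      fitv <- a + b * u
    }
    rss <- sum(w * (y - fitv)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * max(best$rss, 1e-300)) {
      best <- list(cstar = cstar, a = unname(a), b = unname(b), rss = rss,
                   fitted = fitv)
    }
  }
  plateau <- best$a + best$b * best$cstar
  res <- structure(list(
    slope = best$b, intercept = best$a, breakpoint = best$cstar,
    plateau = min(max(plateau, 0), 1),
    ramp_onset = if (abs(best$b) > 1e-12) -best$a / best$b else NA_real_,
    rss = best$rss, residuals = y - best$fitted,
    bin_centers = cc, occupancy = y, weights = w),
    class = "saturation_fit")
  res
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> occupancy = intercept + slope * curvedness, then plateau\n")
  cat(sprintf("  slope      %8.3f per (1/nm)\n", x$slope))
  cat(sprintf("  intercept  %8.3f\n", x$intercept))
  cat(sprintf("  ramp onset %8.4f 1/nm (fitted zero-occupancy curvedness)\n",
              x$ramp_onset))
  cat(sprintf("  breakpoint %8.4f 1/nm\n", x$breakpoint))
  cat(sprintf("  plateau    %8.3f\n", x$plateau))
  cat(sprintf("  weighted RSS %.4g over %d bins\n", x$rss, length(x$residuals)))
  invisible(x)
}

#' Plot an occupancy profile with an optional saturation fit overlay
#'
#' @param x an `occupancy_profile`.
#' @param fit optional `saturation_fit` to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.occupancy_profile <- function(x, fit = NULL, ...) {
  cc <- (x$curvedness_lo + x$curvedness_hi) / 2
  graphics::plot(cc, x$occupancy, xlab = "curvedness (1/nm)",
                 ylab = "occupancy", ylim = c(0, 1), pch = 16, ...)
  if (!is.null(fit)) {
    xs <- seq(min(cc), max(cc), length.out = 200)
    ys <- fit$intercept + fit$slope * pmin(xs, fit$breakpoint)
    graphics::lines(xs, pmin(pmax(ys, 0), 1), col = "firebrick", lwd = 2)
    graphics::abline(v = fit$breakpoint, lty = 2, col = "grey40")
  }
  invisible(x)
}
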