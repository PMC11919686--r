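# Radial and axial density profiling of tube/ring reconstructions: bilayer
# leaflet radii and thickness, tube outer diameter, per-slice membrane traces
# and the kink angle at a constriction.

#' Radial density profile of a tube map
#'
#' Mean density per radial annulus about the z axis (through the map center in
#' xy by default), averaged over azimuth and the chosen axial range. Bin
#' assignment is by voxel-center radius, so the binned totals conserve the
#' slab density exactly.
#'
#' @param map a [density_map()] with the tube axis along z.
#' @param z_range optional physical z interval (Angstrom) to average over.
#' @param bin_width radial bin width, Angstrom (defaults to the voxel size).
#' @param center optional xy center of the axis, Angstrom.
#' @return A `radial_profile` data frame: `radius` (bin centers, Angstrom),
#'   `mean_density`, `n_voxels`. Bins cover 0 to the inscribed half-extent.
#' @export
radial_profile <- function(map, z_range = NULL, bin_width = NULL, center = NULL) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  if (is.null(bin_width)) bin_width <- map$voxel_size
  cen <- if (is.null(center)) .map_center(map)[1:2] else center
  xs <- map$origin[1] + (seq_len(d[1]) - 1) * map$voxel_size
  ys <- map$origin[2] + (seq_len(d[2]) - 1) * map$voxel_size
  zs <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel_size
  kz <- if (is.null(z_range)) seq_len(d[3]) else
    which(zs >= z_range[1] & zs <= z_range[2])
  if (!length(kz)) stop("empty z range", call. = FALSE)
  rmat <- sqrt(outer((xs - cen[1])^2, (ys - cen[2])^2, "+"))
  r_in <- min(cen[1] - xs[1], xs[d[1]] - cen[1], cen[2] - ys[1], ys[d[2]] - cen[2])
  nb <- max(2L, as.integer(floor(r_in / bin_width)))
  bin <- pmin(as.integer(floor(rmat / bin_width)) + 1L, nb + 1L)  # nb+1 = overflow
  binv <- as.vector(bin)
  grp <- split(seq_along(binv), binv)
  gid <- as.integer(names(grp))
  sums <- numeric(nb + 1L)
  cnts <- numeric(nb + 1L)
  cnts[gid] <- lengths(grp) * length(kz)
  for (k in kz) {
    sl <- as.vector(map$values[, , k])
    sums[gid] <- sums[gid] + vapply(grp, function(ii) sum(sl[ii]), numeric(1))
  }
  # center-of-mass drift check (axis misalignment warning)
  if (length(kz) >= 3) {
    pos <- pmax(map$values[, , kz, drop = FALSE], 0)
    tot <- apply(pos, 3, sum)
    okk <- tot > 0
    if (sum(okk) >= 3) {
      comx <- apply(pos, 3, function(s) sum(s * xs) / sum(s))
      comy <- apply(pos, 3, function(s) sum(s * rep(ys, each = d[1])) / sum(s))
      drift <- max(diff(range(comx[okk])), diff(range(comy[okk])))
      if (drift > 2 * map$voxel_size)
        warning("center-of-mass drift of ", signif(drift, 3),
                " A across z; tube axis may be misaligned")
    }
  }
  out <- data.frame(radius = (seq_len(nb) - 0.5) * bin_width,
                    mean_density = (sums / pmax(cnts, 1))[seq_len(nb)],
                    n_voxels = cnts[seq_len(nb)])
  class(out) <- c("radial_profile", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "n_slices") <- length(kz)
  attr(out, "total_density") <- sum(sums[seq_len(nb)])
  out
}

# peaks of a 1-D signal with their (topographic) prominences
.find_peaks <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx)) return(data.frame(index = integer(0), value = numeric(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    hl <- which(left >= y[i]); hr <- which(right >= y[i])
    base_l <- if (length(hl)) min(y[seq(max(hl) + 0, i - 1)]) else min(left)
    base_r <- if (length(hr)) min(y[seq(i + 1, i + min(hr))]) else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, value = y[idx], prominence = prom)
}

# half-prominence width of peak `i` (in radius units)
.peak_width <- function(r, y, i, prom) {
  lev <- y[i] - prom / 2
  li <- i; while (li > 1 && y[li] > lev) li <- li - 1
  ri <- i; while (ri < length(y) && y[ri] > lev) ri <- ri + 1
  r[ri] - r[li]
}

#' Detect bilayer leaflet radii in a radial profile
#'
#' The two innermost peaks whose prominence exceeds `prominence_fraction` of
#' the profile's dynamic range are taken as the inner and outer leaflet;
#' thickness is their peak-to-peak separation. With `refine = TRUE` (the
#' default) the leaflet radii are refined by a two-Gaussian-plus-baseline fit
#' of the bilayer region, which recovers each leaflet's own density maximum
#' even when the two headgroup peaks are broad enough to merge into a single
#' local maximum of the summed profile (an innermost peak much wider than its
#' neighbor is treated as such a merged pair and split for initialization).
#'
#' @param profile a `radial_profile`.
#' @param prominence_fraction minimal peak prominence as a fraction of the
#'   profile dynamic range.
#' @param refine refine peak-to-peak positions by the two-component fit.
#' @return List with `r_inner`, `r_outer`, `thickness` (Angstrom), `refined`
#'   (logical) and the raw peak table. A detection error listing the peaks
#'   found is raised when no bilayer pair can be identified.
#' @export
detect_leaflets <- function(profile, prominence_fraction = 0.1, refine = TRUE) {
  stopifnot(inherits(profile, "radial_profile"))
  y <- profile$mean_density
  r <- profile$radius
  pk <- .find_peaks(y)
  thr <- prominence_fraction * diff(range(y))
  pk <- pk[order(pk$index), , drop = FALSE]
  qual <- pk[pk$prominence >= thr, , drop = FALSE]
  if (nrow(qual) == 0)
    stop("leaflet detection error: found 0 qualifying peaks (need 2)",
         call. = FALSE)
  qual$width <- vapply(seq_len(nrow(qual)), function(i)
    .peak_width(r, y, qual$index[i], qual$prominence[i]), numeric(1))
  merged <- nrow(qual) == 1 ||
    (nrow(qual) >= 2 && qual$width[1] > 1.8 * qual$width[2])
  if (merged) {
    # innermost peak is a merged headgroup pair: split it for initialization.
    # Any outer (protein) shell peak is included as an explicit third
    # component so its inner tail cannot bias the pair.
    p <- r[qual$index[1]]
    w <- qual$width[1]
    init <- c(c1 = p - w / 4, c2 = p + w / 4, s = w / 2.8)
    if (nrow(qual) >= 2) {
      p3 <- r[qual$index[2]]
      w3 <- qual$width[2]
      win <- r >= p - 1.0 * w & r <= p3 + w3
      init <- c(init, c3 = p3, s3 = w3 / 2.355)
    } else {
      win <- r >= p - 1.0 * w & r <= p + 1.0 * w
    }
    cbound <- c(p - 0.7 * w, p + 0.7 * w)
  } else {
    if (nrow(qual) < 2)
      stop("leaflet detection error: found 1 qualifying peak at radius ",
           signif(r[qual$index[1]], 4), " A (need 2)", call. = FALSE)
    init <- c(c1 = r[qual$index[1]], c2 = r[qual$index[2]],
              s = max(mean(qual$width[1:2]) / 2.355, profile$radius[2] - profile$radius[1]))
    win <- r >= init["c1"] - 3 * init["s"] & r <= init["c2"] + 3 * init["s"]
    cbound <- c(init[["c1"]] - 2 * init[["s"]], init[["c2"]] + 2 * init[["s"]])
  }
  out <- list(r_inner = unname(init["c1"]), r_outer = unname(init["c2"]),
              refined = FALSE,
              peaks = transform(qual, radius = r[qual$index]))
  if (!merged) {
    out$r_inner <- r[qual$index[1]]
    out$r_outer <- r[qual$index[2]]
  }
  if (refine && sum(win) >= 8) {
    df <- data.frame(r = r[win], y = y[win])
    amp0 <- max(df$y) - min(df$y)
    three <- "c3" %in% names(init)
    form <- if (three)
      y ~ b + a1 * exp(-(r - c1)^2 / (2 * s^2)) +
        a2 * exp(-(r - c2)^2 / (2 * s^2)) +
        a3 * exp(-(r - c3)^2 / (2 * s3^2)) else
      y ~ b + a1 * exp(-(r - c1)^2 / (2 * s^2)) +
        a2 * exp(-(r - c2)^2 / (2 * s^2))
    start <- list(b = min(df$y), a1 = amp0, a2 = amp0,
                  c1 = unname(init["c1"]), c2 = unname(init["c2"]),
                  s = unname(init["s"]))
    lower <- c(b = -Inf, a1 = 0, a2 = 0, c1 = cbound[1], c2 = cbound[1], s = 1.5)
    upper <- c(b = Inf, a1 = Inf, a2 = Inf, c1 = cbound[2], c2 = cbound[2],
               s = diff(range(df$r)))
    if (three) {
      start <- c(start, list(a3 = amp0, c3 = unname(init["c3"]),
                             s3 = unname(init["s3"])))
      lower <- c(lower, a3 = 0, c3 = unname(init["c3"]) - 15, s3 = 1.5)
      upper <- c(upper, a3 = Inf, c3 = unname(init["c3"]) + 15,
                 s3 = diff(range(df$r)))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      sep <- abs(cf[["c2"]] - cf[["c1"]])
      amps_ok <- min(cf[["a1"]], cf[["a2"]]) > 0.05 * diff(range(y))
      if (is.finite(sep) && sep > 5 && sep < 120 && amps_ok) {
        out$r_inner <- min(cf[["c1"]], cf[["c2"]])
        out$r_outer <- max(cf[["c1"]], cf[["c2"]])
        out$refined <- TRUE
      }
    }
  }
  if (!out$refined && merged && nrow(qual) < 2)
    stop("leaflet detection error: single broad peak at radius ",
         signif(r[qual$index[1]], 4), " A could not be resolved into two leaflets",
         call. = FALSE)
  out$thickness <- out$r_outer - out$r_inner
  out
}

#' Measure the tube outer diameter from a radial profile
#'
#' Diameter is twice the outermost radius at which the density crosses
#' `threshold_fraction` of the outermost qualifying peak (relative to the
#' large-radius background), on the outward side of that peak.
#'
#' @param profile a `radial_profile` decaying to background at large radius.
#' @param threshold_fraction crossing level as a fraction of the peak height
#'   above background.
#' @param prominence_fraction peak qualification threshold, as in
#'   [detect_leaflets()].
#' @return Outer diameter in Angstrom.
#' @export
measure_outer_diameter <- function(profile, threshold_fraction = 0.5,
                                   prominence_fraction = 0.1) {
  stopifnot(inherits(profile, "radial_profile"))
  y <- profile$mean_density
  r <- profile$radius
  n <- length(y)
  pk <- .find_peaks(y)
  thr <- prominence_fraction * diff(range(y))
  qual <- pk[pk$prominence >= thr, , drop = FALSE]
  if (!nrow(qual))
    stop("no qualifying peak; cannot measure a diameter", call. = FALSE)
  ip <- max(qual$index)
  tail_idx <- seq(max(ip + 1, n - max(3, round(0.1 * n)) + 1), n)
  baseline <- median(y[tail_idx])
  level <- baseline + threshold_fraction * (y[ip] - baseline)
  below <- which(y < level & seq_len(n) > ip)
  if (!length(below))
    stop("profile does not decay to background beyond the outermost peak",
         call. = FALSE)
  i1 <- min(below)
  i0 <- i1 - 1L
  f <- (y[i0] - level) / (y[i0] - y[i1])
  2 * (r[i0] + f * (r[i1] - r[i0]))
}

#' Per-slice leaflet trace along the tube axis, with kink angle
#'
#' Computes a radial profile per axial slab, detects the leaflet radii in
#' each, and derives the narrowest/widest membrane diameters and the kink
#' angle at the constriction: the angle between straight-line fits of r(z)
#' over flanking windows on either side of the trace minimum (180 degrees for
#' a straight tube).
#'
#' @param map a [density_map()] with the tube axis along z.
#' @param slab_width axial slab thickness in voxels.
#' @param prominence_fraction per-slab leaflet qualification threshold.
#' @param leaflet which leaflet trace to analyze: "outer", "inner" or "mid".
#' @param flank_window window length on each side of the constriction used
#'   for the straight-line fits, Angstrom.
#' @param flank_gap gap excluded around the apex (where shell width rounds
#'   the profile), Angstrom.
#' @return An `axial_trace` list: per-slab trace (z, r_inner, r_outer; NA
#'   where fewer than two peaks were found), `narrowest` and `widest` membrane
#'   diameters (Angstrom), `kink_angle` (degrees) and `z_constriction`.
#' @export
axial_leaflet_trace <- function(map, slab_width = 2, prominence_fraction = 0.1,
                                leaflet = c("outer", "inner", "mid"),
                                flank_window = 30, flank_gap = 6) {
  stopifnot(inherits(map, "density_map"))
  leaflet <- match.arg(leaflet)
  d <- dim(map$values)
  zs <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel_size
  starts <- seq(1, d[3], by = slab_width)
  trace <- data.frame(z = numeric(0), r_inner = numeric(0), r_outer = numeric(0))
  for (s in starts) {
    kk <- s:min(s + slab_width - 1, d[3])
    zr <- range(zs[kk])
    prof <- radial_profile(map, z_range = zr + c(-1e-9, 1e-9))
    det <- tryCatch(detect_leaflets(prof, prominence_fraction),
                    error = function(e) NULL)
    trace <- rbind(trace, data.frame(
      z = mean(zs[kk]),
      r_inner = if (is.null(det)) NA_real_ else det$r_inner,
      r_outer = if (is.null(det)) NA_real_ else det$r_outer))
  }
  rsel <- switch(leaflet, outer = trace$r_outer, inner = trace$r_inner,
                 mid = (trace$r_inner + trace$r_outer) / 2)
  okz <- is.finite(rsel)
  if (sum(okz) < 5)
    stop("too few slabs with two leaflet peaks (", sum(okz), ")", call. = FALSE)
  zv <- trace$z[okz]; rv <- rsel[okz]
  # constriction: interior minimum with room for a flank window on each side
  interior <- zv >= min(zv) + flank_window & zv <= max(zv) - flank_window
  if (!any(interior)) interior <- rep(TRUE, length(zv))
  z0 <- zv[interior][which.min(rv[interior])]
  fit_flank <- function(side) {
    sel <- if (side < 0)
      zv >= z0 - flank_window - flank_gap & zv <= z0 - flank_gap else
      zv >= z0 + flank_gap & zv <= z0 + flank_window + flank_gap
    if (sum(sel) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(rv[sel] ~ zv[sel]))[2])
  }
  s1 <- fit_flank(-1); s2 <- fit_flank(+1)
  kink <- if (is.na(s1) || is.na(s2)) NA_real_ else
    180 - abs(atan(s2) - atan(s1)) * 180 / pi
  out <- list(trace = trace,
              narrowest = 2 * min(rv), widest = 2 * max(rv),
              kink_angle = kink, z_constriction = z0,
              leaflet = leaflet,
              n_gaps = sum(!is.finite(rsel)))
  class(out) <- "axial_trace"
  out
}

#' @export
print.axial_trace <- function(x, ...) {
  cat(sprintf("<axial_trace> %d slabs (%d gaps), %s leaflet\n",
              nrow(x$trace), x$n_gaps, x$leaflet))
  cat(sprintf("  membrane diameter: narrowest %.1f A, widest %.1f A\n",
              x$narrowest, x$widest))
  cat(sprintf("  kink angle %.1f deg at z = %.1f A\n", x$kink_angle,
              x$z_constriction))
  invisible(x)
}
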