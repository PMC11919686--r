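# End-to-end pipelines chaining the analysis stages, with a validated
# parameter container and provenance output.

#' Pipeline configuration
#'
#' All stage parameters with their defaults: 50-Angstrom coat proximity,
#' 15-Angstrom minimal particle spacing, 150-voxel island removal, C18-C22
#' symmetry range with 1-Angstrom offset steps, 0.004 1/nm occupancy bin
#' width, 50-Angstrom edge margin. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return A `memcurve_config` list.
#' @export
memcurve_config <- function(...) {
  cfg <- list(
    min_component_voxels = 150,
    surface_step = NULL,            # A; default voxel size
    edge_margin = 50,               # A
    neighborhood_radius = NULL,     # A; default 3 x step
    proximity_distance = 50,        # A
    bin_width = 0.004,              # 1/nm
    c_max = NULL,                   # 1/nm
    min_particle_distance = 15,     # A
    k_clusters = 3,
    outlier_radius = 100,           # A
    outlier_max_angle = 30,         # degrees
    outlier_min_neighbors = 3,
    n_range = 18:22,
    offset_range = NULL,            # A
    offset_step = 1.0,              # A
    rotation_step = 0.5,            # degrees
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "memcurve_config"
  cfg
}

.write_provenance <- function(dir, cfg, inputs = character(0)) {
  lines <- c(sprintf("memcurve_version: %s", as.character(packageVersion("memcurve"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "config:",
             vapply(names(unclass(cfg)), function(nm)
               sprintf("  %s: %s", nm, paste(deparse(cfg[[nm]]), collapse = "")),
               character(1)))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs[file.exists(inputs)])
    lines <- c(lines, "inputs:",
               sprintf("  %s: %s", names(sums), unname(sums)))
  }
  writeLines(lines, file.path(dir, "run-metadata.yaml"))
}

#' Occupancy analysis pipeline
#'
#' Runs the full coat-occupancy workflow on a segmented label volume:
#' small-island cleanup, membrane surface extraction, curvature estimation,
#' edge exclusion, coat-proximity labeling, curvedness binning with the
#' saturation fit, and subtomogram-style particle preparation (spacing,
#' orientation priors, curvature clustering, orientation-consensus filter).
#'
#' @param labels a [label_volume()] with membrane and coat classes.
#' @param config a [memcurve_config()].
#' @param output_dir optional directory: profiles, particles and a provenance
#'   file are written there.
#' @return List with `surface`, `proximal`, `profile`, `fit`, `particles`.
#' @export
run_occupancy <- function(labels, config = memcurve_config(), output_dir = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(config, "memcurve_config"))
  for (cl in c("membrane", "coat"))
    if (!cl %in% names(labels$class_table))
      stop("configuration error: class '", cl, "' missing from class_table",
           call. = FALSE)
  vol <- remove_small_components(labels, config$min_component_voxels)
  surf <- extract_surface(vol, "membrane", step = config$surface_step,
                          edge_margin = config$edge_margin)
  surf <- estimate_curvature(surf, config$neighborhood_radius)
  surf <- exclude_edges(surf)
  prox <- label_proximal(surf, vol, config$proximity_distance)
  profile <- bin_occupancy(surf, prox, config$bin_width, config$c_max)
  fit <- fit_saturation(profile)
  parts <- as_particle_table(surf)
  parts <- enforce_min_distance(parts, config$min_particle_distance)
  parts <- orientations_from_normals(parts)
  parts <- filter_orientation_outliers(parts, config$outlier_radius,
                                       config$outlier_max_angle,
                                       config$outlier_min_neighbors)
  parts <- cluster_by_curvature(parts, config$k_clusters, seed = config$seed)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(as.data.frame(profile), file.path(output_dir, "occupancy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_particles(parts, file.path(output_dir, "particles.tsv"))
    write_surface_tsv(surf, file.path(output_dir, "surface.tsv"))
    .write_provenance(output_dir, config)
  }
  list(surface = surf, proximal = prox, profile = profile, fit = fit,
       particles = parts)
}

#' Symmetry and tube-profile pipeline
#'
#' Cn symmetry search on a density map followed by radial profiling (leaflet
#' radii, bilayer thickness, outer diameter) and, optionally, the axial
#' leaflet trace with the kink angle. Profiling can run on the raw or the
#' symmetrized map.
#'
#' @param map a [density_map()] with the ring/tube axis along z.
#' @param config a [memcurve_config()].
#' @param search run the symmetry search.
#' @param axial_trace compute the per-slice leaflet trace.
#' @param symmetrize profile the Cn-symmetrized map instead of the raw map.
#' @param output_dir optional output directory.
#' @return List with `symmetry` (or NULL), `profile`, `leaflets` (or NULL on
#'   detection failure), `outer_diameter` (or NA), `axial` (or NULL).
#' @export
run_symprof <- function(map, config = memcurve_config(), search = TRUE,
                        axial_trace = FALSE, symmetrize = FALSE,
                        output_dir = NULL) {
  stopifnot(inherits(map, "density_map"), inherits(config, "memcurve_config"))
  sym <- NULL
  if (search)
    sym <- search_symmetry(map, n_range = config$n_range,
                           offset_range = config$offset_range,
                           offset_step = config$offset_step,
                           rotation_step = config$rotation_step)
  pmap <- map
  if (symmetrize) {
    if (is.null(sym)) stop("symmetrize = TRUE requires search = TRUE", call. = FALSE)
    pmap <- apply_cn(map, sym$best$n, sym$best$axis_offset, sym$best$rotation)
  }
  profile <- radial_profile(pmap)
  leaf <- tryCatch(detect_leaflets(profile), error = function(e) NULL)
  od <- tryCatch(measure_outer_diameter(profile), error = function(e) NA_real_)
  ax <- if (axial_trace) axial_leaflet_trace(pmap) else NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(as.data.frame(profile), file.path(output_dir, "radial_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sym)) write_symmetry_tsv(sym, file.path(output_dir, "symmetry.tsv"))
    .write_provenance(output_dir, config)
  }
  list(symmetry = sym, profile = profile, leaflets = leaf,
       outer_diameter = od, axial = ax)
}
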