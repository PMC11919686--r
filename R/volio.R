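#' Density map container
#'
#' A 3D scalar density grid with isotropic physical voxel size. The physical
#' position of voxel `(i, j, k)` (0-based, x fastest) is
#' `origin + c(i, j, k) * voxel_size`, at the voxel center.
#'
#' @param values 3D numeric array of densities (arbitrary units); every axis
#'   must have length >= 2 and all values must be finite.
#' @param voxel_size voxel edge length in Angstrom (> 0, isotropic).
#' @param origin physical position (Angstrom) of the center of voxel (0,0,0).
#' @return An object of class `density_map`: a list with elements `values`,
#'   `voxel_size` and `origin`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 2L))
    stop("grid dimensions must be >= 2 on every axis", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector (Angstrom)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite (found NA/NaN/Inf)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.4g A/voxel, origin (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Default segmentation class table
#'
#' Named integer vector mapping class names to label integers. Background is
#' always label 0.
#' @export
default_class_table <- function() {
  c(background = 0L, membrane = 1L, coat = 2L, ribbon = 3L)
}

#' Label volume container
#'
#' An integer-class 3D segmentation grid sharing the coordinate conventions of
#' [density_map()]. Every voxel value must appear in `class_table` and
#' background must be label 0.
#'
#' @param labels 3D integer array of class labels.
#' @param voxel_size voxel edge length in Angstrom.
#' @param class_table named integer vector mapping class name -> label integer
#'   (see [default_class_table()]).
#' @param origin physical position (Angstrom) of the center of voxel (0,0,0).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, class_table = default_class_table(),
                         origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (is.null(names(class_table)) || any(names(class_table) == ""))
    stop("`class_table` must be a named integer vector (class name -> label)",
         call. = FALSE)
  class_table <- vapply(class_table, as.integer, integer(1))
  if (!"background" %in% names(class_table) || class_table[["background"]] != 0L)
    stop("`class_table` must map 'background' to label 0", call. = FALSE)
  if (anyDuplicated(class_table) || anyDuplicated(names(class_table)))
    stop("`class_table` labels and names must be unique", call. = FALSE)
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, unname(class_table))
  if (length(unknown))
    stop("label value(s) not in class_table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(voxel_size) || voxel_size <= 0 || !is.finite(voxel_size))
    stop("`voxel_size` must be a single positive number (Angstrom)", call. = FALSE)
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 class_table = class_table, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  counts <- tabulate(as.vector(x$labels) + 1L, nbins = max(x$class_table) + 1L)
  for (nm in names(x$class_table)) {
    lab <- x$class_table[[nm]]
    cat(sprintf("  %-10s (label %d): %d voxels\n", nm, lab, counts[lab + 1L]))
  }
  invisible(x)
}

#' Extract the binary mask of one segmentation class
#'
#' @param vol a [label_volume()].
#' @param class_name class name present in the class table.
#' @return 3D integer array of 0/1.
#' @export
class_mask <- function(vol, class_name) {
  stopifnot(inherits(vol, "label_volume"))
  if (!class_name %in% names(vol$class_table))
    stop("class '", class_name, "' not in class_table", call. = FALSE)
  m <- array(0L, dim(vol$labels))
  m[vol$labels == vol$class_table[[class_name]]] <- 1L
  m
}

# physical coordinates (A) of 0-based voxel indices (n x 3 matrix)
voxel_to_phys <- function(idx, voxel_size, origin) {
  sweep(idx * voxel_size, 2, origin, "+")
}

# ---------------------------------------------------------------------------
# MRC2014 I/O. Header words follow the CCP4/MRC2014 layout; data are written
# little-endian with x the fastest axis, matching R's column-major order.

.mrc_read_header <- function(con, path) {
  ints <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  flts <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  h <- list()
  h$nxyz <- ints(3)
  h$mode <- ints(1)
  h$nstart <- ints(3)
  h$mxyz <- ints(3)
  h$cella <- flts(3)
  h$cellb <- flts(3)
  h$mapcrs <- ints(3)
  h$dstats <- flts(3)
  h$ispg <- ints(1)
  h$nsymbt <- ints(1)
  h$extra <- readBin(con, "raw", n = 100)
  h$origin <- flts(3)
  h$map <- rawToChar(readBin(con, "raw", n = 4))
  h$machst <- readBin(con, "raw", n = 4)
  h$rms <- flts(1)
  h$nlabl <- ints(1)
  h$labels <- readBin(con, "raw", n = 800)
  if (any(h$nxyz <= 0) || any(is.na(h$nxyz)))
    stop("MRC format error in '", path, "': invalid dimensions (nx/ny/nz)",
         call. = FALSE)
  if (any(h$mxyz <= 0))
    stop("MRC format error in '", path, "': invalid sampling (mx/my/mz)",
         call. = FALSE)
  vox <- h$cella / h$mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("MRC format error in '", path, "': zero or invalid voxel size (cella/mx)",
         call. = FALSE)
  if (diff(range(vox)) > 1e-4 * mean(vox))
    stop("MRC format error in '", path, "': anisotropic voxel size not supported (cella)",
         call. = FALSE)
  h$voxel_size <- mean(vox)
  if (all(abs(h$origin) < 1e-20)) {
    h$origin_phys <- h$nstart * h$voxel_size
  } else {
    h$origin_phys <- h$origin
  }
  h
}

.mrc_read_data <- function(con, h, path) {
  n <- prod(h$nxyz)
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  vals <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop("MRC format error in '", path, "': unsupported mode ", h$mode,
         " (need 0, 1, 2 or 6)", call. = FALSE))
  if (length(vals) < n)
    stop("MRC format error in '", path, "': truncated data section (",
         length(vals), " of ", n, " voxels)", call. = FALSE)
  array(vals, dim = h$nxyz)
}

#' Read an MRC/CCP4 density map
#'
#' Reads a standard MRC volume (modes 0, 1, 2, 6). The voxel size is taken
#' from the header cell dimensions (`cella / mx`), the origin from the ORIGIN
#' header words (falling back to `nstart * voxel_size` when ORIGIN is zero).
#'
#' @param path path to an MRC file.
#' @return A [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) < 1024)
    stop("MRC format error in '", path, "': file shorter than the 1024-byte header",
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con, path)
  vals <- .mrc_read_data(con, h, path)
  density_map(vals, h$voxel_size, h$origin_phys)
}

.mrc_write <- function(values, voxel_size, origin, mode, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- dim(values)
  wi(d)                                  # nx ny nz
  wi(mode)                               # mode
  wi(c(0, 0, 0))                         # nstart
  wi(d)                                  # mx my mz
  wf(d * voxel_size)                     # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1, 2, 3))                         # mapc mapr maps
  rng <- range(values)
  wf(c(rng[1], rng[2], mean(values)))    # dmin dmax dmean
  wi(1)                                  # ispg (volume)
  wi(0)                                  # nsymbt
  extra <- raw(100)
  writeBin(extra, con)
  wf(origin)                             # ORIGIN (MRC2014)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(sd(as.numeric(values)))             # rms
  wi(0)                                  # nlabl
  writeBin(raw(800), con)
  if (mode == 2) {
    writeBin(as.numeric(values), con, size = 4, endian = "little")
  } else if (mode == 0) {
    writeBin(as.integer(values), con, size = 1)
  } else if (mode == 1) {
    writeBin(as.integer(values), con, size = 2, endian = "little")
  } else stop("unsupported write mode ", mode, call. = FALSE)
  invisible(NULL)
}

#' Write a density map as 32-bit float MRC
#'
#' @param map a [density_map()].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  if (!inherits(map, "density_map"))
    map <- density_map(map$values, map$voxel_size, map$origin)  # re-validate
  if (any(!is.finite(map$values)))
    stop("refusing to write map with non-finite values", call. = FALSE)
  .mrc_write(map$values, map$voxel_size, map$origin, mode = 2L, path = path)
  invisible(path)
}

#' Read an integer label volume from MRC
#'
#' @param path path to an integer-valued MRC file (mode 0, 1 or 6; float maps
#'   holding exact integers are accepted).
#' @param class_table named integer vector mapping class name -> label.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, class_table = default_class_table()) {
  m <- read_map(path)
  vals <- m$values
  if (max(abs(vals - round(vals))) > 1e-6)
    stop("MRC format error in '", path, "': label volume contains non-integer values",
         call. = FALSE)
  lab <- array(as.integer(round(vals)), dim(vals))
  label_volume(lab, m$voxel_size, class_table, m$origin)
}

#' Write a label volume as integer MRC
#'
#' Uses mode 0 (signed 8-bit) when all labels fit, otherwise mode 1 (16-bit).
#' @param vol a [label_volume()].
#' @param path output path.
#' @export
write_labels <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  mode <- if (max(vol$labels) < 128L) 0L else 1L
  .mrc_write(vol$labels, vol$voxel_size, vol$origin, mode = mode, path = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Particle tables: plain TSV with a header row; positions in Angstrom, ZYZ
# Euler angles in degrees, curvedness in 1/nm.

.particle_cols <- c("x", "y", "z", "euler_alpha", "euler_beta", "euler_gamma",
                    "curvedness", "cluster_id")

#' Construct a particle table
#'
#' @param df data frame with at least columns `x`, `y`, `z` (Angstrom).
#'   Optional: `euler_alpha`, `euler_beta`, `euler_gamma` (ZYZ, degrees),
#'   `nx`, `ny`, `nz` (unit normal), `curvedness` (1/nm), `cluster_id`.
#' @return The data frame with class `particle_table`.
#' @export
particle_table <- function(df) {
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss))
    stop("particle table schema error: missing mandatory column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("particle positions must be finite", call. = FALSE)
  class(df) <- unique(c("particle_table", class(df)))
  df
}

#' Read a particle table from TSV
#'
#' Tab-separated with a header row naming columns. Positions are Angstrom and
#' angles degrees. Orientation columns may be absent (read as unset).
#'
#' @param path input TSV path.
#' @return A [particle_table()].
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss))
    stop("particle table schema error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- intersect(c(.particle_cols, "nx", "ny", "nz"), names(df))
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(raw %in% c("", "NA")))
    if (length(bad))
      stop("particle table parse error in '", path, "': non-numeric value '",
           raw[bad[1]], "' in column '", cl, "', row ", bad[1], call. = FALSE)
    df[[cl]] <- val
  }
  particle_table(df)
}

#' Write a particle table as TSV
#'
#' @param table a [particle_table()] (or compatible data frame).
#' @param path output TSV path.
#' @export
write_particles <- function(table, path) {
  table <- particle_table(as.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert membrane surface points to a particle table
#'
#' Carries positions, normals and curvedness; orientations can then be assigned
#' with [orientations_from_normals()].
#'
#' @param surface a `surface_points` data frame from [extract_surface()].
#' @return A [particle_table()].
#' @export
as_particle_table <- function(surface) {
  stopifnot(inherits(surface, "surface_points"))
  df <- data.frame(x = surface$x, y = surface$y, z = surface$z,
                   nx = surface$nx, ny = surface$ny, nz = surface$nz)
  if (!is.null(surface$curvedness)) df$curvedness <- surface$curvedness
  particle_table(df)
}
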