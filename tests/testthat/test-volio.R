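test_that("density map MRC round trip preserves values, voxel size and origin", {
  set.seed(11)
  m <- density_map(array(rnorm(24 * 20 * 16), c(24, 20, 16)), 13.6,
                   c(-100, -100, -100))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  m2 <- read_map(path)
  expect_equal(dim(m2$values), dim(m$values))
  expect_equal(m2$voxel_size, 13.6, tolerance = 1e-6)
  expect_equal(m2$origin, c(-100, -100, -100), tolerance = 1e-5)
  # data are stored as 32-bit floats
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  # a second write/read of the already-float32 data is bit-exact
  write_map(m2, path)
  expect_identical(read_map(path)$values, m2$values)
})

test_that("map validation refuses bad input", {
  expect_error(density_map(array(1, c(1, 4, 4)), 1), "dimensions")
  expect_error(density_map(array(1, c(4, 4, 4)), 0), "voxel_size")
  v <- array(1, c(4, 4, 4)); v[2, 2, 2] <- NaN
  expect_error(density_map(v, 1), "finite")
  expect_error(read_map(withr::local_tempfile()), "not found")
})

test_that("truncated and malformed MRC files raise format errors", {
  path <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), path)
  expect_error(read_map(path), "header")
  m <- density_map(array(0:63 + 0.5, c(4, 4, 4)), 2)
  write_map(m, path)
  full <- readBin(path, "raw", n = file.size(path))
  writeBin(full[1:(length(full) - 40)], path)  # drop part of the data section
  expect_error(read_map(path), "truncated")
})

test_that("physical coordinate convention: origin + index * voxel, x fastest", {
  v <- array(0, c(8, 8, 8))
  v[3, 5, 7] <- 1  # 0-based index (2, 4, 6)
  m <- density_map(v, 5, c(10, 20, 30))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  m2 <- read_map(path)
  idx0 <- arrayInd(which(m2$values == 1), dim(m2$values)) - 1L
  expect_equal(as.vector(idx0), c(2, 4, 6))
  phys <- m2$origin + idx0 * m2$voxel_size
  expect_equal(as.vector(phys), c(10 + 2 * 5, 20 + 4 * 5, 30 + 6 * 5))
})

test_that("memcurve-written MRC is readable by an independent parser", {
  set.seed(2)
  m <- density_map(array(rnorm(32 * 24 * 16), c(32, 24, 16)), 4.25, c(-50, 20, 0))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  script <- paste0(
    "import gemmi, json, numpy as np; g = gemmi.read_ccp4_map('", path, "');",
    "a = np.array(g.grid, copy=False);",
    "print(json.dumps([list(a.shape), round(g.grid.spacing[0], 5), float(a.sum())]))")
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE,
                          stderr = FALSE),
                  warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(out))
  parsed <- strsplit(gsub("[][ ]", "", out), ",")[[1]]
  expect_equal(as.numeric(parsed[1:3]), c(32, 24, 16))
  expect_equal(as.numeric(parsed[4]), 4.25)
  expect_equal(as.numeric(parsed[5]), sum(m$values), tolerance = 1e-5)
})

test_that("label volumes round trip with class counts preserved", {
  set.seed(3)
  lab <- array(sample(0:2, 6 * 6 * 6, replace = TRUE), c(6, 6, 6))
  ct <- c(background = 0L, membrane = 1L, coat = 2L)
  lv <- label_volume(lab, 10, ct)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_labels(lv, path)
  lv2 <- read_labels(path, ct)
  expect_identical(lv2$labels, lv$labels)
  expect_equal(tabulate(lv2$labels + 1L), tabulate(lv$labels + 1L))
})

test_that("unknown labels are rejected with the offending value named", {
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 7L
  expect_error(label_volume(lab, 10, c(background = 0L, membrane = 1L, coat = 2L)),
               "7")
  expect_error(label_volume(array(1L, c(4, 4, 4)), 10, c(membrane = 1L)),
               "background")
})

test_that("particle tables round trip and validate their schema", {
  tb <- particle_table(data.frame(x = c(1, 2, 3), y = c(4, 5, 6),
                                  z = c(7, 8, 9),
                                  euler_alpha = c(0, 90, 180),
                                  euler_beta = c(0, 45, 90),
                                  euler_gamma = 0,
                                  curvedness = c(0.02, 0.04, 0.06)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_particles(tb, path)
  tb2 <- read_particles(path)
  expect_equal(as.data.frame(tb2), as.data.frame(tb))

  # orientations may be absent -> readable with orientations unset
  writeLines(c("x\ty\tz", "1\t2\t3"), path)
  tb3 <- read_particles(path)
  expect_equal(tb3$x, 1)
  expect_null(tb3$euler_alpha)

  # malformed numeric cell -> parse error naming the row
  writeLines(c("x\ty\tz", "1\t2\t3", "4\tbad\t6"), path)
  expect_error(read_particles(path), "row 2")

  # missing mandatory column -> schema error
  writeLines(c("x\ty", "1\t2"), path)
  expect_error(read_particles(path), "schema")
})
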