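#' Class scheme for categorical land-cover rasters
#'
#' A class scheme maps integer raster codes to land-cover class names and to
#' ordinal vulnerability grades (1 = least vulnerable, 6 = most vulnerable).
#' The vulnerability grade expresses how sensitive a cover type's structure and
#' function are to external disturbance: intensively managed covers (built-up)
#' are stable, semi-natural open covers are fragile.
#'
#' @param codes integer vector of unique raster codes.
#' @param names character vector of class names, one per code.
#' @param vulnerability integer vector of grades in 1..6, one per code.
#' @return An object of class `class_scheme`.
#' @seealso [ezhou_scheme()] for the default six-class scheme.
#' @export
class_scheme <- function(codes, names, vulnerability) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (length(names) != length(codes) || length(vulnerability) != length(codes))
    stop("codes, names and vulnerability must have equal length")
  vulnerability <- as.integer(vulnerability)
  if (any(vulnerability < 1L | vulnerability > 6L))
    stop("vulnerability grades must lie in 1..6")
  structure(
    list(codes = codes, names = as.character(names),
         vulnerability = vulnerability),
    class = "class_scheme")
}

#' Default six-class land-cover scheme
#'
#' Farmland, forest, built-up, water, aquaculture and other land, coded 1..6,
#' with vulnerability grades built-up (1, lowest), forest (2), farmland (3),
#' aquaculture (4), water (5) and other land (6, highest).
#'
#' @return A `class_scheme` with six classes.
#' @export
ezhou_scheme <- function() {
  class_scheme(
    codes = 1:6,
    names = c("farmland", "forest", "builtup", "water", "aquaculture", "other"),
    vulnerability = c(3L, 2L, 1L, 5L, 4L, 6L))
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Land-cover class scheme (", length(x$codes), " classes)\n", sep = "")
  print(data.frame(code = x$codes, name = x$names,
                   vulnerability = x$vulnerability), row.names = FALSE)
  invisible(x)
}

#' Read a class scheme from a YAML file
#'
#' Expects a top-level `classes` list whose entries have `code`, `name` and
#' `vulnerability` fields.
#'
#' @param path path to a YAML file.
#' @return A `class_scheme`.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$classes)) stop("YAML scheme must have a 'classes' list")
  class_scheme(
    codes = vapply(y$classes, function(z) as.integer(z$code), integer(1)),
    names = vapply(y$classes, function(z) as.character(z$name), character(1)),
    vulnerability = vapply(y$classes, function(z) as.integer(z$vulnerability),
                           integer(1)))
}

#' Construct a categorical land-cover grid
#'
#' The raster model used throughout the package: a 2-D integer matrix in
#' row-major, north-up orientation (row 1 is the northern edge), square cells,
#' and an origin at the upper-left corner. Cell area is `cell_size^2` square
#' metres; divide by 10,000 for hectares.
#'
#' @param values integer matrix of class codes (and possibly nodata).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the upper-left corner.
#' @param nodata integer code reserved for missing cells.
#' @param scheme a [class_scheme()]; when supplied, all non-nodata values are
#'   validated against it.
#' @return An object of class `land_grid`.
#' @export
land_grid <- function(values, cell_size = 100, origin = c(0, 0),
                      nodata = -9999L, scheme = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (cell_size <= 0) stop("cell_size must be positive")
  g <- structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.integer(nodata),
         scheme = scheme),
    class = "land_grid")
  if (!is.null(scheme)) validate_grid(g)
  g
}

validate_grid <- function(grid) {
  v <- grid$values
  bad <- setdiff(unique(v[v != grid$nodata & !is.na(v)]), grid$scheme$codes)
  if (length(bad))
    stop("grid contains codes outside the class scheme: ",
         paste(sort(bad), collapse = ", "))
  invisible(grid)
}

#' @export
print.land_grid <- function(x, ...) {
  cat("land_grid: ", nrow(x$values), " x ", ncol(x$values),
      " cells, cell size ", x$cell_size, " m (",
      format(grid_area_ha(x), big.mark = ","), " ha valid)\n", sep = "")
  tab <- table(x$values[x$values != x$nodata])
  if (!is.null(x$scheme)) {
    nm <- x$scheme$names[match(as.integer(names(tab)), x$scheme$codes)]
    names(tab) <- ifelse(is.na(nm), names(tab), nm)
  }
  print(tab)
  invisible(x)
}

#' Construct a zone grid
#'
#' Integer zone labels (>= 1) aligned to a companion land-cover grid; used for
#' per-town / per-region evaluation.
#'
#' @param values integer matrix of zone ids.
#' @inheritParams land_grid
#' @return An object of class `zone_grid`.
#' @export
zone_grid <- function(values, cell_size = 100, origin = c(0, 0),
                      nodata = -9999L) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.integer(nodata)),
    class = "zone_grid")
}

# area of valid (non-nodata) cells in hectares
grid_area_ha <- function(grid) {
  sum(grid$values != grid$nodata) * cell_area_ha(grid)
}

cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

#' Per-class areas of a land-cover grid, in hectares
#'
#' @param grid a [land_grid()] with a scheme.
#' @return Named numeric vector of areas (ha), one entry per scheme class
#'   (zero for absent classes).
#' @export
class_areas <- function(grid) {
  stopifnot(inherits(grid, "land_grid"), !is.null(grid$scheme))
  v <- grid$values[grid$values != grid$nodata]
  cnt <- tabulate(match(v, grid$scheme$codes), nbins = length(grid$scheme$codes))
  stats::setNames(cnt * cell_area_ha(grid), grid$scheme$names)
}

#' Read a raster grid from disk
#'
#' Supports the ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by north-up rows) and
#' plain single-band TIFF accompanied by an ESRI world file (`.tfw`) carrying
#' the georeference.
#'
#' @param path file path.
#' @param format `"ascii_grid"` or `"tiff"`; default guesses from the
#'   extension.
#' @param scheme optional [class_scheme()] used to validate values.
#' @param categorical logical; integer-code grid (default) or continuous
#'   surface. Continuous reads return a `land_grid`-shaped list with numeric
#'   values and no scheme.
#' @return A [land_grid()] (categorical) or a list with `values`, `cell_size`,
#'   `origin`, `nodata` (continuous).
#' @export
read_grid <- function(path, format = c("auto", "ascii_grid", "tiff"),
                      scheme = NULL, categorical = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ascii_grid") g <- read_ascii_grid(path, categorical)
  else g <- read_tiff_grid(path, categorical)
  if (categorical) {
    g <- land_grid(g$values, g$cell_size, g$origin, g$nodata, scheme)
  }
  g
}

read_ascii_grid <- function(path, categorical) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header, missing: ", paste(miss, collapse = ", "))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop("malformed ESRI ASCII grid: expected ", nrows * ncols,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  origin <- c(xll, yll + nrows * hdr$cellsize)  # upper-left corner
  if (categorical) storage.mode(m) <- "integer"
  list(values = m, cell_size = hdr$cellsize, origin = origin,
       nodata = as.integer(nodata))
}

read_tiff_grid <- function(path, categorical) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- m - 32768L  # undo the fixed signed-integer offset
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  if (!file.exists(tfw)) stop("world file not found: ", tfw)
  w <- scan(tfw, quiet = TRUE)
  if (length(w) != 6) stop("malformed world file: ", tfw)
  cell <- w[1]
  # world file references the center of the upper-left cell
  origin <- c(w[5] - cell / 2, w[6] + cell / 2)
  if (categorical) storage.mode(m) <- "integer"
  list(values = m, cell_size = cell, origin = origin, nodata = -9999L)
}

#' Write a raster grid to disk
#'
#' @param grid a [land_grid()], [zone_grid()] or continuous grid list.
#' @param path output path.
#' @param format `"ascii_grid"` or `"tiff"` (TIFF writes a `.tfw` world file
#'   alongside); default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("auto", "ascii_grid", "tiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  v <- grid$values
  if (format == "ascii_grid") {
    hdr <- c(
      paste("ncols", ncol(v)), paste("nrows", nrow(v)),
      paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
      paste("yllcorner",
            format(grid$origin[2] - nrow(v) * grid$cell_size, scientific = FALSE)),
      paste("cellsize", format(grid$cell_size, scientific = FALSE)),
      paste("NODATA_value", grid$nodata))
    body <- apply(v, 1, paste, collapse = " ")
    writeLines(c(hdr, body), path)
  } else {
    if (any(v != round(v)) || min(v) < -32768 || max(v) > 32767)
      stop("TIFF output supports integer grids in [-32768, 32767]; ",
           "use ascii_grid for continuous surfaces")
    # 16-bit samples with a fixed +32768 offset keep signed codes exact
    tiff::writeTIFF((v + 32768) / 65535, path, bits.per.sample = 16L,
                    reduce = FALSE)
    tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
    writeLines(format(c(grid$cell_size, 0, 0, -grid$cell_size,
                        grid$origin[1] + grid$cell_size / 2,
                        grid$origin[2] - grid$cell_size / 2),
                      scientific = FALSE), tfw)
  }
  invisible(path)
}

#' Check that grids share shape, cell size and origin
#'
#' Report-only: callers decide whether a failed report is fatal. Grids align
#' when shapes match exactly and cell sizes and origins agree to within 1e-6
#' of a cell.
#'
#' @param ... two or more grids (`land_grid`, `zone_grid`, driver stacks, or
#'   anything with `values`/`cell_size`/`origin`).
#' @return A list with elements `pass` (logical) and `mismatches`
#'   (character vector describing each disagreement).
#' @export
align_check <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && is.null(gs[[1]]$values) &&
      is.null(gs[[1]]$surfaces)) gs <- gs[[1]]
  if (length(gs) < 2L) stop("align_check needs at least two grids")
  dims <- lapply(gs, function(g) {
    v <- if (!is.null(g$surfaces)) g$surfaces[[1]] else g$values
    list(dim = dim(v), cell = g$cell_size, origin = g$origin)
  })
  ref <- dims[[1]]
  mism <- character(0)
  tol <- 1e-6 * ref$cell
  for (k in seq_along(dims)[-1]) {
    d <- dims[[k]]
    if (!identical(d$dim, ref$dim))
      mism <- c(mism, sprintf("grid %d shape %dx%d vs %dx%d", k,
                              d$dim[1], d$dim[2], ref$dim[1], ref$dim[2]))
    if (abs(d$cell - ref$cell) > tol)
      mism <- c(mism, sprintf("grid %d cellsize %g vs %g", k, d$cell, ref$cell))
    if (any(abs(d$origin - ref$origin) > tol))
      mism <- c(mism, sprintf("grid %d origin (%g, %g) vs (%g, %g)", k,
                              d$origin[1], d$origin[2],
                              ref$origin[1], ref$origin[2]))
  }
  list(pass = length(mism) == 0L, mismatches = mism)
}

assert_aligned <- function(...) {
  rep <- align_check(...)
  if (!rep$pass)
    stop("grids are not aligned: ", paste(rep$mismatches, collapse = "; "))
  invisible(TRUE)
}

#' Exact Euclidean distance transform
#'
#' Distance in metres from every cell center to the nearest target cell
#' center. Uses the two-pass squared-distance algorithm (exact, not
#' chamfer-approximate).
#'
#' @param targets logical matrix marking target cells.
#' @param cell_size cell edge length in metres.
#' @return Numeric matrix of distances (0 on targets).
#' @export
distance_surface <- function(targets, cell_size) {
  if (!any(targets)) stop("distance_surface: no target cells")
  nr <- nrow(targets); nc <- ncol(targets)
  inf <- .Machine$double.xmax / 4
  # pass 1: per row, squared distance along columns to nearest target in row
  d1 <- matrix(inf, nr, nc)
  cols <- seq_len(nc)
  for (r in seq_len(nr)) {
    tc <- which(targets[r, ])
    if (length(tc))
      d1[r, ] <- apply(outer(cols, tc, function(a, b) (a - b)^2), 1, min)
  }
  # pass 2: per column, minimize over rows of d1 + row offset squared
  rows <- seq_len(nr)
  off2 <- outer(rows, rows, function(a, b) (a - b)^2)  # nr x nr
  d <- matrix(0, nr, nc)
  for (cc in seq_len(nc)) {
    m <- off2 + matrix(d1[, cc], nr, nr, byrow = TRUE)  # [r, r'] term
    d[, cc] <- do.call(pmin, as.data.frame(m))          # min over r'
  }
  sqrt(d) * cell_size
}

#' Slope surface from elevation (Horn's method)
#'
#' 3x3 finite-difference slope in degrees; border cells use edge replication.
#'
#' @param elevation numeric matrix of elevations (metres).
#' @param cell_size cell edge length in metres.
#' @return Numeric matrix of slopes in degrees.
#' @export
slope_surface <- function(elevation, cell_size) {
  if (nrow(elevation) < 3L || ncol(elevation) < 3L)
    stop("slope_surface needs a grid of at least 3x3 cells")
  if (any(!is.finite(elevation))) stop("elevation must be finite")
  p <- pad_replicate(elevation)
  nr <- nrow(elevation); nc <- ncol(elevation)
  sh <- function(dr, dc) p[(1 + dr):(nr + dr) + 1 - 1, (1 + dc):(nc + dc) + 1 - 1]
  # neighbours: z1 z2 z3 / z4 . z6 / z7 z8 z9 (z1 = NW)
  z1 <- sh(0, 0); z2 <- sh(0, 1); z3 <- sh(0, 2)
  z4 <- sh(1, 0);               z6 <- sh(1, 2)
  z7 <- sh(2, 0); z8 <- sh(2, 1); z9 <- sh(2, 2)
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cell_size)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * cell_size)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

pad_replicate <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Bundle driver surfaces into an aligned stack
#'
#' Driver variables (distances to infrastructure and water, elevation, slope)
#' feed the suitability models. Min/max and mean/sd per surface are recorded
#' so standardization can travel with trained models.
#'
#' @param surfaces named list of numeric matrices, all the same shape.
#' @param cell_size cell edge length in metres.
#' @param origin (x, y) upper-left corner.
#' @return An object of class `driver_stack`.
#' @export
driver_stack <- function(surfaces, cell_size = 100, origin = c(0, 0)) {
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    stop("surfaces must be a named list")
  dims <- unique(lapply(surfaces, dim))
  if (length(dims) != 1L) stop("driver surfaces must share one shape")
  stats <- data.frame(
    name = names(surfaces),
    min = vapply(surfaces, min, numeric(1)),
    max = vapply(surfaces, max, numeric(1)),
    mean = vapply(surfaces, mean, numeric(1)),
    sd = vapply(surfaces, stats::sd, numeric(1)),
    row.names = NULL)
  structure(
    list(surfaces = surfaces, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), stats = stats),
    class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  d <- dim(x$surfaces[[1]])
  cat("driver_stack: ", length(x$surfaces), " surfaces, ",
      d[1], " x ", d[2], " cells\n", sep = "")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

# driver matrix (cells x features) for the given linear cell indices
driver_matrix <- function(drivers, idx = NULL) {
  mats <- drivers$surfaces
  if (is.null(idx)) idx <- seq_along(mats[[1]])
  X <- vapply(mats, function(m) m[idx], numeric(length(idx)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  colnames(X) <- names(mats)
  X
}
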