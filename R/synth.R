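#' Specification for a synthetic study landscape
#'
#' Defines the seeded synthetic world used to exercise the whole pipeline
#' without external GIS data: a spatially autocorrelated six-class landscape,
#' driver surfaces (distances to infrastructure and water, elevation, slope),
#' analysis zones, and a ground-truth transition process with known per-cell
#' probabilities.
#'
#' Defaults describe a 150 x 150 grid of 100 m cells (2250 ha) with class
#' proportions matching a mixed agricultural lake-plain region (farmland
#' dominant, substantial water and aquaculture), nine zones, and a mild
#' neighbourhood effect in the transition process.
#'
#' @param size grid edge length in cells.
#' @param cell_size cell edge in metres.
#' @param proportions named class proportions (sum to 1, scheme order).
#' @param autocorrelation spatial autocorrelation length in cells.
#' @param n_zones number of Voronoi analysis zones.
#' @param dem_roughness amplitude of the fractal elevation field (m).
#' @param persistence base log-odds bonus for a cell keeping its class.
#' @param beta named list: per class name, named coefficient vector on
#'   standardized drivers for transitions into that class.
#' @param eta coefficient on the neighbourhood fraction of the target class.
#' @param seed integer seed; every generated object is deterministic in it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 150, cell_size = 100,
                           proportions = c(farmland = 0.4436, forest = 0.0570,
                                           builtup = 0.1169, water = 0.2044,
                                           aquaculture = 0.1231,
                                           other = 0.0550),
                           autocorrelation = 8, n_zones = 9,
                           dem_roughness = 40,
                           persistence = 3.0,
                           beta = list(
                             farmland = c(slope = -0.5),
                             forest = c(elevation = 0.8, slope = 0.6),
                             builtup = c(distance_roads = -1.2,
                                         distance_urban_centers = -0.8),
                             water = c(distance_water = -1.0),
                             aquaculture = c(distance_water = -1.2,
                                             slope = -0.6),
                             other = c()),
                           eta = 0.5, seed = 1) {
  proportions <- proportions / sum(proportions)
  if (autocorrelation < 0) stop("autocorrelation length must be >= 0")
  structure(list(size = as.integer(size), cell_size = cell_size,
                 proportions = proportions,
                 autocorrelation = autocorrelation,
                 n_zones = as.integer(n_zones),
                 dem_roughness = dem_roughness,
                 persistence = persistence, beta = beta, eta = eta,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# separable Gaussian blur with edge renormalization (row-stochastic band
# matrix applied to both dimensions)
blur_matrix <- function(m, sd) {
  if (sd <= 0) return(m)
  band <- function(n) {
    idx <- seq_len(n)
    B <- exp(-outer(idx, idx, "-")^2 / (2 * sd^2))
    B[abs(outer(idx, idx, "-")) > 3 * sd] <- 0
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' One smooth latent field per class (seeded white noise blurred at the
#' autocorrelation length, re-standardized), with per-class additive offsets
#' calibrated so the argmax assignment hits the requested class proportions;
#' empirical shares land within about three percentage points of the spec on
#' grids of 100 x 100 and larger.
#'
#' @param spec a [synthetic_spec()].
#' @param scheme class scheme (default [ezhou_scheme()]).
#' @return A [land_grid()].
#' @export
generate_landscape <- function(spec, scheme = ezhou_scheme()) {
  k <- length(spec$proportions)
  n <- spec$size
  with_seed(spec$seed, {
    fields <- lapply(seq_len(k), function(i) {
      f <- blur_matrix(matrix(stats::rnorm(n * n), n, n),
                       spec$autocorrelation)
      (f - mean(f)) / stats::sd(f)
    })
    off <- log(as.numeric(spec$proportions))
    target <- as.numeric(spec$proportions)
    assign_cls <- function() {
      best <- fields[[1]] + off[1]
      cls <- matrix(1L, n, n)
      for (i in 2:k) {
        fi <- fields[[i]] + off[i]
        sel <- fi > best
        best[sel] <- fi[sel]
        cls[sel] <- i
      }
      cls
    }
    for (it in seq_len(200)) {
      cls <- assign_cls()
      share <- tabulate(cls, nbins = k) / (n * n)
      err <- target - share
      if (max(abs(err)) < 0.002) break
      off <- off + 2.5 * err
    }
    land_grid(matrix(scheme$codes[cls], n, n), spec$cell_size,
              nodata = -9999L, scheme = scheme)
  })
}

#' Generate Voronoi analysis zones
#'
#' @param spec a [synthetic_spec()].
#' @return A [zone_grid()] with `n_zones` contiguous zones.
#' @export
generate_zones <- function(spec) {
  n <- spec$size
  with_seed(spec$seed + 101L, {
    sr <- stats::runif(spec$n_zones, 1, n)
    sc <- stats::runif(spec$n_zones, 1, n)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    best <- (rows - sr[1])^2 + (cols - sc[1])^2
    z <- matrix(1L, n, n)
    for (i in seq_len(spec$n_zones)[-1]) {
      d <- (rows - sr[i])^2 + (cols - sc[i])^2
      sel <- d < best
      best[sel] <- d[sel]
      z[sel] <- i
    }
    zone_grid(z, spec$cell_size)
  })
}

# mark cells whose center lies within tol of segment (x1,y1)-(x2,y2),
# in cell-index coordinates (row, col)
rasterize_segment <- function(n, r1, c1, r2, c2, tol = 0.75) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr^2 + dc^2
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((rows - r1) * dr + (cols - c1) * dc) / len2))
  (rows - (r1 + t * dr))^2 + (cols - (c1 + t * dc))^2 <= tol^2
}

random_polyline_mask <- function(n, n_vertices) {
  vr <- stats::runif(n_vertices, 1, n)
  vc <- stats::runif(n_vertices, 1, n)
  mask <- matrix(FALSE, n, n)
  for (s in seq_len(n_vertices - 1))
    mask <- mask | rasterize_segment(n, vr[s], vc[s], vr[s + 1], vc[s + 1])
  mask
}

point_mask <- function(n, pr, pc) {
  mask <- matrix(FALSE, n, n)
  mask[cbind(pmin(pmax(round(pr), 1), n), pmin(pmax(round(pc), 1), n))] <- TRUE
  mask
}

#' Generate the eight driver surfaces for a synthetic landscape
#'
#' Random polyline features give distance-to-highway/railway/roads surfaces,
#' random points the town/urban-center distances, the landscape's own water
#' cells the distance-to-water surface, and a multi-octave fractal field the
#' elevation (slope derived by Horn's method). All surfaces share the
#' landscape's georeference.
#'
#' @param spec a [synthetic_spec()].
#' @param landscape the [land_grid()] the drivers accompany.
#' @return A [driver_stack()] with the eight standard surfaces.
#' @export
generate_drivers <- function(spec, landscape) {
  n <- spec$size
  cs <- spec$cell_size
  with_seed(spec$seed + 211L, {
    masks <- list(
      distance_highway = random_polyline_mask(n, 3),
      distance_railway = random_polyline_mask(n, 3),
      distance_roads = random_polyline_mask(n, 4) |
        random_polyline_mask(n, 3),
      distance_town_centers = point_mask(n, stats::runif(9, 1, n),
                                         stats::runif(9, 1, n)),
      distance_urban_centers = point_mask(n, stats::runif(2, 1, n),
                                          stats::runif(2, 1, n)))
    water_code <- landscape$scheme$codes[landscape$scheme$names == "water"]
    wmask <- landscape$values == water_code
    if (!any(wmask)) wmask <- point_mask(n, n / 2, n / 2)
    masks$distance_water <- wmask
    surfaces <- lapply(masks, distance_surface, cell_size = cs)
    dem <- matrix(0, n, n)
    if (spec$dem_roughness > 0) {
      for (s in c(32, 16, 8, 4)) {
        f <- blur_matrix(matrix(stats::rnorm(n * n), n, n), s)
        dem <- dem + f / stats::sd(f) * s
      }
      dem <- dem / stats::sd(dem) * spec$dem_roughness
      dem <- dem - min(dem)
    }
    surfaces$elevation <- dem
    surfaces$slope <- slope_surface(dem, cs)
    driver_stack(surfaces, cs, landscape$origin)
  })
}

#' Evolve a landscape under a known transition process
#'
#' Ground-truth generator for suitability recovery experiments. Per cell of
#' class i, the utility of ending in class j is
#' `persistence * 1(i == j) + beta_j' x + eta * neighfrac_j`, with `x` the
#' standardized drivers; the realized class is sampled from the softmax of
#' the utilities. Returns the realization together with the exact per-cell
#' probability surfaces so stochastic tests can use closed-form expectations.
#'
#' @param landscape starting [land_grid()].
#' @param drivers a [driver_stack()] aligned to it.
#' @param spec a [synthetic_spec()] carrying the transition model.
#' @return List: `grid` (evolved [land_grid()]), `prob` (named list of
#'   per-class probability matrices), `tally` (realized transition count
#'   matrix, scheme order).
#' @export
evolve_landscape <- function(landscape, drivers, spec) {
  sch <- landscape$scheme
  k <- length(sch$codes)
  n <- nrow(landscape$values)
  X <- driver_matrix(drivers)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, scale = scl)
  util <- matrix(0, n * n, k)
  for (j in seq_len(k)) {
    b <- spec$beta[[sch$names[j]]]
    if (length(b))
      util[, j] <- Xs[, names(b), drop = FALSE] %*% b
    if (spec$eta != 0)
      util[, j] <- util[, j] +
        spec$eta * as.vector(neighborhood_factor(landscape, sch$codes[j]))
  }
  cls1 <- match(as.vector(landscape$values), sch$codes)
  pers <- matrix(0, n * n, k)
  pers[cbind(seq_len(n * n), cls1)] <- spec$persistence
  eu <- exp(util + pers)
  P <- eu / rowSums(eu)
  with_seed(spec$seed + 431L, {
    u <- stats::runif(n * n)
    cum <- t(apply(P, 1, cumsum))
    cls2 <- rowSums(u > cum) + 1L
  })
  v2 <- matrix(sch$codes[cls2], n, n)
  tally <- matrix(tabulate((cls1 - 1L) * k + cls2, nbins = k * k), k, k,
                  byrow = TRUE, dimnames = list(sch$names, sch$names))
  prob <- lapply(seq_len(k), function(j) matrix(P[, j], n, n))
  names(prob) <- sch$names
  list(grid = land_grid(v2, spec$cell_size, landscape$origin,
                        landscape$nodata, sch),
       prob = prob, tally = tally)
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper producing everything the pipeline consumes: two dated
#' land-cover grids (the second evolved from the first under the ground-truth
#' process), the driver stack, analysis zones, and the policy masks
#' (permanent farmland, first- and second-grade conservation zones).
#'
#' @param spec a [synthetic_spec()].
#' @return List with `grid_t1`, `grid_t2`, `truth` (full [evolve_landscape()]
#'   result), `drivers`, `zones`, `masks`, and `spec`.
#' @export
synth_world <- function(spec = synthetic_spec()) {
  g1 <- generate_landscape(spec)
  drivers <- generate_drivers(spec, g1)
  truth <- evolve_landscape(g1, drivers, spec)
  zones <- generate_zones(spec)
  n <- spec$size
  sch <- g1$scheme
  farm_code <- sch$codes[sch$names == "farmland"]
  masks <- with_seed(spec$seed + 601L, {
    pf_field <- blur_matrix(matrix(stats::rnorm(n * n), n, n), 6)
    dw <- drivers$surfaces$distance_water
    list(
      permanent_farmland = g1$values == farm_code &
        pf_field > stats::quantile(pf_field, 0.5),
      conservation_grade1 = dw <= 500,
      conservation_grade2 = dw > 500 & dw <= 1500)
  })
  list(grid_t1 = g1, grid_t2 = truth$grid, truth = truth,
       drivers = drivers, zones = zones, masks = masks, spec = spec)
}

#' Printed land-change tables of the Ezhou study region
#'
#' The published class-area summary for 1991/2004/2013 and the two land-use
#' transition matrices (1991-2004 and 2004-2013), in hectares, shipped as
#' plain CSV and returned as package objects. These serve as deterministic
#' fixtures for the change-accounting operations.
#'
#' @return List with `table1` (matrix of class areas, rows = years),
#'   `table2` and `table3` ([transition_matrix()] objects).
#' @export
ezhou_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "landriskr",
                                  mustWork = TRUE)
  t1 <- utils::read.csv(path("ezhou_table1_class_areas.csv"),
                        check.names = FALSE)
  table1 <- as.matrix(t1[, -1])
  rownames(table1) <- as.character(t1$year)
  list(
    table1 = table1,
    table2 = read_transition_matrix(
      path("ezhou_table2_transition_1991_2004.csv"),
      from_date = 1991, to_date = 2004),
    table3 = read_transition_matrix(
      path("ezhou_table3_transition_2004_2013.csv"),
      from_date = 2004, to_date = 2013))
}
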