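#' Policy scenario specification
#'
#' Encodes a land-policy scenario as transformations of the simulator inputs:
#' an immutable-cell mask, multiplicative suitability boosts for transitions
#' into chosen classes (optionally restricted to a zone mask), minimum class
#' areas, and optional per-pair demand scaling.
#'
#' @param name scenario label.
#' @param immutable logical matrix of cells barred from any conversion, or
#'   NULL.
#' @param multipliers list of entries `list(target =` class code`, mask =`
#'   logical matrix or NULL`, factor =` positive number`)`.
#' @param floors named numeric vector of minimum class areas (ha), names are
#'   class names.
#' @param demand_adjustments optional n x n matrix of per-pair demand scale
#'   factors.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, immutable = NULL, multipliers = list(),
                          floors = NULL, demand_adjustments = NULL) {
  for (m in multipliers)
    if (is.null(m$factor) || m$factor <= 0)
      stop("multiplier factors must be positive")
  if (!is.null(floors) && any(floors < 0)) stop("floors must be non-negative")
  structure(list(name = name, immutable = immutable,
                 multipliers = multipliers, floors = floors,
                 demand_adjustments = demand_adjustments),
            class = "scenario_spec")
}

#' Build one of the four standard policy scenarios
#'
#' * S1 (status quo): no constraints; the simulation runs unmodified.
#' * S2 (farmland protection): planned permanent farmland is immutable and
#'   total farmland area may not fall below its baseline.
#' * S3 (ecological conservation): suitability of all transitions into forest
#'   and water is raised by 20% inside the first-grade conservation zone and
#'   by 10% inside the second-grade zone; forest and water areas may not fall
#'   below baseline.
#' * S4 (urban development): suitability of all transitions into built-up
#'   land is raised by 20% everywhere.
#'
#' @param name one of "S1", "S2", "S3", "S4".
#' @param scheme the [class_scheme()] in use.
#' @param baseline_areas named per-class baseline areas in ha (the scenario
#'   start year), as from [class_areas()].
#' @param permanent_farmland logical mask (required for S2).
#' @param conservation_grade1,conservation_grade2 logical masks (required for
#'   S3).
#' @return A [scenario_spec()].
#' @export
build_scenario <- function(name = c("S1", "S2", "S3", "S4"), scheme,
                           baseline_areas = NULL,
                           permanent_farmland = NULL,
                           conservation_grade1 = NULL,
                           conservation_grade2 = NULL) {
  name <- match.arg(name)
  code_of <- function(cl) scheme$codes[match(cl, scheme$names)]
  switch(name,
    S1 = scenario_spec("S1"),
    S2 = {
      if (is.null(permanent_farmland))
        stop("S2 requires a permanent-farmland mask")
      scenario_spec("S2", immutable = permanent_farmland,
                    floors = c(farmland = unname(baseline_areas["farmland"])))
    },
    S3 = {
      if (is.null(conservation_grade1) || is.null(conservation_grade2))
        stop("S3 requires both conservation-zone masks")
      mult <- list()
      for (cl in c("forest", "water")) {
        mult[[length(mult) + 1L]] <- list(target = code_of(cl),
                                          mask = conservation_grade1,
                                          factor = 1.2)
        mult[[length(mult) + 1L]] <- list(target = code_of(cl),
                                          mask = conservation_grade2,
                                          factor = 1.1)
      }
      scenario_spec("S3", multipliers = mult,
                    floors = c(forest = unname(baseline_areas["forest"]),
                               water = unname(baseline_areas["water"])))
    },
    S4 = scenario_spec("S4", multipliers = list(
      list(target = code_of("builtup"), mask = NULL, factor = 1.2))))
}

#' Apply a scenario to simulator inputs
#'
#' Suitability multipliers are applied and clipped to `[0, 1]`; the immutable
#' mask and class-area floors are merged into the configuration. An empty
#' spec returns the inputs unchanged.
#'
#' @param spec a [scenario_spec()].
#' @param suit a [suitability_stack()].
#' @param config a [sim_config()].
#' @return List with adjusted `suit` and `config`.
#' @export
apply_scenario <- function(spec, suit, config) {
  for (m in spec$multipliers) {
    for (key in names(suit$surfaces)) {
      ij <- as.integer(strsplit(key, "->", fixed = TRUE)[[1]])
      if (ij[2] != m$target || ij[1] == ij[2]) next
      s <- suit$surfaces[[key]]
      if (is.null(m$mask)) s <- s * m$factor
      else s[m$mask] <- s[m$mask] * m$factor
      suit$surfaces[[key]] <- pmin(s, 1)
    }
  }
  if (!is.null(spec$immutable)) {
    config$immutable <- if (is.null(config$immutable)) spec$immutable
      else (config$immutable | spec$immutable)
  }
  if (!is.null(spec$floors)) {
    config$floors <- if (is.null(config$floors)) spec$floors
      else {
        f <- config$floors
        for (nm in names(spec$floors))
          f[nm] <- max(f[nm], spec$floors[nm], na.rm = TRUE)
        f
      }
  }
  list(suit = suit, config = config)
}

#' Cap out-demands so floored classes never fall below their minimum
#'
#' When the cells a class can still afford to lose are fewer than its total
#' out-demand, out-demands are scaled pro-rata (largest-remainder rounding)
#' to exactly the affordable number. A class sitting at its floor has all
#' out-demands capped to zero.
#'
#' @param state current [land_grid()].
#' @param demands n x n integer matrix of cell-count demands.
#' @param floors named numeric vector of minimum areas (ha) per class name.
#' @return Capped demand matrix.
#' @export
enforce_floors <- function(state, demands, floors) {
  if (is.null(floors) || !length(floors)) return(demands)
  sch <- state$scheme
  cnt <- class_counts(state)
  ca <- cell_area_ha(state)
  for (nm in names(floors)) {
    k <- match(nm, sch$names)
    if (is.na(k)) stop("unknown class in floors: ", nm)
    floor_cells <- ceiling(floors[[nm]] / ca - 1e-9)
    if (cnt[k] < floor_cells)
      stop(sprintf("infeasible floor for %s: %d cells below the floor of %d",
                   nm, cnt[k], floor_cells))
    avail <- cnt[k] - floor_cells
    out <- demands[k, ]; out[k] <- 0L
    tot <- sum(out)
    if (tot <= avail) next
    if (avail == 0) {
      demands[k, -k] <- 0L
      next
    }
    exact <- out * avail / tot
    capped <- floor(exact)
    rem <- avail - sum(capped)
    if (rem > 0) {
      frac <- exact - capped
      give <- order(-frac, seq_along(frac))[seq_len(rem)]
      capped[give] <- capped[give] + 1L
    }
    capped[k] <- demands[k, k]
    demands[k, ] <- as.integer(capped)
  }
  demands
}

#' Project land cover and risk under policy scenarios
#'
#' Runs the Markov-CA simulation from a baseline grid out to a projection
#' horizon under each scenario, using the calibrated transition matrix
#' rescaled to the horizon (the calibrated per-iteration conversion rate is
#' held fixed). Emits land-cover snapshots at the requested iterations,
#' zonal ecological risk for the baseline and every snapshot (normalized
#' jointly within each scenario), and per-zone risk change ratios relative
#' to the baseline.
#'
#' @param initial baseline [land_grid()] (the scenario start year).
#' @param tm calibrated [transition_matrix()].
#' @param suit a [suitability_stack()] computed on the baseline grid.
#' @param specs named list of [scenario_spec()]s.
#' @param config a [sim_config()]; its `iterations` is overridden by the
#'   projection horizon.
#' @param zones optional [zone_grid()] for zonal risk.
#' @param snapshot_iters iterations at which to emit snapshots (default
#'   c(4, 14, 24, 34): years 2, 7, 12 and 17 at half-year steps).
#' @param snapshot_labels names for the snapshots (default the iterations).
#' @param calibration_iterations iterations the transition matrix spans at
#'   the calibrated rate (default 18).
#' @param risk_weights disturbance weights for [zonal_risk()].
#' @return Named list per scenario: `sim` (a `lulcc_sim`), `risk`
#'   (data.frame over baseline + snapshots), `change_ratio` (data.frame of
#'   (R_t - R_base) / R_base per unit and snapshot).
#' @export
run_projection <- function(initial, tm, suit, specs, config = sim_config(),
                           zones = NULL,
                           snapshot_iters = c(4L, 14L, 24L, 34L),
                           snapshot_labels = NULL,
                           calibration_iterations = 18L,
                           risk_weights = c(0.3, 0.5, 0.2)) {
  horizon <- max(snapshot_iters)
  if (is.null(snapshot_labels)) snapshot_labels <- as.character(snapshot_iters)
  tm_scaled <- tm
  tm_scaled$area <- tm$area * (horizon / calibration_iterations)
  out <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    tm_s <- tm_scaled
    if (!is.null(spec$demand_adjustments)) {
      adj <- tm_s$area * spec$demand_adjustments
      diag(adj) <- diag(tm_s$area)
      tm_s$area <- adj
    }
    adj <- apply_scenario(spec, suit, config)
    cfg <- adj$config
    cfg$iterations <- as.integer(horizon)
    sched <- demand_schedule(tm_s, horizon, cell_area_ha(initial))
    sim <- run_ca(initial, sched, adj$suit, cfg, snapshots = snapshot_iters)
    grids <- c(list(baseline = initial),
               stats::setNames(sim$snapshots[as.character(snapshot_iters)],
                               snapshot_labels))
    risk <- zonal_risk(grids, zones, weights = risk_weights)
    base <- risk[risk$date == "baseline", c("unit", "R")]
    cr <- risk[risk$date != "baseline", ]
    cr$change_ratio <- (cr$R - base$R[match(cr$unit, base$unit)]) /
      base$R[match(cr$unit, base$unit)]
    out[[nm]] <- list(sim = sim, risk = risk,
                      change_ratio = cr[, c("date", "unit", "change_ratio")])
  }
  out
}
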