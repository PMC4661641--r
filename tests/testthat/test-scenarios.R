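# shared small world with trained suitability for scenario runs
scen_setup <- local({
  env <- NULL
  function() {
    if (!is.null(env)) return(env)
    sp <- synthetic_spec(size = 60, seed = 3)
    w <- synth_world(sp)
    samp <- suppressWarnings(
      stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 150, seed = 2))
    models <- train_transition_models(samp)
    pairs <- list()
    for (i in 1:6) for (j in 1:6) if (i != j) pairs[[length(pairs) + 1]] <- c(i, j)
    suit <- suitability_stack(models, w$drivers, w$grid_t2, pairs = pairs)
    tm <- cross_tabulate(w$grid_t1, w$grid_t2)
    env <<- list(w = w, suit = suit, tm = tm, sch = w$grid_t1$scheme,
                 base_areas = class_areas(w$grid_t2))
    env
  }
})

test_that("scenario construction encodes the four policies", {
  e <- scen_setup()
  s1 <- build_scenario("S1", e$sch)
  expect_null(s1$immutable); expect_length(s1$multipliers, 0)
  expect_null(s1$floors)

  s2 <- build_scenario("S2", e$sch, e$base_areas,
                       permanent_farmland = e$w$masks$permanent_farmland)
  expect_equal(s2$floors[["farmland"]], e$base_areas[["farmland"]])
  expect_error(build_scenario("S2", e$sch, e$base_areas), "mask")

  s3 <- build_scenario("S3", e$sch, e$base_areas,
                       conservation_grade1 = e$w$masks$conservation_grade1,
                       conservation_grade2 = e$w$masks$conservation_grade2)
  expect_length(s3$multipliers, 4)
  expect_setequal(vapply(s3$multipliers, `[[`, numeric(1), "factor"),
                  c(1.2, 1.1))
  expect_equal(sort(names(s3$floors)), c("forest", "water"))
  expect_error(build_scenario("S3", e$sch, e$base_areas), "mask")

  s4 <- build_scenario("S4", e$sch)
  expect_equal(s4$multipliers[[1]]$target, 3L)  # built-up code
  expect_equal(s4$multipliers[[1]]$factor, 1.2)
  expect_null(s4$multipliers[[1]]$mask)
})

test_that("applying a scenario boosts, clips, and merges constraints", {
  e <- scen_setup()
  cfg <- sim_config(seed = 1)
  # empty spec: inputs unchanged
  out1 <- apply_scenario(scenario_spec("empty"), e$suit, cfg)
  expect_identical(out1$suit$surfaces, e$suit$surfaces)
  expect_identical(out1$config$immutable, cfg$immutable)

  # factor 1.2: 0.5 -> 0.6, 0.9 -> 1.0 (clipped)
  toy <- structure(list(surfaces = list(
    "1->3" = matrix(c(0.5, 0.9, 0.1, 0), 2, 2)), cell_size = 100,
    origin = c(0, 0)), class = "suitability_stack")
  spec <- scenario_spec("boost", multipliers = list(
    list(target = 3L, mask = NULL, factor = 1.2)))
  boosted <- apply_scenario(spec, toy, cfg)$suit$surfaces[["1->3"]]
  expect_equal(boosted[1, 1], 0.6)
  expect_equal(boosted[2, 1], 1.0)

  # masked boost touches only masked cells
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  specm <- scenario_spec("boostm", multipliers = list(
    list(target = 3L, mask = mask, factor = 1.2)))
  bm <- apply_scenario(specm, toy, cfg)$suit$surfaces[["1->3"]]
  expect_equal(bm[1, 1], 0.6)
  expect_equal(bm[2, 1], 0.9)

  # immutable masks merge with OR; floors take the max
  cfg2 <- sim_config(seed = 1, immutable = mask,
                     floors = c(farmland = 10))
  spec2 <- scenario_spec("s", immutable = !mask, floors = c(farmland = 5,
                                                            water = 2))
  merged <- apply_scenario(spec2, toy, cfg2)$config
  expect_true(all(merged$immutable))
  expect_equal(merged$floors[["farmland"]], 10)
  expect_equal(merged$floors[["water"]], 2)
})

test_that("floor enforcement caps out-demands pro-rata", {
  sch <- ezhou_scheme()
  g <- lg(matrix(rep(c(1L, 2L), c(60, 40)), 10, 10))
  demands <- matrix(0L, 6, 6)
  demands[1, 2] <- 15L; demands[1, 3] <- 10L  # 25 out of farmland
  # farmland has 60 cells = 60 ha; floor at 50 ha leaves 10 affordable
  capped <- enforce_floors(g, demands, c(farmland = 50))
  expect_equal(sum(capped[1, -1]), 10)
  expect_equal(capped[1, 2], 6)  # 15 * 10/25 = 6 exactly
  expect_equal(capped[1, 3], 4)

  # class at its floor: everything capped to zero
  at_floor <- enforce_floors(g, demands, c(farmland = 60))
  expect_equal(sum(at_floor[1, -1]), 0)

  # no floors: unchanged; untouched classes unaffected
  expect_identical(enforce_floors(g, demands, NULL), demands)
  demands2 <- demands; demands2[2, 1] <- 5L
  capped2 <- enforce_floors(g, demands2, c(farmland = 50))
  expect_equal(capped2[2, 1], 5L)

  # infeasible floor errors
  expect_error(enforce_floors(g, demands, c(farmland = 80)), "infeasible")

  # largest-remainder split sums exactly even with awkward ratios
  demands3 <- matrix(0L, 6, 6)
  demands3[1, 2:4] <- c(7L, 5L, 3L)
  capped3 <- enforce_floors(g, demands3, c(farmland = 53))
  expect_equal(sum(capped3[1, -1]), 7)
})

test_that("projections honor scenario contracts across every iteration", {
  e <- scen_setup()
  specs <- list(
    S1 = build_scenario("S1", e$sch),
    S2 = build_scenario("S2", e$sch, e$base_areas,
                        permanent_farmland = e$w$masks$permanent_farmland),
    S3 = build_scenario("S3", e$sch, e$base_areas,
                        conservation_grade1 = e$w$masks$conservation_grade1,
                        conservation_grade2 = e$w$masks$conservation_grade2),
    S4 = build_scenario("S4", e$sch))
  cfg <- sim_config(seed = 11)
  proj <- run_projection(e$w$grid_t2, e$tm, e$suit, specs, cfg,
                         zones = e$w$zones,
                         snapshot_iters = c(4L, 14L, 24L, 34L))
  ca <- cell_area_ha(e$w$grid_t2)

  # S1 equals a plain simulation with the same rescaled demands
  tm_scaled <- e$tm
  tm_scaled$area <- e$tm$area * (34 / 18)
  cfg1 <- cfg; cfg1$iterations <- 34L
  plain <- simulate_lulcc(e$w$grid_t2, tm_scaled, e$suit, cfg1)
  expect_identical(proj$S1$sim$final$values, plain$final$values)

  # S2: farmland never below its baseline area at any iteration, and
  # permanent farmland cells are bit-identical across all snapshots
  cc2 <- proj$S2$sim$report$class_counts
  expect_true(all(cc2[, "farmland"] * ca >=
                    e$base_areas[["farmland"]] - 1e-9))
  pf <- e$w$masks$permanent_farmland
  for (sn in proj$S2$sim$snapshots)
    expect_identical(sn$values[pf], e$w$grid_t2$values[pf])

  # S3: forest and water floors hold at every iteration
  cc3 <- proj$S3$sim$report$class_counts
  expect_true(all(cc3[, "forest"] * ca >= e$base_areas[["forest"]] - 1e-9))
  expect_true(all(cc3[, "water"] * ca >= e$base_areas[["water"]] - 1e-9))

  # S4 ends with at least as much built-up as S1
  cc1 <- proj$S1$sim$report$class_counts
  cc4 <- proj$S4$sim$report$class_counts
  expect_gte(cc4[nrow(cc4), "builtup"], cc1[nrow(cc1), "builtup"])

  # risk output covers baseline + 4 snapshots for 10 units, with ratios
  expect_equal(nrow(proj$S1$risk), 5 * 10)
  expect_equal(nrow(proj$S1$change_ratio), 4 * 10)
  base_R <- proj$S1$risk$R[proj$S1$risk$date == "baseline" &
                             proj$S1$risk$unit == "landscape"]
  r4 <- proj$S1$risk$R[proj$S1$risk$date == "4" &
                         proj$S1$risk$unit == "landscape"]
  cr <- proj$S1$change_ratio
  expect_equal(cr$change_ratio[cr$date == "4" & cr$unit == "landscape"],
               (r4 - base_R) / base_R)
})

test_that("boost monotonicity: stronger multipliers never shrink the target", {
  e <- scen_setup()
  dem <- matrix(0, 6, 6)
  dem[1, 3] <- 120; dem[4, 3] <- 40
  diag(dem) <- as.numeric(class_counts(e$w$grid_t2))
  tmb <- transition_matrix(dem, classes = e$sch$names)
  cfg <- sim_config(iterations = 6, seed = 9)
  runs <- lapply(c(1.0, 1.5), function(f) {
    spec <- scenario_spec("b", multipliers = list(
      list(target = 3L, mask = NULL, factor = f)))
    adj <- apply_scenario(spec, e$suit, cfg)
    sim <- simulate_lulcc(e$w$grid_t2, tmb, adj$suit, adj$config)
    sum(sim$final$values == 3L)
  })
  expect_gte(runs[[2]], runs[[1]])
})
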