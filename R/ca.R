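#' Simulation configuration for the Markov-CA model
#'
#' @param iterations number of CA iterations (default 18, i.e. half-year steps
#'   over a nine-year calibration period).
#' @param window odd neighbourhood window size (default 3).
#' @param seed integer seed for deterministic tie-breaking.
#' @param epsilon neighbourhood floor in `(0, 1]`; keeps isolated but highly
#'   suitable cells convertible (default 0.1).
#' @param immutable optional logical matrix of cells barred from conversion.
#' @param floors named numeric vector of minimum class areas (ha) enforced at
#'   every iteration by demand capping.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(iterations = 18, window = 3, seed = 1, epsilon = 0.1,
                       immutable = NULL, floors = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (window %% 2 != 1) stop("window must be odd")
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  structure(list(iterations = as.integer(iterations),
                 window = as.integer(window), seed = as.integer(seed),
                 epsilon = epsilon, immutable = immutable, floors = floors),
            class = "sim_config")
}

#' Per-iteration conversion demands from a transition matrix
#'
#' Converts each off-diagonal transition area to a cell count and apportions
#' it equally across iterations, assigning remainders to the earliest
#' iterations (largest-remainder rule) so totals are conserved exactly.
#'
#' @param tm a [transition_matrix()].
#' @param iterations number of CA iterations.
#' @param cell_area cell area in hectares.
#' @return An object of class `demand_schedule`: list of per-iteration n x n
#'   integer count matrices, with the rounded per-pair targets in attribute
#'   `targets`.
#' @export
demand_schedule <- function(tm, iterations, cell_area) {
  if (cell_area <= 0) stop("cell_area must be positive")
  a <- tm$area
  n <- nrow(a)
  counts <- round(a / cell_area)
  diag_counts <- diag(counts)
  off <- counts; diag(off) <- 0
  # feasibility: total out-demand from class i must not exceed its cells
  avail <- round(rowSums(a) / cell_area)
  for (i in seq_len(n)) {
    if (sum(off[i, ]) > avail[i]) {
      j <- which.max(off[i, ])
      stop(sprintf("demand from class %s (pair %s->%s) exceeds available cells",
                   tm$classes[i], tm$classes[i], tm$classes[j]))
    }
  }
  sched <- vector("list", iterations)
  base <- floor(off / iterations)
  rem <- off - base * iterations
  for (it in seq_len(iterations)) {
    m <- base + (rem >= it)       # earliest iterations absorb remainders
    storage.mode(m) <- "integer"
    dimnames(m) <- dimnames(a)
    sched[[it]] <- m
  }
  structure(sched, class = "demand_schedule", targets = off,
            classes = tm$classes)
}

#' Neighbourhood enrichment of a target class
#'
#' Per cell, the fraction of in-window neighbours (excluding the center and
#' nodata cells) already in the target class; windows truncate at the grid
#' border. This is the CA contiguity signal: conversions are attracted to
#' cells whose neighbourhood already carries the target class.
#'
#' @param grid a [land_grid()].
#' @param target_class class code.
#' @param window odd window size (default 3).
#' @return Numeric matrix in `[0, 1]`.
#' @export
neighborhood_factor <- function(grid, target_class, window = 3) {
  if (window %% 2 != 1) stop("window must be odd")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  is_t <- (v == target_class) * 1
  is_valid <- (v != grid$nodata) * 1
  h <- (window - 1L) %/% 2L
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    num[rs, cs] <- num[rs, cs] + is_t[rs + dr, cs + dc]
    den[rs, cs] <- den[rs, cs] + is_valid[rs + dr, cs + dc]
  }
  out <- num / pmax(den, 1)
  out[den == 0] <- 0
  out
}

#' Allocate one iteration of conversion demands
#'
#' For each ordered pair (i, j) with positive demand, candidate cells are the
#' current class-i cells not under an immutable mask; each candidate scores
#' `suitability(i->j) * (epsilon + neighbourhood_factor(j))`. Every pair
#' nominates its top-demand candidates; a cell claimed by several pairs goes
#' to the highest-scoring claim (fixed pair order breaks exact ties), and
#' unmet demand is reported so the caller can roll it forward. Exact score
#' ties within a pair are broken by seeded uniform jitter.
#'
#' @param state current [land_grid()].
#' @param suit a [suitability_stack()].
#' @param demands n x n integer matrix of cell-count demands (off-diagonal).
#' @param config a [sim_config()].
#' @param iter iteration number (folded into the tie-break seed).
#' @return List with `state` (next [land_grid()]), `met` and `shortfall`
#'   (n x n count matrices).
#' @export
allocate_iteration <- function(state, suit, demands, config, iter = 1L) {
  codes <- state$scheme$codes
  n <- length(codes)
  v <- state$values
  met <- matrix(0L, n, n); shortfall <- matrix(0L, n, n)
  dimnames(met) <- dimnames(shortfall) <- list(state$scheme$names,
                                               state$scheme$names)
  if (sum(demands) == 0)
    return(list(state = state, met = met, shortfall = shortfall))

  nf <- list()
  for (j in seq_len(n)) {
    if (any(demands[, j] > 0))
      nf[[j]] <- neighborhood_factor(state, codes[j], config$window)
  }
  cl_cell <- integer(0); cl_score <- numeric(0)
  cl_i <- integer(0); cl_j <- integer(0); cl_ord <- integer(0)
  pair_no <- 0L
  with_seed(config$seed + 7919L * as.integer(iter), {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- demands[i, j]
      if (i == j) next
      pair_no <- pair_no + 1L
      if (d == 0) next
      key <- trans_key(codes[i], codes[j])
      s <- suit$surfaces[[key]]
      cand <- which(v == codes[i])
      if (!is.null(config$immutable))
        cand <- cand[!config$immutable[cand]]
      if (!length(cand)) next
      sc <- (if (is.null(s)) 0 else s[cand]) * (config$epsilon + nf[[j]][cand])
      jit <- stats::runif(length(cand))
      take <- order(-sc, jit)[seq_len(min(d, length(cand)))]
      m <- length(take)
      cl_cell <- c(cl_cell, cand[take])
      cl_score <- c(cl_score, sc[take])
      cl_i <- c(cl_i, rep(i, m)); cl_j <- c(cl_j, rep(j, m))
      cl_ord <- c(cl_ord, rep(pair_no, m))
    }
  })
  if (length(cl_cell)) {
    # conflict resolution: best score per cell wins; fixed pair order on ties
    keep <- order(cl_cell, -cl_score, cl_ord)
    keep <- keep[!duplicated(cl_cell[keep])]
    v[cl_cell[keep]] <- codes[cl_j[keep]]
    won <- tabulate((cl_i[keep] - 1L) * n + cl_j[keep], nbins = n * n)
    met <- met + matrix(won, n, n, byrow = TRUE)
  }
  shortfall <- demands - met
  storage.mode(shortfall) <- "integer"
  next_state <- state
  next_state$values <- v
  list(state = next_state, met = met, shortfall = shortfall)
}

#' Run the Markov-constrained CA simulation
#'
#' Applies [allocate_iteration()] for `config$iterations` steps, drawing
#' per-iteration demands from [demand_schedule()], rolling unmet demand
#' forward, and (when `config$floors` is set) capping out-demands so floored
#' classes never drop below their minimum area. Land is conserved: the valid
#' cell count is constant and nodata never changes.
#'
#' @param initial the starting [land_grid()].
#' @param tm calibrated [transition_matrix()] fixing the conversion amounts.
#' @param suit a [suitability_stack()] for the off-diagonal transitions.
#' @param config a [sim_config()].
#' @param snapshots integer iterations at which to keep full grids (the final
#'   state is always kept).
#' @return An object of class `lulcc_sim`: list with `final`, `snapshots`
#'   (named list of grids), `report` (per-iteration class counts, demands met
#'   and shortfalls, and any residual unmet demand).
#' @export
simulate_lulcc <- function(initial, tm, suit, config = sim_config(),
                           snapshots = integer(0)) {
  sched <- demand_schedule(tm, config$iterations, cell_area_ha(initial))
  run_ca(initial, sched, suit, config, snapshots)
}

# core loop shared by simulate_lulcc and scenario projections
run_ca <- function(initial, sched, suit, config, snapshots = integer(0)) {
  n <- length(initial$scheme$codes)
  state <- initial
  carried <- matrix(0L, n, n)
  counts <- list(class_counts(initial))
  met_total <- matrix(0L, n, n,
                      dimnames = list(initial$scheme$names,
                                      initial$scheme$names))
  shortfall_log <- list()
  snaps <- list()
  iters <- length(sched)
  for (it in seq_len(iters)) {
    demands <- sched[[it]] + carried
    if (!is.null(config$floors))
      demands <- enforce_floors(state, demands, config$floors)
    step <- allocate_iteration(state, suit, demands, config, iter = it)
    state <- step$state
    carried <- step$shortfall
    met_total <- met_total + step$met
    shortfall_log[[it]] <- step$shortfall
    counts[[it + 1L]] <- class_counts(state)
    if (it %in% snapshots) snaps[[as.character(it)]] <- state
  }
  structure(
    list(final = state, snapshots = snaps,
         report = list(
           class_counts = do.call(rbind, counts),
           met = met_total,
           targets = attr(sched, "targets"),
           residual_unmet = carried,
           shortfalls = shortfall_log),
         config = config),
    class = "lulcc_sim")
}

class_counts <- function(grid) {
  v <- grid$values[grid$values != grid$nodata]
  stats::setNames(tabulate(match(v, grid$scheme$codes),
                           nbins = length(grid$scheme$codes)),
                  grid$scheme$names)
}

#' @export
print.lulcc_sim <- function(x, ...) {
  nit <- nrow(x$report$class_counts) - 1L
  cat("Markov-CA simulation:", nit, "iterations\n")
  cat("final class counts:\n")
  print(x$report$class_counts[nit + 1L, ])
  resid <- sum(x$report$residual_unmet)
  cat("unmet demand after final iteration:", resid, "cells\n")
  invisible(x)
}

#' Overall map accuracy (fraction of matching cells)
#'
#' @param simulated,observed aligned [land_grid()]s with one scheme.
#' @return Fraction of matching non-nodata cells.
#' @export
overall_accuracy <- function(simulated, observed) {
  assert_aligned(simulated, observed)
  ok <- simulated$values != simulated$nodata &
    observed$values != observed$nodata
  if (!any(ok)) stop("no overlapping valid cells")
  mean(simulated$values[ok] == observed$values[ok])
}

#' Cohen's Kappa between two categorical maps
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the cell-level
#' confusion matrix, with expected agreement from the marginal products.
#'
#' @param simulated,observed aligned [land_grid()]s with one scheme.
#' @return Kappa coefficient.
#' @export
kappa_coefficient <- function(simulated, observed) {
  assert_aligned(simulated, observed)
  ok <- simulated$values != simulated$nodata &
    observed$values != observed$nodata
  if (!any(ok)) stop("no overlapping valid cells")
  codes <- simulated$scheme$codes
  n <- length(codes)
  i <- match(simulated$values[ok], codes)
  j <- match(observed$values[ok], codes)
  cm <- matrix(tabulate((i - 1L) * n + j, nbins = n * n), n, n, byrow = TRUE)
  N <- sum(cm)
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe == 1) {
    if (po == 1) return(1)
    stop("kappa undefined: expected agreement is 1")
  }
  (po - pe) / (1 - pe)
}
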