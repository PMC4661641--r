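#' Min-max normalize metric observations
#'
#' Landscape metrics are normalized to `[0, 1]` before entering the
#' disturbance index. Normalization is done across the full collection of
#' observations passed in (all zones, classes and dates of one analysis), so
#' values stay comparable across dates. A constant collection carries no
#' relative signal and maps to 0, with a warning.
#'
#' @param x numeric vector of raw metric values (NAs pass through).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_metrics <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1])) return(x)
  if (r[1] == r[2]) {
    warning("constant metric collection: normalized to 0")
    out <- ifelse(is.na(x), NA_real_, 0)
    return(out)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Landscape disturbance index
#'
#' Weighted combination of normalized splitting index, patch density and
#' Shannon diversity for one class of one analysis unit:
#' `D_i = w1 * SPLIT'_i + w2 * PD'_i + w3 * SHDI'`. SHDI is the unit-level
#' landscape value shared by every class of the unit. Default weights
#' (0.3, 0.5, 0.2) emphasize fragmentation.
#'
#' @param split_n,pd_n,shdi_n normalized metric values in `[0, 1]`.
#' @param weights numeric length-3 non-negative weights on SPLIT, PD, SHDI.
#' @return Disturbance value in `[0, 1]` for unit-sum weights.
#' @export
disturbance_index <- function(split_n, pd_n, shdi_n,
                              weights = c(0.3, 0.5, 0.2)) {
  if (length(weights) != 3 || any(weights < 0))
    stop("weights must be three non-negative numbers")
  if (sum(weights) == 0) stop("weights must not all be zero")
  weights[1] * split_n + weights[2] * pd_n + weights[3] * shdi_n
}

#' Landscape vulnerability index per class
#'
#' Normalizes the ordinal vulnerability grades of a class scheme. The default
#' divides each grade by the grade total (grades 1..6 give 1/21 .. 6/21),
#' keeping every class strictly positive; min-max normalization (which zeroes
#' the least vulnerable class) is available as an alternative.
#'
#' @param scheme a [class_scheme()].
#' @param method `"sum"` (default) or `"minmax"`.
#' @return Named numeric vector of V values, one per class.
#' @export
vulnerability_index <- function(scheme, method = c("sum", "minmax")) {
  method <- match.arg(method)
  g <- as.numeric(scheme$vulnerability)
  v <- switch(method,
    sum = g / sum(g),
    minmax = if (max(g) == min(g)) rep(0, length(g))
             else (g - min(g)) / (max(g) - min(g)))
  stats::setNames(v, scheme$names)
}

#' Landscape ecological risk index
#'
#' `R = sum_i alpha_i * sqrt(D_i * V_i)` over the classes of one analysis
#' unit, with `alpha_i` the class area share. With D, V in `[0, 1]` and
#' shares summing to one, R lies in `[0, 1]`.
#'
#' @param alpha per-class area shares (must sum to 1).
#' @param D per-class disturbance values in `[0, 1]`.
#' @param V per-class vulnerability values in `[0, 1]`.
#' @return Risk value R.
#' @export
landscape_risk <- function(alpha, D, V) {
  if (any(alpha < 0) || any(D < 0) || any(V < 0))
    stop("landscape_risk: inputs must be non-negative")
  if (abs(sum(alpha) - 1) > 1e-6)
    stop("landscape_risk: area shares must sum to 1")
  sum(alpha * sqrt(D * V))
}

#' Risk category from a risk value
#'
#' Five 0.2-wide bands: low (0-0.2], relatively low (0.2-0.4], medium
#' (0.4-0.6], relatively high (0.6-0.8], high (0.8-1.0]. Bins are
#' right-closed; 0 falls in "low".
#'
#' @param R risk value(s) in `[0, 1]`.
#' @return Factor with levels low, relatively low, medium, relatively high,
#'   high.
#' @export
categorize_risk <- function(R) {
  if (any(R < 0 | R > 1, na.rm = TRUE))
    stop("risk values must lie in [0, 1]")
  cut(R, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
      labels = c("low", "relatively low", "medium", "relatively high", "high"),
      include.lowest = TRUE, right = TRUE)
}

#' Zonal landscape ecological risk
#'
#' End-to-end risk evaluation: per-zone class metrics, joint min-max
#' normalization across every (date, zone, class) observation in the call,
#' disturbance index, and the risk index with class area shares as weights.
#' Passing several dated grids in one call normalizes them together, so risk
#' values are comparable over time.
#'
#' @param grids a [land_grid()] or named list of them (names = date labels).
#' @param zones optional [zone_grid()]; when NULL only the whole landscape is
#'   evaluated.
#' @param weights disturbance weights, see [disturbance_index()].
#' @param vulnerability_method passed to [vulnerability_index()].
#' @param connectivity patch rule for the underlying metrics.
#' @return A data.frame with one row per (date, unit): `date`, `unit`, `R`,
#'   `category`, plus a `breakdown` attribute holding per-class alpha/D/V.
#' @export
zonal_risk <- function(grids, zones = NULL, weights = c(0.3, 0.5, 0.2),
                       vulnerability_method = "sum", connectivity = 8) {
  if (inherits(grids, "land_grid")) grids <- list(grids)
  if (is.null(names(grids)) || any(!nzchar(names(grids))))
    names(grids) <- paste0("t", seq_along(grids))
  scheme <- grids[[1]]$scheme
  V <- vulnerability_index(scheme, vulnerability_method)

  # collect raw metrics for every (date, unit)
  obs <- NULL
  for (d in names(grids)) {
    mt <- metric_table(grids[[d]], zones, connectivity)
    mt$date <- d
    obs <- rbind(obs, mt)
  }
  # joint normalization per metric across all observations
  obs$norm <- NA_real_
  for (m in c("SPLIT", "PD", "SHDI")) {
    sel <- obs$metric == m & (if (m == "SHDI") obs$class == "LAND"
                              else obs$class != "LAND")
    obs$norm[sel] <- normalize_metrics(obs$value[sel])
  }

  units <- unique(obs$unit)
  res <- NULL
  breakdown <- list()
  for (d in names(grids)) {
    areas_by_unit <- unit_class_areas(grids[[d]], zones)
    for (u in units) {
      o <- obs[obs$unit == u & obs$date == d, ]
      shdi_n <- o$norm[o$class == "LAND" & o$metric == "SHDI"]
      ar <- areas_by_unit[[u]]
      if (is.null(ar) || sum(ar) == 0 || !length(shdi_n) || is.na(shdi_n)) {
        res <- rbind(res, data.frame(date = d, unit = u, R = NA_real_,
                                     category = NA_character_))
        next
      }
      alpha <- ar / sum(ar)
      Dm <- numeric(length(scheme$names))
      for (k in seq_along(scheme$names)) {
        cl <- scheme$names[k]
        if (alpha[k] == 0) { Dm[k] <- 0; next }  # absent classes contribute 0
        sp <- o$norm[o$class == cl & o$metric == "SPLIT"]
        pd <- o$norm[o$class == cl & o$metric == "PD"]
        Dm[k] <- disturbance_index(sp, pd, shdi_n, weights)
      }
      R <- landscape_risk(alpha, Dm, V)
      res <- rbind(res, data.frame(date = d, unit = u, R = R,
                                   category = as.character(categorize_risk(R))))
      breakdown[[paste(d, u, sep = "/")]] <-
        data.frame(class = scheme$names, alpha = as.numeric(alpha),
                   D = Dm, V = as.numeric(V))
    }
  }
  rownames(res) <- NULL
  attr(res, "breakdown") <- breakdown
  res
}

# named list: unit -> per-class area vector (scheme order)
unit_class_areas <- function(grid, zones) {
  out <- list(landscape = class_areas(grid))
  if (!is.null(zones)) {
    zv <- zones$values
    for (z in sort(unique(zv[zv != zones$nodata]))) {
      gz <- grid
      gz$values[zv != z] <- gz$nodata
      out[[as.character(z)]] <- class_areas(gz)
    }
  }
  out
}
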