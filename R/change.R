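#' Construct a land-use transition matrix
#'
#' Entry (i, j) is the area in hectares that moved from class i at the first
#' date to class j at the second date. Row sums are the class areas at the
#' first date, column sums the class areas at the second.
#'
#' @param area numeric n x n matrix of hectares (non-negative).
#' @param classes character vector of class names in fixed scheme order.
#' @param from_date,to_date labels for the two dates.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(area, classes = rownames(area),
                              from_date = NA, to_date = NA) {
  area <- as.matrix(area)
  if (nrow(area) != ncol(area)) stop("transition matrix must be square")
  if (any(area < 0)) stop("transition areas must be non-negative")
  if (is.null(classes)) classes <- as.character(seq_len(nrow(area)))
  dimnames(area) <- list(from = classes, to = classes)
  structure(list(area = area, classes = classes,
                 from_date = from_date, to_date = to_date),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 2, ...) {
  cat("Land-use transition matrix", if (!is.na(x$from_date))
    paste0(" (", x$from_date, " -> ", x$to_date, ")"), " [ha]\n", sep = "")
  print(round(x$area, digits))
  cat("total:", format(sum(x$area), big.mark = ","), "ha; change:",
      sprintf("%.2f%%\n", dynamic_degree(x)))
  invisible(x)
}

#' Cross-tabulate land cover between two dates
#'
#' Overlays two aligned categorical grids of the same scheme and counts cells
#' per ordered class pair; cells that are nodata at either date are excluded
#' entirely so the grand total is identical at both dates.
#'
#' @param grid_t1,grid_t2 aligned [land_grid()]s sharing one scheme.
#' @param from_date,to_date optional date labels.
#' @return A [transition_matrix()] in hectares.
#' @export
cross_tabulate <- function(grid_t1, grid_t2, from_date = NA, to_date = NA) {
  assert_aligned(grid_t1, grid_t2)
  if (!identical(grid_t1$scheme$codes, grid_t2$scheme$codes))
    stop("grids must share one class scheme")
  sch <- grid_t1$scheme
  v1 <- grid_t1$values; v2 <- grid_t2$values
  ok <- v1 != grid_t1$nodata & v2 != grid_t2$nodata
  i <- match(v1[ok], sch$codes); j <- match(v2[ok], sch$codes)
  n <- length(sch$codes)
  cnt <- matrix(tabulate((i - 1L) * n + j, nbins = n * n), n, n, byrow = TRUE)
  transition_matrix(cnt * cell_area_ha(grid_t1), classes = sch$names,
                    from_date = from_date, to_date = to_date)
}

#' Dynamic degree index of land change
#'
#' The converted (off-diagonal) area as a percentage of total landscape area
#' over the period: the overall rate of land conversion.
#'
#' @param tm a [transition_matrix()].
#' @return Percentage in `[0, 100]`.
#' @export
dynamic_degree <- function(tm) {
  a <- tm$area
  tot <- sum(a)
  if (tot <= 0) stop("dynamic_degree: zero total area")
  (tot - sum(diag(a))) / tot * 100
}

#' Net area change per class
#'
#' Column sum minus row sum for every class: positive values are net gains.
#' Always sums to zero across classes.
#'
#' @param tm a [transition_matrix()].
#' @return Named numeric vector of hectares.
#' @export
net_change <- function(tm) {
  colSums(tm$area) - rowSums(tm$area)
}

#' Row-stochastic transition probabilities
#'
#' Divides each row by its sum. Classes absent at the first date (zero row)
#' get a unit self-transition so the matrix stays row-stochastic.
#'
#' @param tm a [transition_matrix()].
#' @return n x n numeric matrix with unit row sums.
#' @export
transition_probabilities <- function(tm) {
  a <- tm$area
  rs <- rowSums(a)
  p <- a / ifelse(rs > 0, rs, 1)
  for (i in which(rs == 0)) p[i, i] <- 1
  p
}

#' Summarize conversions into one class
#'
#' Totals the off-diagonal column of `to_class` (area gained from other
#' classes) and the share each source contributed. An optional subset of
#' sources returns the partial total and its share of the full total.
#'
#' @param tm a [transition_matrix()].
#' @param to_class target class name (or index).
#' @param from_classes optional subset of source class names.
#' @return List with `total` (ha), `shares` (named, fractions of total) and,
#'   when `from_classes` is given, `subset_total` and `subset_share`.
#' @export
conversion_summary <- function(tm, to_class, from_classes = NULL) {
  a <- tm$area
  j <- class_index(tm, to_class)
  col <- a[, j]
  col[j] <- 0
  total <- sum(col)
  if (total == 0)
    return(list(total = 0, shares = stats::setNames(numeric(0), character(0))))
  shares <- col[-j] / total
  out <- list(total = total, shares = shares)
  if (!is.null(from_classes)) {
    ii <- vapply(from_classes, function(cl) class_index(tm, cl), integer(1))
    out$subset_total <- sum(col[ii])
    out$subset_share <- out$subset_total / total
  }
  out
}

class_index <- function(tm, cl) {
  if (is.character(cl)) {
    i <- match(cl, tm$classes)
    if (is.na(i)) stop("unknown class: ", cl)
    return(i)
  }
  as.integer(cl)
}

#' Write / read a transition matrix as CSV
#'
#' Plain CSV with class names as header row and first column; date labels go
#' in a comment-free side file-naming convention (they are arguments on read).
#'
#' @param tm a [transition_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [transition_matrix()] (read).
#' @export
write_transition_matrix <- function(tm, path) {
  utils::write.csv(as.data.frame(tm$area), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @param from_date,to_date optional date labels attached on read.
#' @export
read_transition_matrix <- function(path, from_date = NA, to_date = NA) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  transition_matrix(as.matrix(df), classes = rownames(df),
                    from_date = from_date, to_date = to_date)
}
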