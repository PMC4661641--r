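# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

trans_key <- function(i, j) paste0(i, "->", j)

#' Stratified sampling of observed land conversions
#'
#' For every ordered class pair (i, j) observed between two dates, draws up to
#' `n_per_type` positive cells (class i at the first date, j at the second)
#' and an equal number of negative cells (class i that did not convert to j),
#' uniformly without replacement under the seed. Transitions with fewer
#' occurrences than requested take everything available, with a warning.
#'
#' @param grid_t1,grid_t2 aligned [land_grid()]s sharing one scheme.
#' @param drivers a [driver_stack()] aligned to the grids.
#' @param n_per_type samples per conversion type (default 500).
#' @param seed integer seed; sampling is reproducible given the seed.
#' @param pairs optional list of `c(i, j)` code pairs; default all observed
#'   ordered pairs including persistence.
#' @return Named list (keys `"i->j"`) of `sample_set` data.frames with the
#'   driver features, `label` (+1/-1) and cell `row`/`col`.
#' @export
stratified_sample <- function(grid_t1, grid_t2, drivers, n_per_type = 500,
                              seed = 1, pairs = NULL) {
  assert_aligned(grid_t1, grid_t2, drivers)
  v1 <- grid_t1$values; v2 <- grid_t2$values
  ok <- v1 != grid_t1$nodata & v2 != grid_t2$nodata
  codes <- grid_t1$scheme$codes
  if (is.null(pairs)) {
    pairs <- list()
    for (i in codes) for (j in codes) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  nr <- nrow(v1)
  out <- list()
  with_seed(seed, {
    for (p in pairs) {
      i <- p[1]; j <- p[2]
      pos_idx <- which(ok & v1 == i & v2 == j)
      neg_idx <- which(ok & v1 == i & v2 != j)
      key <- trans_key(i, j)
      if (!length(pos_idx) || !length(neg_idx)) {
        out[[key]] <- empty_sample_set(drivers, key)
        next
      }
      n <- min(n_per_type, length(pos_idx), length(neg_idx))
      if (n < n_per_type)
        warning(sprintf("transition %s: only %d balanced samples available",
                        key, n))
      pos <- if (length(pos_idx) > n) sample(pos_idx, n) else pos_idx
      neg <- if (length(neg_idx) > n) sample(neg_idx, n) else neg_idx
      idx <- c(pos, neg)
      X <- driver_matrix(drivers, idx)
      ss <- data.frame(X, check.names = FALSE)
      ss$label <- rep(c(1, -1), c(length(pos), length(neg)))
      ss$row <- ((idx - 1L) %% nr) + 1L
      ss$col <- ((idx - 1L) %/% nr) + 1L
      attr(ss, "transition") <- key
      attr(ss, "features") <- colnames(X)
      class(ss) <- c("sample_set", "data.frame")
      out[[key]] <- ss
    }
  })
  out
}

empty_sample_set <- function(drivers, key) {
  ss <- data.frame(matrix(numeric(0), 0, length(drivers$surfaces),
                          dimnames = list(NULL, names(drivers$surfaces))))
  ss$label <- numeric(0); ss$row <- integer(0); ss$col <- integer(0)
  attr(ss, "transition") <- key
  attr(ss, "features") <- names(drivers$surfaces)
  class(ss) <- c("sample_set", "data.frame")
  ss
}

#' Fit a least-squares support vector machine
#'
#' Binary LSSVM with an RBF kernel. Training reduces to one linear (KKT)
#' system: `[[0, 1'], [1, K + I/gamma]] %*% c(b, alpha) = c(0, y)` with
#' `K_mn = exp(-||x_m - x_n||^2 / (2 sigma^2))` on standardized features.
#' The decision function is `f(x) = sum_m alpha_m K(x, x_m) + b`.
#'
#' @param x numeric matrix of features (rows = samples) or a `sample_set`.
#' @param y labels in {+1, -1}; taken from the sample set when omitted.
#' @param gamma regularization weight (larger = closer interpolation).
#' @param sigma RBF kernel width on standardized features; the default
#'   `sqrt(d)` (d = number of features) scales the kernel to the typical
#'   inter-point distance in d dimensions.
#' @return An object of class `lssvm` with coefficients `alpha`, bias `b`,
#'   the standardized training matrix, feature statistics, and the KKT
#'   residual of the solve.
#' @export
lssvm <- function(x, y = NULL, gamma = 1, sigma = NULL) {
  if (inherits(x, "sample_set")) {
    feats <- attr(x, "features")
    y <- x$label
    x <- as.matrix(x[, feats, drop = FALSE])
  }
  x <- as.matrix(x)
  if (is.null(sigma)) sigma <- sqrt(ncol(x))
  if (is.null(y) || length(y) != nrow(x)) stop("labels must match rows of x")
  if (length(unique(sign(y))) < 2) stop("lssvm needs both labels present")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(x, center = ctr, scale = scl)
  K <- rbf_kernel(Xs, Xs, sigma)
  n <- nrow(Xs)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular LSSVM system (duplicate samples with opposite labels?): ",
         conditionMessage(e)))
  res <- max(abs(A %*% sol - rhs))
  structure(
    list(alpha = sol[-1], b = sol[1], X = unclass(Xs)[, , drop = FALSE],
         gamma = gamma, sigma = sigma, center = ctr, scale = scl,
         features = colnames(x), kkt_residual = res,
         transition = attr(x, "transition")),
    class = "landrisk_lssvm")
}

rbf_kernel <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' @export
print.landrisk_lssvm <- function(x, ...) {
  cat("LSSVM (RBF kernel), ", nrow(x$X), " support samples, gamma = ",
      x$gamma, ", sigma = ", x$sigma, "\n", sep = "")
  cat("KKT residual:", format(x$kkt_residual, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.landrisk_lssvm <- function(object, ...) c(b = object$b, alpha = object$alpha)

#' Decision values for new feature rows
#'
#' @param object a fitted [lssvm()].
#' @param newdata numeric matrix with the model's feature columns (raw scale;
#'   standardization statistics travel with the model).
#' @param ... unused.
#' @return Numeric vector of decision values (positive = class +1 side).
#' @export
predict.landrisk_lssvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$features))
    newdata <- newdata[, object$features, drop = FALSE]
  Zs <- scale(newdata, center = object$center, scale = object$scale)
  K <- rbf_kernel(unclass(Zs), object$X, object$sigma)
  drop(K %*% object$alpha + object$b)
}

#' @export
residuals.landrisk_lssvm <- function(object, ...) {
  # from the KKT system, y_m - f(x_m) = alpha_m / gamma
  drop(object$alpha / object$gamma)
}

#' Train LSSVM models for every sampled transition
#'
#' One model per conversion type; transitions without usable samples are
#' skipped (their suitability falls back to a constant-zero surface).
#'
#' @param samples result of [stratified_sample()].
#' @param gamma,sigma hyperparameters passed to [lssvm()].
#' @return Named list of `lssvm` models keyed by transition.
#' @export
train_transition_models <- function(samples, gamma = 1, sigma = NULL) {
  out <- list()
  for (key in names(samples)) {
    ss <- samples[[key]]
    if (nrow(ss) < 2 || length(unique(ss$label)) < 2) next
    out[[key]] <- lssvm(ss, gamma = gamma, sigma = sigma)
  }
  out
}

#' Suitability surface from a trained model
#'
#' Computes decision values for the cells of the source mask and rescales
#' them to `[0, 1]` by min-max over the mask; constant decisions map to 0.5
#' and non-source cells to 0. An optional logistic squash
#' `1 / (1 + exp(-f))` is available instead of min-max.
#'
#' @param model a fitted [lssvm()] (or NULL for the constant-zero fallback).
#' @param drivers a [driver_stack()].
#' @param source_mask logical matrix of cells currently in the source class.
#' @param mapping `"minmax"` (default) or `"logistic"`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
predict_suitability <- function(model, drivers, source_mask,
                                mapping = c("minmax", "logistic")) {
  mapping <- match.arg(mapping)
  out <- matrix(0, nrow(source_mask), ncol(source_mask))
  if (!any(source_mask)) {
    warning("predict_suitability: empty source mask")
    return(out)
  }
  if (is.null(model)) return(out)  # untrained transition: fallback 0
  idx <- which(source_mask)
  f <- predict(model, driver_matrix(drivers, idx))
  s <- if (mapping == "logistic") 1 / (1 + exp(-f)) else {
    r <- range(f)
    if (r[1] == r[2]) rep(0.5, length(f)) else (f - r[1]) / (r[2] - r[1])
  }
  out[idx] <- s
  out
}

#' Build a suitability stack for a set of transitions
#'
#' @param models named list from [train_transition_models()].
#' @param drivers a [driver_stack()].
#' @param grid the current [land_grid()] providing source masks.
#' @param pairs list of `c(i, j)` code pairs to produce (default: all model
#'   keys).
#' @param mapping passed to [predict_suitability()].
#' @return An object of class `suitability_stack`: named list of `[0,1]`
#'   surfaces keyed `"i->j"`.
#' @export
suitability_stack <- function(models, drivers, grid, pairs = NULL,
                              mapping = "minmax") {
  keys <- if (is.null(pairs)) names(models) else
    vapply(pairs, function(p) trans_key(p[1], p[2]), character(1))
  surfaces <- list()
  for (key in keys) {
    ij <- as.integer(strsplit(key, "->", fixed = TRUE)[[1]])
    mask <- grid$values == ij[1]
    surfaces[[key]] <- if (any(mask))
      predict_suitability(models[[key]], drivers, mask, mapping)
    else matrix(0, nrow(grid$values), ncol(grid$values))
  }
  structure(list(surfaces = surfaces, cell_size = grid$cell_size,
                 origin = grid$origin, mapping = mapping),
            class = "suitability_stack")
}

#' Ranking quality (AUC) of a model on held-out samples
#'
#' Area under the ROC curve by the rank statistic (equivalent to the
#' Mann-Whitney U scaled to `[0, 1]`).
#'
#' @param model a fitted [lssvm()].
#' @param held_out a `sample_set` with both labels present.
#' @return AUC in `[0, 1]`, or `NA` for a one-class set.
#' @export
evaluate_suitability <- function(model, held_out) {
  y <- held_out$label
  if (length(unique(y)) < 2) {
    warning("one-class held-out set: AUC undefined")
    return(NA_real_)
  }
  f <- predict(model, as.matrix(held_out[, attr(held_out, "features"),
                                         drop = FALSE]))
  r <- rank(f)
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  (sum(r[y > 0]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
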