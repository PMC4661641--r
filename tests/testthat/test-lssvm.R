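# small synthetic world reused across LSSVM tests
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- synth_world(synthetic_spec(size = 80, seed = 19))
    w
  }
})

test_that("stratified sampling is balanced, capped, and seed-deterministic", {
  w <- small_world()
  s1 <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 100, seed = 4))
  expect_length(s1, 36)
  big <- s1[["1->1"]]  # persistence of the dominant class: plenty of cells
  expect_equal(sum(big$label == 1), 100)
  expect_equal(sum(big$label == -1), 100)

  # shortfall: a transition with fewer occurrences than requested takes all
  counts <- w$truth$tally
  rare <- which(counts > 0 & counts < 100, arr.ind = TRUE)[1, ]
  expect_warning(
    s_rare <- stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 100,
                                seed = 4, pairs = list(unname(rare))),
    "available")
  key <- paste0(rare[1], "->", rare[2])
  expect_lte(sum(s_rare[[key]]$label == 1), counts[rare[1], rare[2]])
  expect_equal(sum(s_rare[[key]]$label == 1), sum(s_rare[[key]]$label == -1))

  # determinism under the seed
  s2 <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 100, seed = 4))
  expect_identical(s1[["1->3"]][, c("row", "col")],
                   s2[["1->3"]][, c("row", "col")])

  # unobserved transitions yield flagged empty sets
  empties <- names(s1)[vapply(s1, nrow, integer(1)) == 0]
  zero_pairs <- which(counts == 0, arr.ind = TRUE)
  if (nrow(zero_pairs)) {
    k0 <- paste0(zero_pairs[1, 1], "->", zero_pairs[1, 2])
    expect_true(k0 %in% empties)
  }
})

test_that("the LSSVM solves its KKT system exactly", {
  # 3-sample system checked against an independent dense construction
  x <- matrix(c(0, 1, 2), 3, 1)
  y <- c(1, 1, -1)
  m <- lssvm(x, y, gamma = 5, sigma = 1.5)
  xs <- (x - mean(x)) / sd(x)
  K <- exp(-as.matrix(dist(xs))^2 / (2 * 1.5^2))
  A <- rbind(c(0, 1, 1, 1), cbind(1, K + diag(3) / 5))
  sol <- solve(A, c(0, y))
  expect_equal(m$b, unname(sol[1]), tolerance = 1e-10)
  expect_equal(unname(m$alpha), unname(sol[-1]), tolerance = 1e-10)
  expect_lt(m$kkt_residual, 1e-8)

  # separable two-point problem
  m2 <- lssvm(matrix(c(0, 1), 2, 1), c(1, -1), gamma = 100, sigma = 1)
  f <- predict(m2, matrix(c(0, 1), 2, 1))
  expect_gt(f[1], 0); expect_lt(f[2], 0)

  # interpolation limit: decision approaches labels as gamma grows
  # (narrow kernel keeps K well conditioned so the limit is numerically clean)
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2)
  yy <- ifelse(X[, 1] + X[, 2] > 0, 1, -1)
  m3 <- lssvm(X, yy, gamma = 1e6, sigma = 0.5)
  expect_equal(unname(predict(m3, X)), yy, tolerance = 1e-3)

  expect_error(lssvm(matrix(1, 3, 1), c(1, 1, 1)), "both labels")
})

test_that("KKT residuals stay below 1e-8 across trained transition models", {
  w <- small_world()
  samp <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 150, seed = 4))
  models <- train_transition_models(samp)
  expect_gt(length(models), 20)
  res <- vapply(models, function(m) m$kkt_residual, numeric(1))
  expect_true(all(res < 1e-8))
  # residuals method matches the KKT identity y - f(x) = alpha / gamma
  m <- models[["1->3"]]
  ss <- samp[["1->3"]]
  f <- predict(m, as.matrix(ss[, m$features]))
  expect_equal(unname(ss$label - f), unname(residuals(m)), tolerance = 1e-8)
})

test_that("decision values agree with an independent LSSVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(43)
  X <- matrix(rnorm(120), 60, 2)
  y <- ifelse(X[, 1]^2 + X[, 2] > 0.5, 1, -1)
  if (length(unique(y)) < 2) skip("degenerate labels")
  m <- lssvm(X, y, gamma = 10, sigma = 1)
  f <- predict(m, X)
  km <- kernlab::lssvm(X, factor(y), kernel = "rbfdot",
                       kpar = list(sigma = 0.5), tau = 0.1, reduced = FALSE)
  pred <- as.numeric(as.character(kernlab::predict(km, X)))
  expect_gt(mean((f > 0) == (pred > 0)), 0.9)
})

test_that("suitability surfaces are [0,1], masked, and fall back safely", {
  w <- small_world()
  samp <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 150, seed = 4))
  m <- lssvm(samp[["1->3"]])
  mask <- w$grid_t1$values == 1
  s <- predict_suitability(m, w$drivers, mask)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s[!mask] == 0))

  # positives rank above an equal-sized random source sample on average
  pos <- samp[["1->3"]][samp[["1->3"]]$label == 1, ]
  pos_idx <- (pos$col - 1) * nrow(mask) + pos$row
  set.seed(6)
  rnd_idx <- sample(which(mask), length(pos_idx))
  expect_gt(mean(s[pos_idx]), mean(s[rnd_idx]))

  # constant drivers give a flat 0.5 surface under the min-max guard
  flat <- driver_stack(stats::setNames(
    replicate(8, matrix(1, 10, 10), simplify = FALSE),
    names(w$drivers$surfaces)), 100)
  set.seed(2)
  Xf <- matrix(rnorm(16), 2, 8,
               dimnames = list(NULL, names(w$drivers$surfaces)))
  mflat <- lssvm(Xf, c(1, -1))
  s2 <- predict_suitability(mflat, flat, matrix(TRUE, 10, 10))
  expect_true(all(s2 == 0.5))

  # untrained transition: constant-zero fallback
  s3 <- predict_suitability(NULL, w$drivers, mask)
  expect_true(all(s3 == 0))
  expect_warning(predict_suitability(m, w$drivers, matrix(FALSE, 2, 2)),
                 "empty")

  # predictions invariant to feature scaling (stats travel with the model)
  dr2 <- w$drivers
  dr2$surfaces$elevation <- dr2$surfaces$elevation * 3 + 100
  X <- as.matrix(samp[["1->3"]][, m$features])
  m_raw <- lssvm(X, samp[["1->3"]]$label)
  X2 <- X; X2[, "elevation"] <- X2[, "elevation"] * 3 + 100
  m_scaled <- lssvm(X2, samp[["1->3"]]$label)
  expect_equal(predict(m_scaled, X2), predict(m_raw, X), tolerance = 1e-8)
})

test_that("AUC evaluation is a proper rank statistic", {
  # recovery experiment: logistic ground truth with a strong driver signal
  set.seed(71)
  n <- 600
  Xl <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, paste0("d", 1:4)))
  p <- plogis(2 * Xl[, 1] - 1.5 * Xl[, 2])
  yl <- ifelse(runif(n) < p, 1, -1)
  make_ss <- function(X, y) {
    ss <- data.frame(X)
    ss$label <- y
    attr(ss, "features") <- colnames(X)
    class(ss) <- c("sample_set", "data.frame")
    ss
  }
  ml <- lssvm(make_ss(Xl[1:300, ], yl[1:300]))
  auc <- evaluate_suitability(ml, make_ss(Xl[301:600, ], yl[301:600]))
  expect_gt(auc, 0.85)

  w <- small_world()
  samp <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 150, seed = 4))
  ss <- samp[["1->3"]]
  idx <- seq_len(nrow(ss)) %% 2 == 0
  m <- lssvm(ss[idx, ])
  held <- ss[!idx, ]

  # perfect separation (labels = thresholded decision) gives AUC 1
  f <- predict(m, as.matrix(held[, attr(ss, "features")]))
  perfect <- held
  perfect$label <- ifelse(f > median(f), 1, -1)
  expect_equal(evaluate_suitability(m, perfect), 1)

  # shuffled labels give chance-level AUC
  set.seed(8)
  null <- held
  null$label <- sample(held$label)
  expect_equal(evaluate_suitability(m, null), 0.5, tolerance = 0.12)

  one <- held; one$label <- rep(1, nrow(held))
  expect_warning(expect_true(is.na(evaluate_suitability(m, one))),
                 "one-class")
})

test_that("suitability tracks a known monotone driver dependence", {
  w <- small_world()
  samp <- suppressWarnings(
    stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 200, seed = 4))
  m <- lssvm(samp[["1->3"]])
  # sweep distance_roads holding other drivers at their mean
  X <- driver_matrix(w$drivers)
  base <- colMeans(X)
  sweep <- matrix(rep(base, each = 50), 50, length(base),
                  dimnames = list(NULL, names(base)))
  sweep[, "distance_roads"] <- seq(min(X[, "distance_roads"]),
                                   max(X[, "distance_roads"]), length.out = 50)
  f <- predict(m, sweep)
  expect_lt(cor(sweep[, "distance_roads"], f, method = "spearman"), -0.9)
})
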