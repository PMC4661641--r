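# Brute-force / enumeration oracles, written independently of the package
# implementations (label propagation instead of stack DFS, explicit loops
# instead of vectorized shifts).

# make a small land grid from a matrix of codes
lg <- function(m, cell_size = 100, scheme = ezhou_scheme(), nodata = -9999L) {
  land_grid(as.matrix(m), cell_size = cell_size, nodata = nodata,
            scheme = scheme)
}

random_codes <- function(nr, nc, k = 3, nodata_frac = 0) {
  m <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
  if (nodata_frac > 0)
    m[sample.int(nr * nc, round(nodata_frac * nr * nc))] <- -9999L
  m
}

# connected-component labelling by iterated min-label propagation
oracle_label <- function(values, nodata = -9999L, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[values == nodata] <- 0L
  if (connectivity == 8) {
    nb <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                c(1, -1), c(1, 0), c(1, 1))
  } else nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (lab[r, cc] == 0L) next
      for (q in seq_len(nrow(nb))) {
        r2 <- r + nb[q, 1]; c2 <- cc + nb[q, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (lab[r2, c2] != 0L && values[r2, c2] == values[r, cc] &&
            lab[r2, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[r2, c2]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# patch count and sorted areas (cells) from the oracle labelling
oracle_patches <- function(values, nodata = -9999L, connectivity = 8) {
  lab <- oracle_label(values, nodata, connectivity)
  ids <- lab[lab != 0L]
  tab <- table(ids)
  cls <- values[match(as.integer(names(tab)), lab)]
  data.frame(class = cls, cells = as.integer(tab))
}

# brute-force min-over-targets Euclidean distance
oracle_distance <- function(targets, cell_size) {
  nr <- nrow(targets); nc <- ncol(targets)
  tr <- which(targets, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc))
    out[r, cc] <- min(sqrt((r - tr[, 1])^2 + (cc - tr[, 2])^2)) * cell_size
  out
}

# per-cell Horn slope with explicit edge replication
oracle_horn <- function(elev, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  at <- function(r, cc) elev[min(max(r, 1), nr), min(max(cc, 1), nc)]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    dzdx <- ((at(r - 1, cc + 1) + 2 * at(r, cc + 1) + at(r + 1, cc + 1)) -
             (at(r - 1, cc - 1) + 2 * at(r, cc - 1) + at(r + 1, cc - 1))) /
      (8 * cell_size)
    dzdy <- ((at(r + 1, cc - 1) + 2 * at(r + 1, cc) + at(r + 1, cc + 1)) -
             (at(r - 1, cc - 1) + 2 * at(r - 1, cc) + at(r - 1, cc + 1))) /
      (8 * cell_size)
    out[r, cc] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  out
}

# contagion recomputed from an explicitly enumerated adjacency matrix
oracle_contagion <- function(values, nodata = -9999L) {
  present <- sort(unique(values[values != nodata]))
  m <- length(present)
  g <- matrix(0, m, m)
  nr <- nrow(values); nc <- ncol(values)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    a <- values[r, cc]
    if (a == nodata) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      b <- values[r2, c2]
      if (b == nodata) next
      g[match(a, present), match(b, present)] <-
        g[match(a, present), match(b, present)] + 1
    }
  }
  areas <- sapply(present, function(k) sum(values == k))
  P <- areas / sum(areas)
  acc <- 0
  for (i in seq_len(m)) for (k in seq_len(m)) {
    if (sum(g[i, ]) == 0) next
    q <- P[i] * g[i, k] / sum(g[i, ])
    if (q > 0) acc <- acc + q * log(q)
  }
  (1 + acc / (2 * log(m))) * 100
}

# per-class neighbourhood fraction by explicit window scan
oracle_neighborhood <- function(values, target, window, nodata = -9999L) {
  h <- (window - 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    hit <- 0; tot <- 0
    for (dr in -h:h) for (dc in -h:h) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (values[r2, c2] == nodata) next
      tot <- tot + 1
      if (values[r2, c2] == target) hit <- hit + 1
    }
    out[r, cc] <- if (tot > 0) hit / tot else 0
  }
  out
}
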