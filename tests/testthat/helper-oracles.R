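# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation: plain loops and
# direct formula evaluation only.

# co-occurrence matrix of one window by exhaustive pair enumeration
oracle_glcm <- function(w, offsets, symmetric = TRUE, n_levels) {
  p <- matrix(0, n_levels, n_levels)
  nr <- nrow(w); nc <- ncol(w)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          !is.na(w[i, j]) && !is.na(w[i2, j2])) {
        a <- w[i, j] + 1; b <- w[i2, j2] + 1
        p[a, b] <- p[a, b] + 1
        if (symmetric) p[b, a] <- p[b, a] + 1
      }
    }
  }
  p / sum(p)
}

# texture statistics by direct double-loop formula evaluation
oracle_texture <- function(p, stat) {
  n <- nrow(p)
  mu <- 0
  for (i in 1:n) for (j in 1:n) mu <- mu + (i - 1) * p[i, j]
  out <- 0
  for (i in 1:n) for (j in 1:n) {
    out <- out + switch(stat,
      mean = (i - 1) * p[i, j],
      variance = (i - 1 - mu)^2 * p[i, j],
      contrast = (i - j)^2 * p[i, j],
      entropy = if (p[i, j] > 0) -p[i, j] * log(p[i, j]) else 0)
  }
  out
}

# focal texture at one pixel: clip the window, enumerate, evaluate
oracle_focal_texture <- function(values, r, c, win, n_levels, offsets,
                                 symmetric, stat) {
  h <- win %/% 2
  rows <- max(1, r - h):min(nrow(values), r + h)
  cols <- max(1, c - h):min(ncol(values), c + h)
  p <- oracle_glcm(values[rows, cols, drop = FALSE], offsets, symmetric, n_levels)
  oracle_texture(p, stat)
}

# percent cover at one pixel by direct window counting
oracle_percent_cover <- function(values, r, c, win) {
  h <- win %/% 2
  rows <- max(1, r - h):min(nrow(values), r + h)
  cols <- max(1, c - h):min(ncol(values), c + h)
  w <- values[rows, cols]
  100 * sum(w == 1, na.rm = TRUE) / sum(!is.na(w))
}

# AUC by exhaustive concordant-pair counting (ties count one half)
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# max TSS by scanning every threshold between consecutive order statistics
oracle_max_tss <- function(pos, neg) {
  s <- sort(unique(c(pos, neg)))
  cand <- c(min(s) - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            max(s) + 1)
  best <- -Inf
  for (t in cand) {
    tss <- mean(pos >= t) + mean(neg < t) - 1
    if (tss > best) best <- tss
  }
  best
}

# rook-adjacency Moran's I of a matrix (for autocorrelation comparisons)
moran_i <- function(m) {
  z <- m - mean(m)
  num <- sum(z[, -1] * z[, -ncol(m)]) + sum(z[-1, ] * z[-nrow(m), ])
  n_edges <- nrow(m) * (ncol(m) - 1) + (nrow(m) - 1) * ncol(m)
  length(m) * num / (n_edges * sum(z^2))
}

rand_layer <- function(nr = 30, nc = 30, seed = 1, grid = NULL) {
  set.seed(seed)
  raster_layer(matrix(runif(nr * nc), nr, nc), grid, name = paste0("rnd", seed))
}
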