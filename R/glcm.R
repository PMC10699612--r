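#' GLCM texture configuration
#'
#' Settings for grey-level co-occurrence texture layers: the number of grey
#' levels the input is quantized to, the pixel-pair displacements, whether
#' pairs are counted in both orders, and the focal window side in metres.
#' Binary inputs (preferred/non-preferred masks) should use `n_levels = 2`.
#'
#' @param n_levels Grey levels for quantization (>= 2). Default 16.
#' @param offsets Integer matrix of `(row, col)` displacements; default the
#'   four unit directions (0, 45, 90, 135 degrees).
#' @param symmetric Count each co-occurring pair in both orders. Default `TRUE`.
#' @param window_m Focal window side in metres (310 or 990 in the standard
#'   catalog).
#' @param log_base Base of the entropy logarithm; natural log by default
#'   (the Haralick convention).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(n_levels = 16,
                        offsets = rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)),
                        symmetric = TRUE, window_m = 310, log_base = exp(1)) {
  stopifnot(n_levels >= 2, nrow(offsets) >= 1, ncol(offsets) == 2, log_base > 1)
  storage.mode(offsets) <- "integer"
  structure(list(n_levels = as.integer(n_levels), offsets = offsets,
                 symmetric = isTRUE(symmetric), window_m = window_m,
                 log_base = log_base),
            class = "glcm_config")
}

#' Quantize a layer into grey levels
#'
#' Equal-interval bins over the layer's global finite range, yielding
#' integer levels `0 .. n_levels - 1`. Global (not per-window) bounds keep
#' texture values comparable across a scene. A constant layer maps to level 0.
#'
#' @param layer An [raster_layer()].
#' @param n_levels Number of levels (>= 2).
#' @return An [raster_layer()] of level indices.
#' @export
quantize_levels <- function(layer, n_levels = 16) {
  stopifnot(is_raster_layer(layer), n_levels >= 2)
  v <- layer$values
  fin <- v[is.finite(v)]
  if (!length(fin)) stop("all-nodata layer cannot be quantized to levels")
  lo <- min(fin); hi <- max(fin)
  out <- layer
  if (hi == lo) {
    out$values[is.finite(v)] <- 0
  } else {
    lev <- floor((v - lo) / (hi - lo) * n_levels)
    lev[lev >= n_levels] <- n_levels - 1  # v == hi lands in the top bin
    out$values <- lev
  }
  out$name <- paste0(layer$name, "_lev", n_levels)
  out
}

#' Grey-level co-occurrence matrix of a single window
#'
#' Accumulates co-occurring level pairs over all configured offsets (and
#' their transposes when symmetric), skipping pairs that touch `NA`, then
#' normalizes to sum 1.
#'
#' @param window_levels Integer matrix of level indices (`NA` = nodata).
#' @param config A [glcm_config()].
#' @return Matrix of class `glcm_matrix` (`n_levels x n_levels`, sums to 1).
#' @export
glcm_matrix <- function(window_levels, config = glcm_config()) {
  n <- config$n_levels
  m <- as.matrix(window_levels)
  if (any(m >= n, na.rm = TRUE) || any(m < 0, na.rm = TRUE))
    stop("level indices must lie in 0 .. n_levels - 1")
  p <- matrix(0, n, n)
  nr <- nrow(m); nc <- ncol(m)
  for (o in seq_len(nrow(config$offsets))) {
    dr <- config$offsets[o, 1]; dc <- config$offsets[o, 2]
    r_idx <- seq_len(nr); c_idx <- seq_len(nc)
    r_ok <- r_idx[r_idx + dr >= 1 & r_idx + dr <= nr]
    c_ok <- c_idx[c_idx + dc >= 1 & c_idx + dc <= nc]
    if (!length(r_ok) || !length(c_ok)) next
    a <- m[r_ok, c_ok, drop = FALSE]
    b <- m[r_ok + dr, c_ok + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(n - 1)),
                 factor(b[ok], levels = 0:(n - 1)))
    p <- p + tab
    if (config$symmetric) p <- p + t(tab)
  }
  tot <- sum(p)
  if (tot == 0) stop("window holds no valid co-occurring pair")
  structure(p / tot, class = c("glcm_matrix", "matrix"))
}

#' Texture statistic of a normalized GLCM
#'
#' Second-order Haralick statistics of the co-occurrence distribution
#' `p(i, j)` over levels `i, j = 0 .. n-1`:
#' mean `mu = sum i p(i,j)`; variance `sum (i - mu)^2 p(i,j)`;
#' contrast `sum (i - j)^2 p(i,j)`; entropy `-sum p log p` (with
#' `0 log 0 = 0`; natural log unless `log_base` says otherwise).
#'
#' @param glcm A normalized GLCM (from [glcm_matrix()]).
#' @param stat One of `"mean"`, `"variance"`, `"contrast"`, `"entropy"`.
#' @param log_base Entropy logarithm base.
#' @return A single number.
#' @export
texture_statistic <- function(glcm, stat = c("mean", "variance", "contrast", "entropy"),
                              log_base = exp(1)) {
  stat <- match.arg(stat)
  p <- unclass(glcm)
  if (abs(sum(p) - 1) > 1e-6) stop("GLCM is not normalized (sum != 1)")
  n <- nrow(p)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  switch(stat,
    mean = sum(i * p),
    variance = { mu <- sum(i * p); sum((i - mu)^2 * p) },
    contrast = sum((i - j)^2 * p),
    entropy = { nz <- p > 0; -sum(p[nz] * log(p[nz])) / log(log_base) })
}

#' Focal GLCM texture layers
#'
#' Computes all four second-order texture statistics of the moving-window
#' GLCM in a single pass (the expensive step is shared, so asking for all
#' four costs the same as one). Edge windows are truncated to in-bounds
#' pixels and the output is flagged with `edge_mode = "truncate"`; when a
#' buffered scene is used, crop the buffer afterwards with [crop_margin()]
#' so every retained pixel had a full window.
#'
#' @param layer An [raster_layer()] (continuous, or binary 0/1).
#' @param config A [glcm_config()]. For binary input `n_levels` is forced
#'   to 2.
#' @return Named list of four [raster_layer()]s: `mean`, `variance`,
#'   `contrast`, `entropy`.
#' @export
focal_textures <- function(layer, config = glcm_config()) {
  stopifnot(is_raster_layer(layer))
  win <- meters_to_pixels(config$window_m, layer$grid$pixel_size)
  if (win > min(layer$grid$n_rows, layer$grid$n_cols))
    stop("focal window (", win, " px) larger than the raster")
  fin <- layer$values[is.finite(layer$values)]
  is_binary <- length(fin) && all(fin %in% c(0, 1))
  n_levels <- if (is_binary) 2L else config$n_levels
  lev <- if (is_binary) layer else quantize_levels(layer, n_levels)
  lm <- lev$values
  lm[!is.finite(lm)] <- NA
  storage.mode(lm) <- "integer"
  res <- cpp_focal_glcm(lm, win, n_levels, config$offsets, config$symmetric)
  out <- lapply(names(res), function(s) {
    v <- res[[s]]
    if (s == "entropy" && config$log_base != exp(1)) v <- v / log(config$log_base)
    l <- raster_layer(v, layer$grid,
                      name = paste0(layer$name, "_", substr(s, 1, 1), config$window_m))
    attr(l, "edge_mode") <- "truncate"
    l
  })
  names(out) <- names(res)
  out
}

#' Single focal texture layer
#'
#' Convenience wrapper around [focal_textures()] returning one statistic.
#'
#' @inheritParams focal_textures
#' @param stat One of `"mean"`, `"variance"`, `"contrast"`, `"entropy"`.
#' @return An [raster_layer()].
#' @export
focal_texture <- function(layer, stat = c("mean", "variance", "contrast", "entropy"),
                          config = glcm_config()) {
  stat <- match.arg(stat)
  focal_textures(layer, config)[[stat]]
}
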