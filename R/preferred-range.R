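#' Central "preferred" range of presence-sampled values
#'
#' Estimates the central `pct`% interval of a predictor's values sampled at
#' presence points: bounds at the `(50 - pct/2)`th and `(50 + pct/2)`th
#' percentiles using the inclusive linear-interpolation percentile
#' convention (R `quantile` type 7, the spreadsheet PERCENTILE.INC rule).
#' Raw-index features conventionally use 50% and 70% ranges; texture
#' features use 70/80/85/90%. Ranges must be estimated only from presence
#' points withheld from model fitting, to keep range estimation and model
#' training independent.
#'
#' @param values_at_presence Numeric vector of predictor values sampled at
#'   (withheld) presence points; at least 2 finite values.
#' @param pct Central percentage, strictly between 0 and 100.
#' @param source_feature Name of the predictor the sample came from.
#' @return A `central_range` object with fields `lo`, `hi`, `pct`,
#'   `source_feature`, `n_samples`.
#' @export
central_range <- function(values_at_presence, pct, source_feature = "feature") {
  v <- values_at_presence[is.finite(values_at_presence)]
  if (length(v) < 2) stop("need at least 2 finite presence values")
  if (!is.numeric(pct) || pct <= 0 || pct >= 100) stop("pct must be in (0, 100)")
  qs <- stats::quantile(v, probs = c(50 - pct / 2, 50 + pct / 2) / 100,
                        type = 7, names = FALSE)
  structure(list(lo = qs[1], hi = qs[2], pct = pct,
                 source_feature = source_feature, n_samples = length(v)),
            class = "central_range")
}

#' @export
print.central_range <- function(x, ...) {
  cat(sprintf("<central_range %g%% of '%s': [%.6g, %.6g] (n = %d)>\n",
              x$pct, x$source_feature, x$lo, x$hi, x$n_samples))
  invisible(x)
}

#' Binarize a raster against a preferred range
#'
#' 1 where the pixel value falls inside the closed interval `[lo, hi]`,
#' 0 otherwise; nodata propagates. Ties at the bounds count as preferred.
#'
#' @param layer An [raster_layer()].
#' @param range A [central_range()].
#' @return A binary [raster_layer()] carrying the range as attribute
#'   `central_range`.
#' @export
binarize_preferred <- function(layer, range) {
  stopifnot(is_raster_layer(layer), inherits(range, "central_range"))
  v <- layer$values
  out <- layer
  out$values <- ifelse(is.na(v), NA_real_,
                       as.numeric(v >= range$lo & v <= range$hi))
  out$name <- paste0(layer$name, "_bin", range$pct)
  attr(out, "central_range") <- range
  out
}

#' Percent cover of preferred pixels in a focal window
#'
#' For every pixel, the percentage of non-nodata pixels inside the centred
#' square window that are flagged 1: `100 * ones / valid`. Windows are
#' truncated to in-bounds pixels at the edges (use a buffered scene and
#' [crop_margin()] when full windows are required everywhere); the
#' denominator counts valid pixels, so buffered and truncated modes agree
#' wherever full windows exist.
#'
#' @param binary A binary (0/1) [raster_layer()], e.g. from
#'   [binarize_preferred()].
#' @param window_m Window side in metres (converted via [meters_to_pixels()]).
#' @return An [raster_layer()] with values in `[0, 100]`.
#' @export
percent_cover <- function(binary, window_m) {
  stopifnot(is_raster_layer(binary))
  fin <- binary$values[is.finite(binary$values)]
  if (length(fin) && !all(fin %in% c(0, 1)))
    stop("percent_cover expects a 0/1 binary layer")
  win <- meters_to_pixels(window_m, binary$grid$pixel_size)
  if (win > min(binary$grid$n_rows, binary$grid$n_cols))
    stop("focal window (", win, " px) larger than the raster")
  out <- raster_layer(cpp_percent_cover(binary$values, win), binary$grid,
                      name = paste0(binary$name, "_pc", window_m))
  attr(out, "edge_mode") <- "truncate"
  out
}
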