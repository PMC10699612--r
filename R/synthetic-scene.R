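# run code under a temporary RNG state so package functions do not disturb
# the caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a reproducible 31-bit substream seed from a master seed and a label
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# mean filter with truncated windows (integral image), applied `passes`
# times; three passes of a box filter approximate a Gaussian
smooth_matrix <- function(m, radius, passes = 3) {
  if (radius <= 0) return(m)
  win <- 2L * as.integer(radius) + 1L
  for (i in seq_len(passes)) m <- cpp_focal_mean(m, win)
  m
}

#' Synthetic scene configuration
#'
#' Parameters for the seeded scene generator: grid shape, pixel size, the
#' smoothing length that controls spatial autocorrelation of the spectral
#' bands, and the magnitude of the between-date change field. Date 1
#' carries red/green/blue/NIR; date 2 carries red/green/NIR only (no blue),
#' matching the band availability the two-date feature catalog assumes.
#'
#' @param n_rows,n_cols Grid dimensions (default 200 x 200).
#' @param pixel_size Pixel edge in metres (default 9.5).
#' @param seed Integer seed; a fixed seed reproduces the scene exactly.
#' @param autocorr_px Smoothing radius in pixels (0 = white noise).
#' @param change_sd Standard deviation (digital numbers, 0-255 scale) of the
#'   smoothed perturbation added to shared bands for date 2.
#' @param elev_range Elevation range in metres (default 1 to 70 m, a
#'   low-relief coastal plain).
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_rows = 200, n_cols = 200, pixel_size = 9.5,
                         seed = 1, autocorr_px = 6, change_sd = 10,
                         elev_range = c(1, 70)) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0, change_sd >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = pixel_size, seed = as.integer(seed),
                 autocorr_px = autocorr_px, change_sd = change_sd,
                 elev_range = elev_range),
            class = "scene_config")
}

rescale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Generate a synthetic two-date scene
#'
#' Each spectral band is smoothed Gaussian white noise rescaled to the
#' 0-255 digital-number range; date-2 bands are the date-1 bands plus a
#' smoothed perturbation of standard deviation `change_sd`, re-clipped to
#' range. Elevation is a linear north-south ramp plus smoothed noise,
#' rescaled to `elev_range`. Every layer shares one [grid_spec()].
#'
#' @param config A [scene_config()].
#' @return A `synthetic_scene` list with elements `bands08` (red, green,
#'   blue, nir), `bands10` (red, green, nir), `elevation` and `grid`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  g <- grid_spec(pixel_size = config$pixel_size,
                 n_rows = config$n_rows, n_cols = config$n_cols,
                 crs_tag = "synthetic-projected")
  nr <- config$n_rows; nc <- config$n_cols
  with_seed(config$seed, {
    mk_band <- function() {
      m <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), config$autocorr_px)
      255 * rescale01(m)
    }
    b08 <- list(red = mk_band(), green = mk_band(), blue = mk_band(),
                nir = mk_band())
    perturb <- function(b) {
      if (config$change_sd == 0) return(b)
      d <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), config$autocorr_px)
      sdd <- stats::sd(d)
      if (sdd > 0) d <- d / sdd * config$change_sd
      pmin(pmax(b + d, 0), 255)
    }
    b10 <- list(red = perturb(b08$red), green = perturb(b08$green),
                nir = perturb(b08$nir))
    ramp <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
    noise <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), config$autocorr_px)
    elev <- config$elev_range[1] +
      diff(config$elev_range) * rescale01(0.6 * ramp + 0.4 * rescale01(noise))
    as_layers <- function(lst, tag)
      lapply(stats::setNames(names(lst), names(lst)), function(b)
        raster_layer(lst[[b]], g, name = paste0(b, tag)))
    structure(list(bands08 = as_layers(b08, "08"),
                   bands10 = as_layers(b10, "10"),
                   elevation = raster_layer(elev, g, name = "elevation"),
                   grid = g, config = config),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %s; date-1 bands %s; date-2 bands %s>\n",
              format(x$grid), paste(names(x$bands08), collapse = "/"),
              paste(names(x$bands10), collapse = "/")))
  invisible(x)
}

#' Ground-truth suitability model
#'
#' A known suitability surface used to plant recoverable structure in a
#' synthetic scene: named driver features (any feature computable from the
#' scene without presence points, e.g. an entropy texture of the date-2
#' NDVI, or elevation), linear weights on their standardized values, and an
#' intercept, passed through the complementary log-log link.
#'
#' @param drivers Character vector of feature names (catalog convention).
#' @param weights Numeric coefficients, one per driver.
#' @param intercept Intercept on the linear-predictor scale.
#' @return A `truth_model` list.
#' @export
truth_model <- function(drivers = c("ndv102e310", "elevation"),
                        weights = c(2, 1.5), intercept = -2) {
  stopifnot(length(drivers) >= 1, length(weights) == length(drivers))
  structure(list(drivers = drivers, weights = weights, intercept = intercept),
            class = "truth_model")
}

#' Derive the ground-truth suitability surface
#'
#' Computes each driver feature from the scene, standardizes it over finite
#' pixels, and maps the linear combination through the cloglog link:
#' `suitability = 1 - exp(-exp(intercept + sum w_i z_i))`, a value in (0, 1)
#' at every valid pixel.
#'
#' @param scene A [generate_scene()] result.
#' @param truth A [truth_model()].
#' @return An [raster_layer()] named `"truth_suitability"`.
#' @export
derive_truth_suitability <- function(scene, truth = truth_model()) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(truth, "truth_model"))
  eta <- matrix(truth$intercept, scene$grid$n_rows, scene$grid$n_cols)
  for (i in seq_along(truth$drivers)) {
    lyr <- compute_feature(scene, truth$drivers[i])
    v <- lyr$values
    mu <- mean(v[is.finite(v)]); sdv <- stats::sd(v[is.finite(v)])
    if (!is.finite(sdv) || sdv == 0) stop("driver '", truth$drivers[i],
                                          "' is constant; no truth signal")
    eta <- eta + truth$weights[i] * (v - mu) / sdv
  }
  raster_layer(1 - exp(-exp(eta)), scene$grid, name = "truth_suitability")
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` distinct pixels without replacement with probability
#' proportional to suitability and returns their pixel-centre coordinates
#' as presence points. Each point carries a positional accuracy drawn
#' uniformly from 5-95 m (all under the conventional 100 m ceiling).
#'
#' @param suitability An [raster_layer()] with values in `[0, 1]`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An occurrence tibble (`x`, `y`, `role`, `accuracy_m`,
#'   `source_tag`) with `role = "presence"`.
#' @export
sample_presence_points <- function(suitability, n, seed = 1) {
  stopifnot(is_raster_layer(suitability), n >= 1)
  co <- as_tibble.rc_raster(suitability)
  pos <- which(!is.na(co$value) & co$value > 0)
  if (n > length(pos)) stop("n exceeds the ", length(pos),
                            " pixels with positive suitability")
  with_seed(seed, {
    pick <- pos[sample.int(length(pos), n, prob = co$value[pos])]
    tibble::tibble(x = co$x[pick], y = co$y[pick], role = "presence",
                   accuracy_m = stats::runif(n, 5, 95),
                   source_tag = "synthetic")
  })
}

#' Generate a categorical land-use / land-cover layer
#'
#' Quantile-slices a smoothed noise field on the suitability grid into
#' `n_classes` contiguous classes of (nearly) equal area, labelled
#' `1 .. n_classes` with a class-name table in attribute `class_names`.
#'
#' @param suitability An [raster_layer()] supplying the grid.
#' @param n_classes Number of classes (>= 2).
#' @param seed Integer seed.
#' @param autocorr_px Smoothing radius of the underlying field.
#' @return A categorical [raster_layer()] named `"lulc"`.
#' @export
generate_lulc <- function(suitability, n_classes = 5, seed = 1, autocorr_px = 8) {
  stopifnot(is_raster_layer(suitability), n_classes >= 2)
  g <- suitability$grid
  if (n_classes > g$n_rows * g$n_cols) stop("more classes than pixels")
  with_seed(seed, {
    f <- smooth_matrix(matrix(stats::rnorm(g$n_rows * g$n_cols),
                              g$n_rows, g$n_cols), autocorr_px)
    # rank-based slicing gives classes of equal pixel count up to ties
    rk <- rank(f, ties.method = "first")
    cls <- ceiling(rk / length(rk) * n_classes)
    out <- raster_layer(matrix(cls, g$n_rows, g$n_cols), g, name = "lulc")
    attr(out, "class_names") <- stats::setNames(
      paste0("class_", seq_len(n_classes)), seq_len(n_classes))
    attr(out, "categorical") <- TRUE
    out
  })
}
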