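#' Spectral band set for one acquisition date
#'
#' Bundles the red, green, optional blue and optional near-infrared bands of
#' one image date. Bands are kept on their native 0-255 digital-number
#' scale; the normalized indices are (nearly) scale-free anyway. Blue is
#' required only for BNDVI, GBNDVI and SARVI; NIR for everything but GRNDI.
#'
#' @param red,green Red and green [raster_layer()]s (required).
#' @param blue,nir Optional blue and near-infrared layers.
#' @param year_tag Two-character year tag used in feature names ("08", "10").
#' @return A `band_set` list.
#' @export
band_set <- function(red, green, blue = NULL, nir = NULL, year_tag = "08") {
  bands <- list(red = red, green = green, blue = blue, nir = nir)
  bands <- bands[!vapply(bands, is.null, logical(1))]
  lapply(bands, function(b) stopifnot(is_raster_layer(b)))
  for (b in bands[-1]) stop_if_grid_mismatch(bands[[1]], b)
  structure(c(bands, list(year_tag = year_tag)), class = "band_set")
}

#' SARVI parameters
#'
#' The soil-and-atmospherically-resistant index uses a soil-conditioning
#' constant `L` and a blue-red weighting `y` in the atmospheric correction
#' term `RB = Red - y (Blue - Red)`. Defaults `L = 0.5`, `y = 1`.
#' `literal = TRUE` switches to the alternative parenthesization
#' `(1 + L) (NIR - (Red - RB) / (NIR + RB + L))` seen in some printed
#' sources, for side-by-side comparison; the default is the standard form
#' `(1 + L)(NIR - RB) / (NIR + RB + L)`.
#'
#' @param L Soil conditioning constant.
#' @param y Blue-red weighting.
#' @param literal Evaluate the non-standard printed parenthesization.
#' @return A `sarvi_params` list.
#' @export
sarvi_params <- function(L = 0.5, y = 1, literal = FALSE) {
  structure(list(L = L, y = y, literal = isTRUE(literal)), class = "sarvi_params")
}

index_requirements <- list(
  ndvi   = c("nir", "red"),
  bndvi  = c("nir", "blue"),
  gbndvi = c("nir", "green", "blue"),
  grndi  = c("green", "red"),
  sarvi  = c("nir", "red", "blue")
)

#' Compute a vegetation/spectral index
#'
#' Pixelwise band arithmetic with a fixed `1e-5` denominator stabilizer:
#' \itemize{
#'   \item NDVI   = (NIR - Red) / (NIR + Red + 1e-5)
#'   \item BNDVI  = (NIR - Blue) / (NIR + Blue + 1e-5)
#'   \item GBNDVI = (NIR - (Green + Blue)) / (NIR + (Green + Blue + 1e-5))
#'   \item GRNDI  = (Green - Red) / (Green + Red + 1e-5)
#'   \item SARVI  = (1 + L)(NIR - RB) / (NIR + RB + L), RB = Red - y(Blue - Red)
#' }
#'
#' @param bands A [band_set()] holding the required bands.
#' @param name Index name: `"ndvi"`, `"bndvi"`, `"gbndvi"`, `"grndi"`, `"sarvi"`.
#' @param params [sarvi_params()] (used for SARVI only).
#' @return An [raster_layer()] named `"<index><year_tag>"` (e.g. `"bndvi08"`),
#'   carrying attributes `index_name` and `year_tag`.
#' @export
compute_index <- function(bands, name = c("ndvi", "bndvi", "gbndvi", "grndi", "sarvi"),
                          params = sarvi_params()) {
  name <- match.arg(name)
  stopifnot(inherits(bands, "band_set"))
  need <- index_requirements[[name]]
  missing_b <- setdiff(need, names(bands))
  if (length(missing_b))
    stop("index '", name, "' needs band(s): ", paste(missing_b, collapse = ", "))
  eps <- 1e-5
  NIR <- bands$nir$values; Red <- bands$red$values
  Green <- bands$green$values; Blue <- bands$blue$values
  v <- switch(name,
    ndvi   = (NIR - Red) / (NIR + Red + eps),
    bndvi  = (NIR - Blue) / (NIR + Blue + eps),
    gbndvi = (NIR - (Green + Blue)) / (NIR + (Green + Blue + eps)),
    grndi  = (Green - Red) / (Green + Red + eps),
    sarvi  = {
      RB <- Red - params$y * (Blue - Red)
      if (params$literal) (1 + params$L) * (NIR - (Red - RB) / (NIR + RB + params$L))
      else (1 + params$L) * (NIR - RB) / (NIR + RB + params$L)
    })
  out <- raster_layer(v, bands$red$grid, name = paste0(name, bands$year_tag))
  attr(out, "index_name") <- name
  attr(out, "year_tag") <- bands$year_tag
  out
}

index_family <- function(layer) {
  fam <- attr(layer, "index_name")
  if (is.null(fam)) NA_character_ else fam
}

check_same_family <- function(a, b) {
  fa <- index_family(a); fb <- index_family(b)
  if (!is.na(fa) && !is.na(fb) && fa != fb)
    stop("index family mismatch: '", fa, "' vs '", fb, "'")
  invisible(TRUE)
}

#' Simple multitemporal index difference
#'
#' `y = a - b` pixelwise, where `a` is the later and `b` the earlier date of
#' the same index. Output named `delt<code><yrA>_<yrB>` (e.g.
#' `"deltgrn10_08"`).
#'
#' @param a,b [raster_layer()]s of the same index family on one grid
#'   (`a` = later date).
#' @return An [raster_layer()].
#' @export
simple_difference <- function(a, b) {
  stop_if_grid_mismatch(a, b); check_same_family(a, b)
  fam <- index_family(a)
  code <- if (is.na(fam)) "idx" else index_short_code[[fam]]
  nm <- paste0("delt", code, attr(a, "year_tag") %||% "a", "_",
               attr(b, "year_tag") %||% "b")
  out <- raster_layer(a$values - b$values, a$grid, name = nm)
  attr(out, "index_name") <- fam
  out
}

#' Normalized multitemporal index difference
#'
#' `y = (a - b) / (a + b + 1e-5)` pixelwise (the same denominator stabilizer
#' as the raw indices, so the output is finite everywhere). Output named
#' `ndelt<code><yrA>_<yrB>`.
#'
#' @inheritParams simple_difference
#' @return An [raster_layer()].
#' @export
normalized_difference <- function(a, b) {
  stop_if_grid_mismatch(a, b); check_same_family(a, b)
  fam <- index_family(a)
  code <- if (is.na(fam)) "idx" else index_short_code[[fam]]
  nm <- paste0("ndelt", code, attr(a, "year_tag") %||% "a", "_",
               attr(b, "year_tag") %||% "b")
  out <- raster_layer((a$values - b$values) / (a$values + b$values + 1e-5),
                      a$grid, name = nm)
  attr(out, "index_name") <- fam
  out
}

#' Signed power transform
#'
#' `sign(v) * |v|^exponent` pixelwise: an order-preserving non-linear
#' stretch used to magnify differences between pixel values of selected
#' feature rasters (exponents below 1 spread small magnitudes apart,
#' exponents above 1 spread large ones).
#'
#' @param layer An [raster_layer()].
#' @param exponent Positive exponent.
#' @return An [raster_layer()] (name suffixed `trans`).
#' @export
signed_power_transform <- function(layer, exponent) {
  stopifnot(is_raster_layer(layer))
  if (!is.numeric(exponent) || exponent <= 0) stop("exponent must be > 0")
  out <- layer
  out$values <- sign(layer$values) * abs(layer$values)^exponent
  out$name <- paste0(layer$name, "trans")
  out
}
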