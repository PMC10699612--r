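#' Grid specification for a raster analysis
#'
#' A `grid_spec` pins the shared geometry of every layer in an analysis:
#' map origin (centre of the north-west pixel), pixel size in metres, grid
#' dimensions and a coordinate-reference tag. All layers entering a model
#' must share an identical grid so that pixels line up exactly.
#'
#' @param origin_x,origin_y Map coordinates (m) of the centre of the
#'   top-left (northernmost, westernmost) pixel.
#' @param pixel_size Pixel edge length in metres. Default 9.5, the working
#'   resolution of the analysis.
#' @param n_rows,n_cols Grid dimensions (row 1 is the northernmost row).
#' @param crs_tag Free-text identifier of the projected CRS (planar metres
#'   assumed; e.g. a NAD83-based projection).
#' @return An object of class `rc_grid`.
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, pixel_size = 9.5,
                      n_rows, n_cols, crs_tag = "local-projected") {
  stopifnot(pixel_size > 0, n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         pixel_size = pixel_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs_tag = crs_tag),
    class = "rc_grid"
  )
}

#' @export
format.rc_grid <- function(x, ...) {
  sprintf("<rc_grid %d x %d @ %g m, origin (%g, %g), %s>",
          x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y, x$crs_tag)
}

#' @export
print.rc_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

grids_identical <- function(a, b, tol = 1e-6) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Construct a raster layer
#'
#' In-memory single-band raster: a numeric matrix (row 1 = north) plus its
#' [grid_spec()]. Missing cells are held as `NA` and excluded from every
#' statistic in the package.
#'
#' @param values Numeric matrix, `n_rows x n_cols`; `NA` marks nodata.
#' @param grid A [grid_spec()]; if omitted, a default grid of matching shape.
#' @param name Layer name (used as the feature/column name downstream).
#' @return An object of class `rc_raster`.
#' @export
raster_layer <- function(values, grid = NULL, name = "layer") {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- grid_spec(n_rows = nrow(values), n_cols = ncol(values))
  if (!inherits(grid, "rc_grid")) stop("`grid` must be an rc_grid")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape (", nrow(values), "x", ncol(values),
         ") does not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, name = name),
            class = "rc_raster")
}

#' @export
print.rc_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<rc_raster '%s' %s; %d valid px, range [%s, %s]>\n",
              x$name, format(x$grid), length(v),
              if (length(v)) signif(min(v), 6) else "-",
              if (length(v)) signif(max(v), 6) else "-"))
  invisible(x)
}

#' Test for a raster layer
#' @param x Any object.
#' @return `TRUE` for [raster_layer()] objects.
#' @export
is_raster_layer <- function(x) inherits(x, "rc_raster")

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_identical(a$grid, b$grid))
    stop("layers '", a$name, "' and '", b$name, "' are on different grids")
  invisible(TRUE)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return Tibble with `row`, `col`, `x`, `y` for every pixel.
#' @export
grid_coordinates <- function(grid) {
  rows <- seq_len(grid$n_rows)
  cols <- seq_len(grid$n_cols)
  tibble::tibble(
    row = rep(rows, times = grid$n_cols),
    col = rep(cols, each = grid$n_rows),
    x = grid$origin_x + (rep(cols, each = grid$n_rows) - 1) * grid$pixel_size,
    y = grid$origin_y - (rep(rows, times = grid$n_cols) - 1) * grid$pixel_size
  )
}

# map coords -> (row, col); points outside grid get NA
coords_to_rowcol <- function(grid, x, y) {
  col <- round((x - grid$origin_x) / grid$pixel_size) + 1
  row <- round((grid$origin_y - y) / grid$pixel_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid interchange format (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/
#' `yllcenter`, `cellsize`, `NODATA_value`) followed by whitespace-separated
#' rows, north first. Nodata cells become `NA`.
#'
#' @param path Path to the `.asc` file.
#' @param name Layer name; defaults to the file stem.
#' @param crs_tag CRS tag to stamp on the grid.
#' @return An [raster_layer()].
#' @export
read_raster <- function(path, name = NULL, crs_tag = "local-projected") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- readLines(con, n = 1)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("unreadable ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])) ||
      !(any(c("xllcorner", "xllcenter") %in% names(hdr))))
    stop("not a georeferenced ASCII grid: ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("value count mismatch in ", path)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  px <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcenter)) hdr$xllcenter - px / 2 else hdr$xllcorner
  yll <- if (!is.null(hdr$yllcenter)) hdr$yllcenter - px / 2 else hdr$yllcorner
  grid <- grid_spec(origin_x = xll + px / 2,
                    origin_y = yll + px / 2 + (nr - 1) * px,
                    pixel_size = px, n_rows = nr, n_cols = nc,
                    crs_tag = crs_tag)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(m, grid, name = name)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Integer-valued layers are written without decimals so they round-trip
#' bit-exactly; float layers round-trip within 1e-6 relative precision.
#'
#' @param layer An [raster_layer()].
#' @param path Output path (parent directory must exist).
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  stopifnot(is_raster_layer(layer))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  g <- layer$grid
  v <- layer$values
  if (any(v == nodata, na.rm = TRUE))
    stop("layer contains the nodata sentinel ", nodata, " as a real value")
  v[is.na(v)] <- nodata
  integerish <- all(v == round(v))
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value %g",
    g$n_cols, g$n_rows,
    g$origin_x - g$pixel_size / 2,
    g$origin_y - (g$n_rows - 1) * g$pixel_size - g$pixel_size / 2,
    g$pixel_size, nodata)
  fmt <- if (integerish) "%d" else "%.9g"
  rows <- apply(v, 1, function(r) {
    if (integerish) paste(sprintf("%d", as.integer(r)), collapse = " ")
    else paste(sprintf("%.9g", r), collapse = " ")
  })
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("could not write raster to ", path)
  invisible(path)
}

#' Resample a layer onto a target grid
#'
#' Nearest-neighbour or bilinear resampling onto `target`, which also crops
#' the output to the target extent. Categorical layers (land cover, binary
#' masks) must use `method = "nearest"` so no new values are invented.
#'
#' @param layer An [raster_layer()].
#' @param target A [grid_spec()] overlapping the layer spatially.
#' @param method `"nearest"` or `"bilinear"`.
#' @return The layer resampled onto `target`.
#' @export
align_to_grid <- function(layer, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is_raster_layer(layer), inherits(target, "rc_grid"))
  g <- layer$grid
  if (grids_identical(g, target)) {
    out <- layer; out$grid <- target
    return(out)
  }
  # target pixel centres in map coordinates
  tx <- target$origin_x + (seq_len(target$n_cols) - 1) * target$pixel_size
  ty <- target$origin_y - (seq_len(target$n_rows) - 1) * target$pixel_size
  # fractional source indices (1-based)
  fc <- (tx - g$origin_x) / g$pixel_size + 1
  fr <- (g$origin_y - ty) / g$pixel_size + 1
  eps <- 1e-9
  if (max(fr) < 1 - eps || min(fr) > g$n_rows + eps ||
      max(fc) < 1 - eps || min(fc) > g$n_cols + eps)
    stop("layer and target grids do not overlap")
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method == "nearest") {
    ri <- pmin(pmax(round(fr), 1), g$n_rows)
    ci <- pmin(pmax(round(fc), 1), g$n_cols)
    inr <- fr >= 0.5 - eps & fr <= g$n_rows + 0.5 + eps
    inc <- fc >= 0.5 - eps & fc <= g$n_cols + 0.5 + eps
    out[inr, inc] <- layer$values[ri[inr], ci[inc], drop = FALSE]
  } else {
    r0 <- pmin(pmax(floor(fr), 1), g$n_rows - 1)
    c0 <- pmin(pmax(floor(fc), 1), g$n_cols - 1)
    wr <- pmin(pmax(fr - r0, 0), 1)
    wc <- pmin(pmax(fc - c0, 0), 1)
    v <- layer$values
    inr <- fr >= 1 - eps & fr <= g$n_rows + eps
    inc <- fc >= 1 - eps & fc <= g$n_cols + eps
    A <- v[r0, c0, drop = FALSE]; B <- v[r0, c0 + 1, drop = FALSE]
    C <- v[r0 + 1, c0, drop = FALSE]; D <- v[r0 + 1, c0 + 1, drop = FALSE]
    WR <- matrix(wr, length(fr), length(fc))
    WC <- matrix(wc, length(fr), length(fc), byrow = TRUE)
    full <- (1 - WR) * ((1 - WC) * A + WC * B) + WR * ((1 - WC) * C + WC * D)
    out[inr, inc] <- full[inr, inc, drop = FALSE]
  }
  raster_layer(out, target, name = layer$name)
}

#' Convert a float layer to scaled-integer form
#'
#' Multiplies the layer by a power of ten and rounds so that the largest
#' absolute value fits in at most `max_digits` decimal digits, then records
#' the scale in the layer name (suffix `_x10e<p>`). A layer that is already
#' whole-valued and within range is returned unchanged (scale `10^0`).
#' Rank order of distinct values is preserved up to rounding ties.
#'
#' @param layer An [raster_layer()] with finite (or `NA`) values.
#' @param max_digits Maximum number of digits of the largest value.
#' @return The quantized layer, with attribute `scale_pow10`.
#' @export
quantize_integer <- function(layer, max_digits = 7) {
  stopifnot(is_raster_layer(layer), max_digits >= 1)
  v <- layer$values
  fin <- v[is.finite(v)]
  if (!length(fin)) stop("all-nodata layer cannot be quantized")
  maxabs <- max(abs(fin))
  if (maxabs == 0) {
    out <- layer
    out$values[is.finite(out$values)] <- 0
    attr(out, "scale_pow10") <- 0L
    return(out)
  }
  if (all(fin == round(fin)) && maxabs < 10^max_digits) {
    attr(layer, "scale_pow10") <- 0L
    return(layer)
  }
  p <- ceiling(max_digits - log10(maxabs)) - 1
  out <- layer
  out$values <- round(v * 10^p)
  out$name <- paste0(layer$name, "_x10e", p)
  attr(out, "scale_pow10") <- as.integer(p)
  out
}

#' Focal window size in pixels
#'
#' Converts a window side length in metres to the odd pixel count nearest to
#' `window_m / pixel_size`, so every focal window has a centre pixel
#' (310 m at 9.5 m pixels gives 33 px; 990 m gives 105 px).
#'
#' @param window_m Window side (m); must be at least one pixel.
#' @param pixel_size Pixel edge (m).
#' @return Odd integer window side in pixels.
#' @export
meters_to_pixels <- function(window_m, pixel_size = 9.5) {
  stopifnot(pixel_size > 0)
  if (window_m < pixel_size) stop("window (", window_m, " m) smaller than one pixel")
  k <- window_m / pixel_size
  as.integer(max(1, 2 * round((k - 1) / 2) + 1))
}

#' Crop a buffered layer back to a core extent
#'
#' Drops `margin_px` pixels from every edge; used to discard the buffer that
#' absorbs focal-window edge effects.
#'
#' @param layer An [raster_layer()].
#' @param margin_px Pixels to remove on each side.
#' @return The cropped layer.
#' @export
crop_margin <- function(layer, margin_px) {
  stopifnot(is_raster_layer(layer), margin_px >= 0)
  g <- layer$grid
  if (2 * margin_px >= min(g$n_rows, g$n_cols))
    stop("margin larger than the raster")
  if (margin_px == 0) return(layer)
  rows <- (margin_px + 1):(g$n_rows - margin_px)
  cols <- (margin_px + 1):(g$n_cols - margin_px)
  ng <- grid_spec(origin_x = g$origin_x + margin_px * g$pixel_size,
                  origin_y = g$origin_y - margin_px * g$pixel_size,
                  pixel_size = g$pixel_size,
                  n_rows = length(rows), n_cols = length(cols),
                  crs_tag = g$crs_tag)
  raster_layer(layer$values[rows, cols, drop = FALSE], ng, name = layer$name)
}

#' Convert a raster layer to a tibble
#'
#' @param x An [raster_layer()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x`, `y`, `value` (nodata rows kept as `NA`).
#' @method as_tibble rc_raster
#' @export
as_tibble.rc_raster <- function(x, ...) {
  co <- grid_coordinates(x$grid)
  co$value <- x$values[cbind(co$row, co$col)]
  co
}
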