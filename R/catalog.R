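feature_families <- c("topography", "raw_index", "multitemporal_diff",
                      "pc_raw_range", "raw_texture", "binary_texture",
                      "pc_texture_range")

texture_letters <- c(mean = "m", variance = "v", contrast = "c", entropy = "e")

blue_dependent <- c("bndvi", "gbndvi", "sarvi")

#' Feature catalog configuration
#'
#' Declarative description of the seven predictor families derived from a
#' two-date scene: which indices exist per date (the second date has no
#' blue band, so blue-dependent indices are date-1 only), which central
#' ranges, focal windows and texture statistics are enumerated, and which
#' index rasters feed each derived family (`NULL` = all available).
#'
#' @param indices08 Indices computed from the 4-band date-1 image.
#' @param indices10 Indices computed from the 3-band (no blue) date-2 image.
#' @param transformed_raw Named numeric vector: raw index rasters receiving
#'   an additional [signed_power_transform()], values are the exponents
#'   (e.g. `c(sarvi08 = 2)`).
#' @param raw_ranges Central percentages for preferred ranges of raw index
#'   values (conventionally 50 and 70).
#' @param texture_ranges Central percentages for preferred ranges of
#'   texture values (conventionally 70, 80, 85, 90).
#' @param windows Focal window sides in metres (310 and 990).
#' @param textures Texture letters: `m`ean, `v`ariance, `c`ontrast,
#'   `e`ntropy.
#' @param families Enabled feature families.
#' @param pc_raw_sources,texture_sources,binary_texture_sources,
#'   pc_texture_sources Optional character vectors of index-raster names
#'   (e.g. `"bndvi08"`) feeding each derived family; `NULL` enumerates all.
#' @return A `catalog_config` list.
#' @export
catalog_config <- function(indices08 = c("ndvi", "bndvi", "gbndvi", "grndi", "sarvi"),
                           indices10 = c("ndvi", "grndi"),
                           transformed_raw = c(sarvi08 = 2),
                           raw_ranges = c(50, 70),
                           texture_ranges = c(70, 80, 85, 90),
                           windows = c(310, 990),
                           textures = c("m", "v", "c", "e"),
                           families = feature_families,
                           pc_raw_sources = NULL,
                           texture_sources = NULL,
                           binary_texture_sources = NULL,
                           pc_texture_sources = NULL) {
  families <- match.arg(families, feature_families, several.ok = TRUE)
  bad10 <- intersect(indices10, blue_dependent)
  if (length(bad10))
    stop("blue-dependent index for the blue-less date-2 image: ",
         paste(bad10, collapse = ", "))
  stopifnot(all(textures %in% texture_letters))
  structure(list(indices08 = indices08, indices10 = indices10,
                 transformed_raw = transformed_raw,
                 raw_ranges = raw_ranges, texture_ranges = texture_ranges,
                 windows = windows, textures = textures, families = families,
                 pc_raw_sources = pc_raw_sources,
                 texture_sources = texture_sources,
                 binary_texture_sources = binary_texture_sources,
                 pc_texture_sources = pc_texture_sources),
            class = "catalog_config")
}

index_year_rasters <- function(config) {
  c(paste0(config$indices08, "08"), paste0(config$indices10, "10"))
}

spec_row <- function(name, family, index = NA, year = NA, texture = NA,
                     window_m = NA, range_pct = NA, normalized = NA,
                     transform_exp = NA) {
  tibble::tibble(name = name, family = family, index = index, year = year,
                 texture = texture, window_m = as.numeric(window_m),
                 range_pct = as.numeric(range_pct),
                 normalized = as.logical(normalized),
                 transform_exp = as.numeric(transform_exp))
}

#' Build the feature catalog
#'
#' Deterministically enumerates every predictor the configuration implies,
#' one row per feature: topography; raw indices per date (respecting band
#' availability); simple and normalized multitemporal differences for
#' indices present on both dates; and the cross-products of index rasters
#' with ranges, windows and texture statistics for the derived families.
#' Names follow the compact field convention (see [feature_name()]).
#'
#' @param config A [catalog_config()].
#' @return Tibble of feature specs (one row per feature, no duplicates).
#' @export
build_catalog <- function(config = catalog_config()) {
  stopifnot(inherits(config, "catalog_config"))
  rows <- list()
  fam <- config$families
  if ("topography" %in% fam)
    rows <- c(rows, list(spec_row("elevation", "topography")))
  iy <- index_year_rasters(config)
  split_iy <- function(nm) list(index = sub("\\d{2}$", "", nm),
                                year = sub("^[a-z]+", "", nm))
  if ("raw_index" %in% fam) {
    for (nm in iy) {
      p <- split_iy(nm)
      rows <- c(rows, list(spec_row(nm, "raw_index", p$index, p$year)))
    }
    for (nm in names(config$transformed_raw)) {
      p <- split_iy(nm)
      rows <- c(rows, list(spec_row(paste0(nm, "trans"), "raw_index", p$index,
                                    p$year,
                                    transform_exp = config$transformed_raw[[nm]])))
    }
  }
  if ("multitemporal_diff" %in% fam) {
    both <- intersect(config$indices08, config$indices10)
    for (ix in both) for (norm in c(FALSE, TRUE)) {
      code <- index_short_code[[ix]]
      nm <- paste0(if (norm) "ndelt" else "delt", code, "10_08")
      rows <- c(rows, list(spec_row(nm, "multitemporal_diff", ix, "10",
                                    normalized = norm)))
    }
  }
  if ("pc_raw_range" %in% fam) {
    src <- config$pc_raw_sources %||% iy
    for (nm in src) for (pct in config$raw_ranges) for (w in config$windows) {
      p <- split_iy(nm)
      fname <- paste0(index_short_code[[p$index]], p$year, "_", pct, "_", w)
      rows <- c(rows, list(spec_row(fname, "pc_raw_range", p$index, p$year,
                                    window_m = w, range_pct = pct)))
    }
  }
  if ("raw_texture" %in% fam) {
    src <- config$texture_sources %||% iy
    for (nm in src) for (tx in config$textures) for (w in config$windows) {
      p <- split_iy(nm)
      fname <- paste0(index_short_code[[p$index]], p$year, "2", tx, w)
      rows <- c(rows, list(spec_row(fname, "raw_texture", p$index, p$year,
                                    texture = tx, window_m = w)))
    }
  }
  if ("binary_texture" %in% fam) {
    src <- config$binary_texture_sources %||% iy
    for (nm in src) for (tx in config$textures) for (w in config$windows)
      for (pct in config$raw_ranges) {
        p <- split_iy(nm)
        fname <- paste0(index_short_code[[p$index]], p$year, "2", tx, w, pct)
        rows <- c(rows, list(spec_row(fname, "binary_texture", p$index, p$year,
                                      texture = tx, window_m = w,
                                      range_pct = pct)))
      }
  }
  if ("pc_texture_range" %in% fam) {
    src <- config$pc_texture_sources %||% iy
    for (nm in src) for (tx in config$textures) for (w in config$windows)
      for (pct in config$texture_ranges) {
        p <- split_iy(nm)
        fname <- paste0(index_short_code[[p$index]], p$year, "2", tx,
                        substr(as.character(w), 1, 2), "pc", pct)
        rows <- c(rows, list(spec_row(fname, "pc_texture_range", p$index,
                                      p$year, texture = tx, window_m = w,
                                      range_pct = pct)))
      }
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Format a feature spec as its conventional name
#'
#' Naming patterns by family: `elevation`; raw `bndvi08` (suffix `trans`
#' when power-transformed); multitemporal `deltgrn10_08` /
#' `ndeltgrn10_08`; raw-range percent cover `bnd08_70_990`; raw texture
#' `bnd082c990`; binary-range texture `bnd082m31070`; texture-range percent
#' cover `ndv102e99pc70` (the parser additionally accepts the compact
#' `bnd082c9985` dialect). `parse_feature_name()` is the inverse;
#' `parse(format(spec)) == spec` for every catalog row.
#'
#' @param spec A single-row feature spec (list or one-row tibble with
#'   fields `family`, `index`, `year`, `texture`, `window_m`, `range_pct`,
#'   `normalized`, `transform_exp`).
#' @return Character name.
#' @export
feature_name <- function(spec) {
  spec <- as.list(spec)
  code <- function() index_short_code[[spec$index]]
  w <- spec$window_m
  switch(spec$family,
    topography = "elevation",
    raw_index = paste0(spec$index, spec$year,
                       if (!is.na(spec$transform_exp %||% NA)) "trans" else ""),
    multitemporal_diff = paste0(if (isTRUE(spec$normalized)) "ndelt" else "delt",
                                code(), "10_08"),
    pc_raw_range = paste0(code(), spec$year, "_", spec$range_pct, "_", w),
    raw_texture = paste0(code(), spec$year, "2", spec$texture, w),
    binary_texture = paste0(code(), spec$year, "2", spec$texture, w, spec$range_pct),
    pc_texture_range = paste0(code(), spec$year, "2", spec$texture,
                              substr(as.character(w), 1, 2), "pc", spec$range_pct),
    stop("unknown family: ", spec$family))
}

short_to_index <- stats::setNames(names(index_short_code), index_short_code)

#' @rdname feature_name
#' @param name A feature name.
#' @return `parse_feature_name()`: a one-row feature spec tibble.
#' @export
parse_feature_name <- function(name) {
  if (name == "elevation") return(spec_row(name, "topography"))
  m <- regmatches(name, regexec("^(ndvi|bndvi|gbndvi|grndi|sarvi)(\\d{2})(trans)?$", name))[[1]]
  if (length(m))
    return(spec_row(name, "raw_index", m[2], m[3],
                    transform_exp = if (nzchar(m[4])) 2 else NA))
  m <- regmatches(name, regexec("^(n?)delt(ndv|bnd|gbn|grn|srv)(\\d{2})_(\\d{2})$", name))[[1]]
  if (length(m))
    return(spec_row(name, "multitemporal_diff", short_to_index[[m[3]]], m[4],
                    normalized = nzchar(m[2])))
  m <- regmatches(name, regexec("^(ndv|bnd|gbn|grn|srv)(\\d{2})_(\\d{2})_(\\d{3})$", name))[[1]]
  if (length(m))
    return(spec_row(name, "pc_raw_range", short_to_index[[m[2]]], m[3],
                    window_m = as.numeric(m[5]), range_pct = as.numeric(m[4])))
  m <- regmatches(name, regexec("^(ndv|bnd|gbn|grn|srv)(\\d{2})2([mvce])(\\d{3})$", name))[[1]]
  if (length(m))
    return(spec_row(name, "raw_texture", short_to_index[[m[2]]], m[3],
                    texture = m[4], window_m = as.numeric(m[5])))
  m <- regmatches(name, regexec("^(ndv|bnd|gbn|grn|srv)(\\d{2})2([mvce])(310|990)(\\d{2})$", name))[[1]]
  if (length(m))
    return(spec_row(name, "binary_texture", short_to_index[[m[2]]], m[3],
                    texture = m[4], window_m = as.numeric(m[5]),
                    range_pct = as.numeric(m[6])))
  m <- regmatches(name, regexec("^(ndv|bnd|gbn|grn|srv)(\\d{2})2([mvce])(31|99)(?:pc)?(\\d{2})$", name))[[1]]
  if (length(m))
    return(spec_row(name, "pc_texture_range", short_to_index[[m[2]]], m[3],
                    texture = m[4],
                    window_m = if (m[5] == "31") 310 else 990,
                    range_pct = as.numeric(m[6])))
  stop("unparseable feature name: ", name)
}

letter_to_stat <- stats::setNames(names(texture_letters), texture_letters)

#' Compute the feature stack for a catalog
#'
#' Derives every feature in `catalog` from a scene, reusing shared
#' intermediates (raw indices, binary preferred masks, the four texture
#' statistics of one GLCM pass). Families built on presence-preferred
#' ranges require `withheld` points (the presence partition withheld from
#' modelling); the fitted central ranges are returned in the manifest so
#' any feature raster is reproducible from bands plus manifest.
#'
#' @param scene A scene list with `bands08`, `bands10`, `elevation` (a
#'   [generate_scene()] result, or equivalently structured real layers).
#' @param catalog Feature spec tibble from [build_catalog()] (or a
#'   character vector of feature names).
#' @param withheld Occurrence tibble of withheld presence points (needed
#'   for the preferred-range families).
#' @param glcm A [glcm_config()] supplying quantization/offset settings
#'   (its `window_m` is overridden per feature).
#' @param sarvi [sarvi_params()].
#' @return List with `stack` (named list of [raster_layer()]s in catalog
#'   order) and `manifest` (central ranges and settings).
#' @export
build_feature_stack <- function(scene, catalog, withheld = NULL,
                                glcm = glcm_config(), sarvi = sarvi_params()) {
  if (is.character(catalog))
    catalog <- dplyr::bind_rows(lapply(catalog, parse_feature_name))
  cache <- new.env(parent = emptyenv())
  ranges <- list()
  band_sets <- list(
    "08" = do.call(band_set, c(scene$bands08 |> stats::setNames(sub("08$", "", names(scene$bands08))),
                               list(year_tag = "08"))),
    "10" = do.call(band_set, c(scene$bands10 |> stats::setNames(sub("10$", "", names(scene$bands10))),
                               list(year_tag = "10"))))
  get_cached <- function(key, fn) {
    if (!exists(key, envir = cache)) assign(key, fn(), envir = cache)
    get(key, envir = cache)
  }
  raw_index <- function(index, year)
    get_cached(paste0(index, year), function()
      compute_index(band_sets[[year]], index, params = sarvi))
  withheld_values <- function(layer) {
    if (is.null(withheld) || !nrow(withheld))
      stop("preferred-range features need withheld presence points")
    rc <- coords_to_rowcol(layer$grid, withheld$x, withheld$y)
    if (anyNA(rc$row)) stop("withheld point(s) outside the scene grid")
    layer$values[cbind(rc$row, rc$col)]
  }
  preferred_binary <- function(layer, pct) {
    get_cached(paste0(layer$name, "_bin", pct), function() {
      rng <- central_range(withheld_values(layer), pct, source_feature = layer$name)
      ranges[[length(ranges) + 1]] <<- rng
      binarize_preferred(layer, rng)
    })
  }
  textures_of <- function(layer, window_m) {
    get_cached(paste0(layer$name, "_tex", window_m), function() {
      cfg <- glcm
      cfg$window_m <- window_m
      focal_textures(layer, cfg)
    })
  }
  compute_one <- function(s) {
    switch(s$family,
      topography = scene$elevation,
      raw_index = {
        l <- raw_index(s$index, s$year)
        if (!is.na(s$transform_exp)) l <- signed_power_transform(l, s$transform_exp)
        l
      },
      multitemporal_diff = {
        a <- raw_index(s$index, "10"); b <- raw_index(s$index, "08")
        if (isTRUE(s$normalized)) normalized_difference(a, b)
        else simple_difference(a, b)
      },
      pc_raw_range =
        percent_cover(preferred_binary(raw_index(s$index, s$year), s$range_pct),
                      s$window_m),
      raw_texture =
        textures_of(raw_index(s$index, s$year), s$window_m)[[letter_to_stat[[s$texture]]]],
      binary_texture =
        textures_of(preferred_binary(raw_index(s$index, s$year), s$range_pct),
                    s$window_m)[[letter_to_stat[[s$texture]]]],
      pc_texture_range = {
        tex <- textures_of(raw_index(s$index, s$year), s$window_m)[[letter_to_stat[[s$texture]]]]
        percent_cover(preferred_binary(tex, s$range_pct), s$window_m)
      },
      stop("unknown family: ", s$family))
  }
  stack <- vector("list", nrow(catalog))
  names(stack) <- catalog$name
  for (i in seq_len(nrow(catalog))) {
    s <- as.list(catalog[i, ])
    l <- compute_one(s)
    l$name <- s$name
    stack[[s$name]] <- l
  }
  manifest <- list(
    ranges = lapply(ranges, function(r)
      list(source_feature = r$source_feature, pct = r$pct, lo = r$lo,
           hi = r$hi, n_samples = r$n_samples)),
    glcm = list(n_levels = glcm$n_levels, symmetric = glcm$symmetric,
                offsets = glcm$offsets, log_base = glcm$log_base),
    sarvi = unclass(sarvi))
  list(stack = stack, manifest = manifest)
}

#' Compute a single feature from a scene by name
#'
#' @param scene A scene list (see [build_feature_stack()]).
#' @param name Feature name in the catalog convention.
#' @param withheld Withheld presence points (only for preferred-range
#'   families).
#' @param ... Passed to [build_feature_stack()].
#' @return An [raster_layer()].
#' @export
compute_feature <- function(scene, name, withheld = NULL, ...) {
  build_feature_stack(scene, name, withheld = withheld, ...)$stack[[name]]
}
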