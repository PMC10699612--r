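#' Calibrate a continuous suitability layer to binary presence/absence
#'
#' Thresholds a prediction raster at the model's max-TSS threshold (from
#' [max_tss()] on that model's own presence/pseudoabsence scores): 1 where
#' `prediction >= threshold`, else 0; nodata propagates.
#'
#' @param prediction An [raster_layer()] of continuous suitability.
#' @param tss_threshold Finite calibration threshold.
#' @return A binary [raster_layer()].
#' @export
calibrate_binary <- function(prediction, tss_threshold) {
  stopifnot(is_raster_layer(prediction))
  if (!is.finite(tss_threshold)) stop("non-finite calibration threshold")
  out <- prediction
  out$values <- ifelse(is.na(prediction$values), NA_real_,
                       as.numeric(prediction$values >= tss_threshold))
  out$name <- paste0(prediction$name, "_bin")
  out
}

#' Frequency-of-consensus count across ensemble members
#'
#' Pixelwise sum of the member binary indicators: how many of the
#' calibrated models agree the pixel is presence.
#'
#' @param binaries Non-empty list of binary [raster_layer()]s on one grid.
#' @return An [raster_layer()] with values `0 .. n_members`.
#' @export
consensus_count <- function(binaries) {
  stopifnot(length(binaries) >= 1)
  g <- binaries[[1]]
  for (b in binaries) stop_if_grid_mismatch(g, b)
  acc <- matrix(0, g$grid$n_rows, g$grid$n_cols)
  na_any <- matrix(FALSE, g$grid$n_rows, g$grid$n_cols)
  for (b in binaries) {
    v <- b$values
    na_any <- na_any | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[na_any] <- NA_real_
  raster_layer(acc, g$grid, name = "consensus_count")
}

#' Core / semi-core consensus masks
#'
#' `core`: pixels where every member agrees (count equals `n_members`,
#' 100% consensus). `semi_core`: pixels where at least half agree
#' (`count >= ceiling(n_members / 2)`; 6 of 12 in the standard ensemble).
#'
#' @param count Consensus-count [raster_layer()] from [consensus_count()].
#' @param n_members Number of ensemble members.
#' @param level `"core"` or `"semi_core"`.
#' @return A binary [raster_layer()].
#' @export
consensus_mask <- function(count, n_members, level = c("core", "semi_core")) {
  level <- match.arg(level)
  stopifnot(is_raster_layer(count), n_members >= 1)
  thr <- if (level == "core") n_members else ceiling(n_members / 2)
  out <- count
  out$values <- ifelse(is.na(count$values), NA_real_,
                       as.numeric(count$values >= thr))
  out$name <- level
  out
}

#' Areal extent of a binary mask
#'
#' Pixel count times the nominal pixel area (no geodesic correction;
#' grids are in projected metres): `km2 = n_ones * pixel_size^2 / 1e6`.
#'
#' @param mask A binary [raster_layer()].
#' @return Extent in square kilometres.
#' @export
areal_extent <- function(mask) {
  stopifnot(is_raster_layer(mask))
  sum(mask$values == 1, na.rm = TRUE) * mask$grid$pixel_size^2 / 1e6
}

#' Land-cover composition of a masked area
#'
#' Percentage of the mask's presence pixels falling in each land-use /
#' land-cover class; percentages sum to 100.
#'
#' @param mask A binary [raster_layer()].
#' @param lulc Categorical [raster_layer()] aligned to the mask.
#' @return Tibble with `class`, `class_name`, `n_pixels`, `percent`.
#' @export
lulc_composition <- function(mask, lulc) {
  stop_if_grid_mismatch(mask, lulc)
  sel <- which(mask$values == 1)
  if (!length(sel)) stop("empty mask: no presence pixels to compose")
  cls <- lulc$values[sel]
  cls <- cls[!is.na(cls)]
  tab <- table(cls)
  nm <- attr(lulc, "class_names")
  tibble::tibble(class = as.numeric(names(tab)),
                 class_name = if (!is.null(nm)) unname(nm[names(tab)])
                              else paste0("class_", names(tab)),
                 n_pixels = as.integer(tab),
                 percent = 100 * as.integer(tab) / sum(tab))
}

#' Overlap between two binary masks
#'
#' @param mask_a,mask_b Binary [raster_layer()]s on one grid.
#' @return List: `km2` (intersection extent) and `pct_a_in_b`
#'   (percentage of `mask_a`'s area inside `mask_b`; error if `mask_a`
#'   is empty).
#' @export
overlap_extent <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a, mask_b)
  inter <- mask_a
  inter$values <- as.numeric(mask_a$values == 1 & mask_b$values == 1)
  a_ext <- areal_extent(mask_a)
  if (a_ext == 0) stop("mask_a is empty; percentage undefined")
  list(km2 = areal_extent(inter), pct_a_in_b = 100 * areal_extent(inter) / a_ext)
}

#' Build the consensus ensemble from fitted members
#'
#' Predicts every ensemble member over the feature stack, calibrates each
#' to binary presence/absence at its own max-TSS threshold, and assembles
#' the frequency-of-consensus count, core and semi-core masks, their areal
#' extents, and (when a land-cover layer is supplied) their LULC
#' compositions.
#'
#' @param ensemble Output of [stage3_select_ensemble()] (fields `models`,
#'   `metrics` with `tss_threshold`).
#' @param stack Named list of feature [raster_layer()]s covering every
#'   member's variables.
#' @param lulc Optional categorical land-cover [raster_layer()].
#' @return An `ensemble_result` list: `members` (binary layers),
#'   `consensus`, `core`, `semi_core`, `extents_km2`, `lulc_core`,
#'   `lulc_semi_core`.
#' @export
build_ensemble_maps <- function(ensemble, stack, lulc = NULL) {
  n <- length(ensemble$models)
  members <- lapply(seq_len(n), function(i) {
    pred <- predict(ensemble$models[[i]], stack, type = "cloglog")
    calibrate_binary(pred, ensemble$metrics$tss_threshold[i])
  })
  cons <- consensus_count(members)
  core <- consensus_mask(cons, n, "core")
  semi <- consensus_mask(cons, n, "semi_core")
  grad <- consensus_mask(cons, 1, "core")  # any-agreement footprint
  grad$name <- "graduated"
  structure(list(
    members = members, consensus = cons, core = core, semi_core = semi,
    n_members = n,
    extents_km2 = c(core = areal_extent(core), semi_core = areal_extent(semi),
                    graduated = areal_extent(grad)),
    lulc_core = if (!is.null(lulc) && areal_extent(core) > 0)
      lulc_composition(core, lulc),
    lulc_semi_core = if (!is.null(lulc) && areal_extent(semi) > 0)
      lulc_composition(semi, lulc)),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d members; extents km2 core %.4g, semi-core %.4g, graduated %.4g>\n",
              x$n_members, x$extents_km2["core"], x$extents_km2["semi_core"],
              x$extents_km2["graduated"]))
  invisible(x)
}
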