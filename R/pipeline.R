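#' Desk-scale fixture feature set
#'
#' A compact catalog of 26 features spanning all seven families, sized for
#' a 200 x 200 synthetic scene: elevation; the seven raw index rasters; the
#' four multitemporal differences; six GLCM textures (including the date-2
#' NDVI entropy textures at both window sizes); four preferred-range
#' percent covers; two binary-range textures; and two texture-range percent
#' covers.
#'
#' @return Character vector of feature names.
#' @export
fixture_features <- function() {
  c("elevation",
    "ndvi08", "ndvi10", "grndi08", "grndi10", "bndvi08", "gbndvi08", "sarvi08",
    "deltndv10_08", "ndeltndv10_08", "deltgrn10_08", "ndeltgrn10_08",
    "ndv102e310", "ndv102e990", "ndv102c310", "grn102e310", "ndv082e310",
    "bnd082c310",
    "ndv08_50_310", "ndv08_70_310", "grn10_50_310", "bnd08_70_310",
    "ndv082e31070", "grn102c31050",
    "ndv102e31pc70", "bnd082c31pc85")
}

#' Assemble the modelling data for one synthetic study
#'
#' Generates the scene and ground truth, samples and partitions presence
#' points (accuracy filter, 80/20 withholding, spatial thinning of the
#' modelling partition), generates background and pseudoabsence points,
#' computes the feature stack (preferred ranges estimated from the withheld
#' partition only), and extracts the SWD table.
#'
#' @param scene_cfg A [scene_config()].
#' @param truth A [truth_model()].
#' @param features Character vector of catalog feature names.
#' @param n_presence Presence points sampled from the truth surface
#'   (before filtering/withholding/thinning).
#' @param n_background,n_pseudoabsence Point counts.
#' @param bg_min_sep_m Minimum pairwise separation of background and
#'   pseudoabsence points. The full-study convention is 100 m; the default
#'   here is 30 m because a 200 x 200 desk scene (3.6 km2) cannot hold a
#'   thousand points 100 m apart.
#' @param exclusion_m Pseudoabsence exclusion radius around modelling
#'   presences. The full-study convention is 200 m, scaled to 100 m on the
#'   desk extent for the same packing reason.
#' @param thin_m Spatial-thinning diameter for the modelling presences
#'   (full-study convention 100 m, scaled to 50 m on the desk extent).
#' @param seed Master seed (substreams derived per step).
#' @param lulc_classes Classes in the synthetic land-cover layer.
#' @return List: `scene`, `truth_suitability`, `points`, `stack`,
#'   `manifest`, `swd`, `lulc`.
#' @export
prepare_study <- function(scene_cfg = scene_config(), truth = truth_model(),
                          features = fixture_features(),
                          n_presence = 250, n_background = 1000,
                          n_pseudoabsence = 1000, bg_min_sep_m = 30,
                          exclusion_m = 100, thin_m = 50, seed = 1,
                          lulc_classes = 5) {
  scene_cfg$seed <- substream_seed(seed, "scene")
  scene <- generate_scene(scene_cfg)
  suit <- derive_truth_suitability(scene, truth)
  presence <- sample_presence_points(suit, n_presence,
                                     seed = substream_seed(seed, "presence")) |>
    filter_by_accuracy(100) |>
    split_presence(0.2, seed = substream_seed(seed, "split"))
  withheld <- presence[presence$role == "presence_withheld", ]
  modelling <- spatial_thin(presence[presence$role == "presence_model", ],
                            thin_m, seed = substream_seed(seed, "thin"))
  background <- generate_background(scene$grid, n_background, bg_min_sep_m,
                                    seed = substream_seed(seed, "background"))
  pseudo <- generate_pseudoabsence(scene$grid, n_pseudoabsence, modelling,
                                   min_sep_m = bg_min_sep_m,
                                   exclusion_m = exclusion_m,
                                   seed = substream_seed(seed, "pseudo"))
  fs <- build_feature_stack(scene, features, withheld = withheld)
  points <- dplyr::bind_rows(modelling, withheld, background, pseudo)
  swd <- extract_swd(dplyr::bind_rows(modelling, background, pseudo), fs$stack)
  lulc <- generate_lulc(suit, lulc_classes, seed = substream_seed(seed, "lulc"))
  list(scene = scene, truth_suitability = suit, points = points,
       stack = fs$stack, manifest = fs$manifest, swd = swd, lulc = lulc,
       withheld = withheld)
}

#' Run the end-to-end habitat-modelling pipeline
#'
#' Scene (or supplied study data) to catalog features to SWD to RSFSA-CV
#' stages to the 12-model calibrated ensemble with consensus maps, extents,
#' land-cover composition and the variable-ranking ledger, writing every
#' artifact (CSV ledgers, ASCII-grid rasters, a JSON manifest of seeds and
#' resolved settings) under one output directory. With a fixed master seed
#' the run is fully reproducible.
#'
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param study Optional precomputed [prepare_study()] result.
#' @param rsfsa An [rsfsa_config()].
#' @param seed Master seed.
#' @param ... Passed to [prepare_study()] when `study` is `NULL`.
#' @return Invisibly, a list: `study`, `result` (the `rsfsa_result`),
#'   `maps` (the `ensemble_result`), `out_dir`.
#' @export
run_pipeline <- function(out_dir = NULL, study = NULL,
                         rsfsa = rsfsa_config(sizes = 1:4,
                                              stage1_subsets_per_size = 60,
                                              stage2_subsets = 200,
                                              stage2_top = 40),
                         seed = 1, ...) {
  stage <- "prepare"
  res <- tryCatch({
    if (is.null(study)) study <- prepare_study(seed = seed, ...)
    stage <- "select"
    result <- run_rsfsa(study$swd, rsfsa, seed = substream_seed(seed, "rsfsa"))
    stage <- "ensemble"
    maps <- build_ensemble_maps(result$ensemble, study$stack, lulc = study$lulc)
    list(study = study, result = result, maps = maps)
  }, error = function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_occurrence(res$study$points, file.path(out_dir, "points.csv"))
    write_swd(res$study$swd, file.path(out_dir, "swd.csv"))
    utils::write.csv(
      dplyr::mutate(res$result$ranking,
                    dplyr::across(dplyr::where(is.numeric), \(x) round(x, 10))),
      file.path(out_dir, "variable_ranking.csv"), row.names = FALSE)
    metrics <- res$result$ensemble$metrics
    metrics$features <- vapply(metrics$features, paste, character(1), collapse = "|")
    utils::write.csv(metrics, file.path(out_dir, "ensemble_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$result$stage1$by_size,
                     file.path(out_dir, "stage1_by_size.csv"), row.names = FALSE)
    write_raster(res$maps$consensus, file.path(out_dir, "consensus_count.asc"))
    write_raster(res$maps$core, file.path(out_dir, "core_mask.asc"))
    write_raster(res$maps$semi_core, file.path(out_dir, "semi_core_mask.asc"))
    ext <- res$maps$extents_km2
    utils::write.csv(tibble::tibble(mask = names(ext), extent_km2 = unname(ext)),
                     file.path(out_dir, "extents.csv"), row.names = FALSE)
    if (!is.null(res$maps$lulc_core))
      utils::write.csv(res$maps$lulc_core,
                       file.path(out_dir, "lulc_core.csv"), row.names = FALSE)
    manifest <- list(
      seed = seed,
      rsfsa = unclass(res$result$config)[setdiff(names(res$result$config), "model")],
      model = unclass(res$result$config$model),
      stage1 = list(size = res$result$stage1$size,
                    criterion = res$result$stage1$criterion,
                    fallback = res$result$stage1$fallback),
      feature_manifest = res$study$manifest,
      extents_km2 = as.list(ext))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(c(res, list(out_dir = out_dir)))
}
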