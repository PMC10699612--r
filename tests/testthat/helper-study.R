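# A small shared study fixture, built lazily once per test run. 120x120
# scene, reduced point counts and a 10-feature catalog keep the selection
# tests fast while exercising every module.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- prepare_study(
        scene_cfg = scene_config(n_rows = 120, n_cols = 120, seed = 404),
        truth = truth_model(),
        features = c("elevation", "ndvi08", "ndvi10", "grndi10", "bndvi08",
                     "deltndv10_08", "ndv102e310", "ndv102c310",
                     "ndv08_50_310", "ndv082e31070"),
        n_presence = 150, n_background = 350, n_pseudoabsence = 350,
        bg_min_sep_m = 20, exclusion_m = 60,
        seed = 404)
    }
    cache
  }
})
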