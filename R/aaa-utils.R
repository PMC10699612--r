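`%||%` <- function(a, b) if (is.null(a)) b else a

# three-letter index codes used in derived-feature names
index_short_code <- c(ndvi = "ndv", bndvi = "bnd", gbndvi = "gbn",
                      grndi = "grn", sarvi = "srv")
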