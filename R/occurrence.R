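#' Construct / validate an occurrence tibble
#'
#' Occurrence sets are plain tibbles with columns `x`, `y` (projected map
#' metres), `role` (one of `presence`, `presence_model`, `presence_withheld`,
#' `background`, `pseudoabsence`), `accuracy_m` (reported positional
#' accuracy) and `source_tag`. All point-handling verbs take and return this
#' shape so they chain with the pipe.
#'
#' @param x,y Numeric coordinates (m).
#' @param role Point role.
#' @param accuracy_m Positional accuracy (m, >= 0); `NA` allowed for
#'   generated background/pseudoabsence points.
#' @param source_tag Free-text provenance tag.
#' @return A validated occurrence tibble.
#' @export
occurrence_points <- function(x, y, role = "presence", accuracy_m = NA_real_,
                              source_tag = "unknown") {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        role = role, accuracy_m = as.numeric(accuracy_m),
                        source_tag = source_tag)
  validate_occurrence(out)
}

occ_roles <- c("presence", "presence_model", "presence_withheld",
               "background", "pseudoabsence")

validate_occurrence <- function(points) {
  need <- c("x", "y", "role")
  missing_c <- setdiff(need, names(points))
  if (length(missing_c))
    stop("occurrence table lacks column(s): ", paste(missing_c, collapse = ", "))
  bad <- setdiff(unique(points$role), occ_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (!"accuracy_m" %in% names(points)) points$accuracy_m <- NA_real_
  if (!"source_tag" %in% names(points)) points$source_tag <- "unknown"
  if (any(points$accuracy_m < 0, na.rm = TRUE)) stop("accuracy_m must be >= 0")
  tibble::as_tibble(points)
}

#' Read / write occurrence points as CSV
#'
#' Plain CSV with header `x, y, role, accuracy_m, source_tag`.
#'
#' @param path File path.
#' @return [read_occurrence()]: an occurrence tibble.
#' @export
read_occurrence <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  validate_occurrence(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrence
#' @param points An occurrence tibble.
#' @export
write_occurrence <- function(points, path) {
  utils::write.csv(validate_occurrence(points), path, row.names = FALSE)
  invisible(path)
}

#' Filter points by positional accuracy
#'
#' Keeps points whose reported accuracy is at or below `max_m` (boundary
#' inclusive). Points with missing accuracy are dropped.
#'
#' @param points Occurrence tibble.
#' @param max_m Accuracy ceiling in metres (default 100).
#' @return Filtered occurrence tibble.
#' @export
filter_by_accuracy <- function(points, max_m = 100) {
  points <- validate_occurrence(points)
  dplyr::filter(points, !is.na(.data$accuracy_m), .data$accuracy_m <= max_m)
}

#' Split presence points into modelling and withheld partitions
#'
#' Random disjoint partition of the presence points: `round(fraction * n)`
#' points are withheld (for estimating preferred value ranges) and the rest
#' are allocated to modelling. Roles are stamped `presence_model` /
#' `presence_withheld`. The split precedes spatial thinning, which is then
#' applied to the modelling partition only.
#'
#' @param points Occurrence tibble of presence points (n >= 5).
#' @param withheld_fraction Fraction withheld, strictly inside (0, 1);
#'   default 0.2 (an 80/20 split).
#' @param seed Integer seed.
#' @return The input tibble with roles stamped (withheld rows last).
#' @export
split_presence <- function(points, withheld_fraction = 0.2, seed = 1) {
  points <- validate_occurrence(points)
  n <- nrow(points)
  if (n < 5) stop("need at least 5 presence points to split")
  if (withheld_fraction <= 0 || withheld_fraction >= 1)
    stop("withheld_fraction must be inside (0, 1)")
  n_withheld <- round(withheld_fraction * n)
  with_seed(seed, {
    idx <- sample.int(n, n_withheld)
    points$role <- "presence_model"
    points$role[idx] <- "presence_withheld"
  })
  points
}

#' Spatially thin points to a minimum separation
#'
#' Retains a single random point wherever points cluster within a circle of
#' the given diameter: points are visited in seeded random order and
#' greedily accepted when at least `diameter_m` from every already-accepted
#' point, so no two retained points are closer than `diameter_m`.
#'
#' @param points Occurrence tibble.
#' @param diameter_m Minimum pairwise separation (m), default 100.
#' @param seed Integer seed (controls which cluster member survives).
#' @return Thinned occurrence tibble (original row order preserved).
#' @export
spatial_thin <- function(points, diameter_m = 100, seed = 1) {
  points <- validate_occurrence(points)
  n <- nrow(points)
  if (n <= 1) return(points)
  with_seed(seed, {
    ord <- sample.int(n)
    keep <- greedy_min_sep(points$x[ord], points$y[ord], diameter_m)
    points[sort(ord[keep]), ]
  })
}

# greedy acceptance with a cell hash so pairwise checks stay local
greedy_min_sep <- function(x, y, min_sep, accepted_x = numeric(0),
                           accepted_y = numeric(0)) {
  n <- length(x)
  keep <- logical(n)
  cell <- function(cx, cy) paste(floor(cx / min_sep), floor(cy / min_sep))
  ht <- new.env(parent = emptyenv(), hash = TRUE)
  put <- function(cx, cy) {
    key <- cell(cx, cy)
    ht[[key]] <- rbind(if (!is.null(ht[[key]])) ht[[key]], c(cx, cy))
  }
  clear <- function(cx, cy) {
    fx <- floor(cx / min_sep); fy <- floor(cy / min_sep)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(fx + dx, fy + dy)
      pts <- ht[[key]]
      if (!is.null(pts) &&
          any((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 < min_sep^2))
        return(FALSE)
    }
    TRUE
  }
  for (i in seq_along(accepted_x)) put(accepted_x[i], accepted_y[i])
  for (i in seq_len(n)) {
    if (clear(x[i], y[i])) { keep[i] <- TRUE; put(x[i], y[i]) }
  }
  keep
}

#' Generate background points
#'
#' Uniform random points over the grid extent with a minimum pairwise
#' separation, via seeded rejection sampling (candidates violating the
#' separation are discarded; sampling aborts if the extent cannot hold `n`
#' points at the requested spacing within a bounded number of attempts).
#'
#' @param extent A [grid_spec()] defining the sampling extent.
#' @param n Number of points (the conventional default is 10,000 at full
#'   study scale).
#' @param min_sep_m Minimum pairwise separation (m), default 100.
#' @param seed Integer seed.
#' @param role Role stamped on the points.
#' @param avoid_x,avoid_y Optional coordinates the points must also keep
#'   `avoid_m` away from.
#' @param avoid_m Exclusion distance for `avoid_x/avoid_y`.
#' @return Occurrence tibble with `n` rows.
#' @export
generate_background <- function(extent, n = 10000, min_sep_m = 100, seed = 1,
                                role = "background",
                                avoid_x = numeric(0), avoid_y = numeric(0),
                                avoid_m = 0) {
  stopifnot(inherits(extent, "rc_grid"), n >= 1)
  half <- extent$pixel_size / 2
  x0 <- extent$origin_x - half; x1 <- extent$origin_x + (extent$n_cols - 1) * extent$pixel_size + half
  y1 <- extent$origin_y + half; y0 <- extent$origin_y - (extent$n_rows - 1) * extent$pixel_size - half
  with_seed(seed, {
    acc_x <- numeric(0); acc_y <- numeric(0)
    attempts <- 0L
    max_attempts <- 200L * n + 1000L
    while (length(acc_x) < n && attempts < max_attempts) {
      m <- min(4L * (n - length(acc_x)), 5000L)
      attempts <- attempts + m
      cx <- stats::runif(m, x0, x1); cy <- stats::runif(m, y0, y1)
      if (avoid_m > 0 && length(avoid_x)) {
        ok <- vapply(seq_len(m), function(i)
          all((avoid_x - cx[i])^2 + (avoid_y - cy[i])^2 >= avoid_m^2), logical(1))
        cx <- cx[ok]; cy <- cy[ok]
      }
      if (!length(cx)) next
      keep <- greedy_min_sep(cx, cy, min_sep_m, acc_x, acc_y)
      acc_x <- c(acc_x, cx[keep]); acc_y <- c(acc_y, cy[keep])
    }
    if (length(acc_x) < n)
      stop("could not place ", n, " points at ", min_sep_m,
           " m separation in this extent (placed ", length(acc_x), ")")
    tibble::tibble(x = acc_x[seq_len(n)], y = acc_y[seq_len(n)], role = role,
                   accuracy_m = NA_real_, source_tag = "generated")
  })
}

#' Generate pseudoabsence points
#'
#' Background-style points that are additionally excluded from the
#' neighbourhood of every true presence point: candidates within
#' `exclusion_m` (default 200 m) of any presence are rejected.
#'
#' @inheritParams generate_background
#' @param presence Occurrence tibble of presence points to avoid.
#' @param exclusion_m Exclusion radius around presences (m), default 200.
#' @return Occurrence tibble with `n` rows, role `pseudoabsence`.
#' @export
generate_pseudoabsence <- function(extent, n, presence, min_sep_m = 100,
                                   exclusion_m = 200, seed = 1) {
  presence <- validate_occurrence(presence)
  generate_background(extent, n = n, min_sep_m = min_sep_m, seed = seed,
                      role = "pseudoabsence",
                      avoid_x = presence$x, avoid_y = presence$y,
                      avoid_m = exclusion_m)
}

#' Extract a samples-with-data (SWD) table
#'
#' Looks up the value of every feature raster at the pixel containing each
#' point and returns one row per point: `role`, `x`, `y`, then one column
#' per feature. Rows touching nodata in any feature are dropped; the count
#' of dropped rows is recorded in attribute `n_dropped` (and messaged).
#'
#' @param points Occurrence tibble (all points inside the grid).
#' @param stack Named list of aligned [raster_layer()]s.
#' @return SWD tibble.
#' @export
extract_swd <- function(points, stack) {
  points <- validate_occurrence(points)
  stopifnot(length(stack) >= 1)
  if (is.null(names(stack)) || any(!nzchar(names(stack))))
    names(stack) <- vapply(stack, function(l) l$name, character(1))
  g <- stack[[1]]$grid
  for (l in stack) if (!grids_identical(l$grid, g)) stop("stack layers on different grids")
  rc <- coords_to_rowcol(g, points$x, points$y)
  if (anyNA(rc$row)) stop(sum(is.na(rc$row)), " point(s) fall outside the grid")
  out <- points[, c("role", "x", "y")]
  for (nm in names(stack))
    out[[nm]] <- stack[[nm]]$values[cbind(rc$row, rc$col)]
  feat <- as.matrix(out[, names(stack), drop = FALSE])
  ok <- stats::complete.cases(feat)
  if (any(!ok)) message(sum(!ok), " point(s) dropped for nodata feature values")
  res <- out[ok, ]
  attr(res, "n_dropped") <- sum(!ok)
  attr(res, "feature_names") <- names(stack)
  res
}

#' Feature column names of an SWD table
#' @param swd An SWD tibble from [extract_swd()].
#' @return Character vector of feature column names.
#' @export
swd_features <- function(swd) {
  fn <- attr(swd, "feature_names")
  if (!is.null(fn)) return(intersect(fn, names(swd)))
  setdiff(names(swd), c("role", "x", "y", "species"))
}

#' Write an SWD table in the MaxEnt SWD CSV dialect
#'
#' Columns `species, x, y, <feature...>`; the `species` column carries the
#' point role.
#'
#' @param swd SWD tibble.
#' @param path Output CSV path.
#' @export
write_swd <- function(swd, path) {
  out <- cbind(species = swd$role, swd[, c("x", "y", swd_features(swd))])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
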