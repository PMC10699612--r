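test_that("quantize_levels bins the global range into balanced levels", {
  b <- raster_layer(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(quantize_levels(b, 2)$values, b$values)
  expect_true(all(quantize_levels(raster_layer(matrix(5, 3, 3)), 16)$values == 0))
  set.seed(12)
  u <- raster_layer(matrix(runif(6400), 80, 80))
  lev <- quantize_levels(u, 16)$values
  expect_setequal(sort(unique(as.vector(lev))), 0:15)
  # uniform input: level counts equal within multinomial error
  cs <- suppressWarnings(chisq.test(table(factor(lev, levels = 0:15))))
  expect_gt(cs$p.value, 1e-4)
})

test_that("single-window GLCM matches enumeration on canonical cases", {
  cfg2 <- glcm_config(n_levels = 2, offsets = rbind(c(0L, 1L)))
  # constant window: all mass at p(0,0)
  p <- glcm_matrix(matrix(0L, 4, 4), cfg2)
  expect_equal(p[1, 1], 1)
  expect_equal(sum(p), 1)
  # 1-D strip [0,1,0,1], offset (0,1), symmetric: p(0,1) = p(1,0) = 0.5
  strip <- matrix(c(0L, 1L, 0L, 1L), nrow = 1)
  ps <- glcm_matrix(strip, cfg2)
  expect_equal(ps[1, 2], 0.5)
  expect_equal(ps[2, 1], 0.5)
  expect_equal(ps[1, 1] + ps[2, 2], 0)
  # random 7x7 window equals the exhaustive pair-enumeration oracle
  set.seed(21)
  w <- matrix(sample(0:7, 49, replace = TRUE), 7, 7)
  cfg8 <- glcm_config(n_levels = 8)
  expect_equal(unclass(glcm_matrix(w, cfg8)),
               oracle_glcm(w, cfg8$offsets, TRUE, 8),
               ignore_attr = TRUE, tolerance = 1e-12)
  # symmetric mode is exactly symmetric
  expect_equal(unclass(glcm_matrix(w, cfg8)), t(unclass(glcm_matrix(w, cfg8))),
               ignore_attr = TRUE)
  expect_error(glcm_matrix(matrix(NA_integer_, 3, 3), cfg2), "no valid")
})

test_that("texture statistics evaluate their closed forms", {
  p00 <- matrix(0, 2, 2); p00[1, 1] <- 1
  for (s in c("mean", "variance", "contrast", "entropy"))
    expect_equal(texture_statistic(p00, s), 0)
  p01 <- matrix(0, 2, 2); p01[1, 2] <- 0.5; p01[2, 1] <- 0.5
  expect_equal(texture_statistic(p01, "mean"), 0.5)
  expect_equal(texture_statistic(p01, "variance"), 0.25)
  expect_equal(texture_statistic(p01, "contrast"), 1)
  expect_equal(texture_statistic(p01, "entropy"), log(2))
  unif <- matrix(0.25, 2, 2)
  expect_equal(texture_statistic(unif, "entropy"), log(4))
  expect_equal(texture_statistic(unif, "entropy", log_base = 2), 2)
  expect_error(texture_statistic(matrix(0.3, 2, 2), "mean"), "not normalized")
})

test_that("focal textures reproduce structure and bounds", {
  g <- grid_spec(n_rows = 40, n_cols = 40, pixel_size = 10)
  const <- raster_layer(matrix(3.7, 40, 40), g)
  for (s in c("mean", "variance", "contrast", "entropy"))
    expect_true(all(focal_texture(const, s, glcm_config(window_m = 50))$values == 0))

  # vertical stripes, horizontal offset only: contrast 1 at interior pixels
  stripes <- raster_layer(matrix(rep(c(0, 1), 20), 40, 40, byrow = TRUE), g)
  cfgh <- glcm_config(n_levels = 2, offsets = rbind(c(0L, 1L)), window_m = 50)
  ct <- focal_texture(stripes, "contrast", cfgh)
  inner <- ct$values[5:36, 5:36]
  expect_true(all(abs(inner - 1) < 1e-12))

  # entropy bounded by log(n_levels^2); all statistics nonnegative
  r <- rand_layer(40, 40, seed = 31, grid = g)
  tex <- focal_textures(r, glcm_config(n_levels = 6, window_m = 70))
  expect_true(all(tex$entropy$values <= log(36) + 1e-9))
  expect_true(all(tex$entropy$values >= 0))
  expect_true(all(tex$variance$values >= -1e-12))
  expect_true(all(tex$contrast$values >= 0))
  expect_error(focal_texture(r, "mean", glcm_config(window_m = 1000)),
               "larger than the raster")
})

test_that("focal path equals the single-window oracle at random pixels", {
  set.seed(17)
  g <- grid_spec(n_rows = 45, n_cols = 45, pixel_size = 10)
  r <- raster_layer(matrix(runif(2025), 45, 45), g)
  cfg <- glcm_config(n_levels = 8, window_m = 110)  # 11 px window
  lev <- quantize_levels(r, 8)$values
  tex <- focal_textures(r, cfg)
  for (i in 1:5) {
    rr <- sample(6:40, 1); cc <- sample(6:40, 1)
    for (s in c("mean", "variance", "contrast", "entropy"))
      expect_equal(tex[[s]]$values[rr, cc],
                   oracle_focal_texture(lev, rr, cc, 11, 8, cfg$offsets, TRUE, s),
                   tolerance = 1e-10)
  }
  # edge pixels (truncated windows) agree too
  for (s in c("mean", "contrast"))
    expect_equal(tex[[s]]$values[1, 1],
                 oracle_focal_texture(lev, 1, 1, 11, 8, cfg$offsets, TRUE, s),
                 tolerance = 1e-10)
})

test_that("shuffled rasters have higher mean focal entropy than autocorrelated ones", {
  sc <- generate_scene(scene_config(n_rows = 70, n_cols = 70, seed = 51,
                                    autocorr_px = 6))
  smooth_band <- sc$bands08$red
  set.seed(52)
  shuffled <- raster_layer(matrix(sample(smooth_band$values), 70, 70),
                           smooth_band$grid)
  cfg <- glcm_config(window_m = 150)
  e_smooth <- mean(focal_texture(smooth_band, "entropy", cfg)$values)
  e_shuf <- mean(focal_texture(shuffled, "entropy", cfg)$values)
  expect_gt(e_shuf, e_smooth)
})

test_that("binary inputs force two levels", {
  b <- raster_layer(matrix(sample(c(0, 1), 900, replace = TRUE), 30, 30),
                    grid_spec(n_rows = 30, n_cols = 30, pixel_size = 10))
  tex <- focal_textures(b, glcm_config(n_levels = 16, window_m = 70))
  expect_true(all(tex$entropy$values <= log(4) + 1e-9))
})
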