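# simple generators for presence-background data with known structure
gen_null_data <- function(seed, n_pres = 60, n_bg = 400, p = 3) {
  set.seed(seed)
  mk <- function(n) as.data.frame(matrix(rnorm(n * p), n,
                                         dimnames = list(NULL, paste0("v", 1:p))))
  list(pres = mk(n_pres), bg = mk(n_bg))
}

gen_signal_data <- function(seed, n_pres = 150, n_bg = 600, beta = 2) {
  set.seed(seed)
  bg <- data.frame(sig = rnorm(n_bg), noise = rnorm(n_bg))
  pool <- data.frame(sig = rnorm(20000), noise = rnorm(20000))
  keep <- runif(20000) < plogis(-2 + beta * pool$sig)
  list(pres = utils::head(pool[keep, ], n_pres), bg = bg)
}

test_that("null data give chance-level held-out background AUC", {
  aucs <- vapply(1:20, function(s) {
    d <- gen_null_data(s, n_pres = 120)
    tr <- 1:60
    fit <- suppressWarnings(fit_maxent_like(d$pres[tr, ], d$bg,
                                            model_spec(c("linear", "quadratic"))))
    eta_p <- predict(fit, d$pres[-tr, ], type = "link")
    eta_b <- predict(fit, d$bg, type = "link")
    rank_auc(eta_p, c(eta_b, eta_p))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the fitted coefficient recovers the generating sign", {
  hits <- vapply(1:10, function(s) {
    d <- gen_signal_data(s)
    fit <- fit_maxent_like(d$pres, d$bg, model_spec("linear"))
    unname(fit$beta["sig"])
  }, numeric(1))
  expect_true(all(hits > 0))
})

test_that("extreme l1 penalty collapses to the uniform model", {
  d <- gen_signal_data(3)
  fit <- fit_maxent_like(d$pres, d$bg,
                         model_spec(c("linear", "quadratic"), l1_penalty = 1e6))
  expect_true(all(fit$beta == 0))
  raw <- predict(fit, d$bg, type = "raw")
  expect_equal(raw, rep(1 / nrow(d$bg), nrow(d$bg)), tolerance = 1e-12)
})

test_that("raw predictions are background-normalized and match hand computation", {
  d <- gen_signal_data(5)
  fit <- fit_maxent_like(d$pres, d$bg, model_spec(c("linear", "quadratic")))
  raw_bg <- predict(fit, d$bg, type = "raw")
  expect_equal(sum(raw_bg), 1, tolerance = 1e-9)
  # spot-check rows against direct exp/normalization of the linear predictor
  eta_bg <- predict(fit, d$bg, type = "link")
  set.seed(1)
  rows <- sample(nrow(d$bg), 5)
  for (i in rows)
    expect_equal(raw_bg[i], exp(eta_bg[i]) / sum(exp(eta_bg)), tolerance = 1e-9)
  # cloglog is a monotone map of the linear predictor, inside [0, 1]
  cl <- predict(fit, d$bg, type = "cloglog")
  expect_true(all(cl >= 0 & cl <= 1))
  expect_true(all(diff(cl[order(eta_bg)]) >= -1e-12))
})

test_that("degenerate designs are reported, not silently absorbed", {
  d <- gen_null_data(1)
  d$pres$flat <- 1; d$bg$flat <- 1
  expect_warning(fit_maxent_like(d$pres, d$bg, model_spec("linear")), "constant")
  expect_error(fit_maxent_like(d$pres[1:5, ], d$bg), "at least 10")
})

test_that("rank_auc equals the concordant-pair oracle over random small inputs", {
  expect_equal(rank_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(rank_auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(rank_auc(rep(1, 5), rep(1, 7)), 0.5)
  set.seed(77)
  for (i in 1:200) {
    np <- sample(1:20, 1); nn <- sample(1:20, 1)
    pos <- sample(seq(0, 1, by = 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), nn, replace = TRUE)
    expect_equal(rank_auc(pos, neg), oracle_auc(pos, neg), tolerance = 1e-12)
  }
  expect_error(rank_auc(numeric(0), 1), "non-empty")
})

test_that("max_tss equals the exhaustive threshold scan", {
  expect_equal(max_tss(c(5, 6), c(1, 2))$tss, 1)
  res <- max_tss(c(0.9, 0.8, 0.4), c(0.6, 0.3, 0.2))
  expect_equal(res$tss, oracle_max_tss(c(0.9, 0.8, 0.4), c(0.6, 0.3, 0.2)))
  set.seed(78)
  for (i in 1:200) {
    pos <- round(runif(sample(2:15, 1)), 2)
    neg <- round(runif(sample(2:15, 1)), 2)
    got <- max_tss(pos, neg)
    expect_equal(got$tss, oracle_max_tss(pos, neg), tolerance = 1e-12)
    # reported threshold reproduces the reported TSS
    expect_equal(mean(pos >= got$threshold) + mean(neg < got$threshold) - 1,
                 got$tss, tolerance = 1e-12)
  }
  # near-identical distributions: TSS close to zero
  set.seed(79)
  expect_lt(max_tss(runif(500), runif(500))$tss, 0.12)
})

test_that("AICc follows its closed form and counts nonzero terms", {
  expect_equal(aicc_from_loglik(-100, 3, 50), 206 + 24 / 46)
  expect_equal(aicc_from_loglik(-77.5, 0, 10), 155)
  expect_warning(v <- aicc_from_loglik(-10, 9, 10), "undefined")
  expect_true(is.na(v))
  d <- gen_signal_data(6)
  fit <- fit_maxent_like(d$pres, d$bg, model_spec(c("linear", "quadratic")))
  k <- sum(fit$beta != 0)
  raw <- predict(fit, d$pres, type = "raw")
  expect_equal(aicc_bg(fit, d$pres, d$bg),
               aicc_from_loglik(sum(log(raw)), k, nrow(d$pres)),
               tolerance = 1e-9)
})

test_that("permutation importance separates signal from noise and normalizes", {
  d <- gen_signal_data(8)
  swd <- dplyr::bind_rows(dplyr::mutate(d$pres, role = "presence"),
                          dplyr::mutate(d$bg, role = "background"))
  fit <- fit_maxent_like(d$pres, d$bg, model_spec(c("linear", "quadratic")))
  wins <- vapply(1:10, function(s) {
    pi <- permutation_importance(fit, swd, n_perm = 2, seed = s)
    pi$importance[pi$variable == "sig"] > pi$importance[pi$variable == "noise"]
  }, logical(1))
  expect_gte(sum(wins), 9)
  pi <- permutation_importance(fit, swd, n_perm = 3, seed = 1)
  expect_equal(sum(pi$importance), 100, tolerance = 1e-9)
  # single-variable model: importance 100 by normalization
  fit1 <- fit_maxent_like(d$pres["sig"], d$bg["sig"], model_spec("linear"))
  pi1 <- permutation_importance(fit1, swd, n_perm = 2, seed = 1)
  expect_equal(pi1$importance, 100)
  expect_error(permutation_importance(fit, swd, variables = "absent"),
               "not in model")
})

test_that("marginal response curves are consistent with predict()", {
  d <- gen_signal_data(9)
  fit <- fit_maxent_like(d$pres, d$bg, model_spec("linear"))
  mr <- marginal_response(fit, "sig", n = 25)
  expect_equal(nrow(mr), 25)
  # positive linear coefficient: monotone nondecreasing curve
  expect_true(all(diff(mr$response) >= -1e-12))
  # spot values match predict() on explicitly constructed rows
  row <- data.frame(sig = mr$value[10], noise = mean(rbind(d$pres, d$bg)$noise))
  expect_equal(mr$response[10], predict(fit, row, type = "cloglog"),
               tolerance = 1e-9)
  expect_error(marginal_response(fit, "absent"), "not in model")
})

test_that("informed models beat the uniform model on held-out data", {
  wins <- vapply(1:20, function(s) {
    d <- gen_signal_data(s, n_pres = 120)
    tr <- 1:80
    fit <- fit_maxent_like(d$pres[tr, ], d$bg, model_spec("linear"))
    set.seed(s + 500)
    psa <- data.frame(sig = rnorm(200), noise = rnorm(200))
    auc_fit <- rank_auc(predict(fit, d$pres[-tr, ], type = "link"),
                        predict(fit, psa, type = "link"))
    auc_fit > 0.5  # the uniform model's AUC is exactly one half
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("raster-stack prediction matches row prediction", {
  g <- grid_spec(n_rows = 8, n_cols = 8, pixel_size = 10)
  set.seed(90)
  stack <- list(sig = raster_layer(matrix(rnorm(64), 8, 8), g, name = "sig"),
                noise = raster_layer(matrix(rnorm(64), 8, 8), g, name = "noise"))
  d <- gen_signal_data(10)
  fit <- fit_maxent_like(d$pres, d$bg, model_spec("linear"))
  pred <- predict(fit, stack, type = "cloglog")
  expect_s3_class(pred, "rc_raster")
  df <- data.frame(sig = as.vector(stack$sig$values),
                   noise = as.vector(stack$noise$values))
  expect_equal(as.vector(pred$values), predict(fit, df, type = "cloglog"),
               tolerance = 1e-12)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  pos <- rnorm(50, mean = 1); neg <- rnorm(80)
  ref <- as.numeric(pROC::auc(pROC::roc(response = c(rep(1, 50), rep(0, 80)),
                                        predictor = c(pos, neg),
                                        quiet = TRUE, direction = "<")))
  expect_equal(rank_auc(pos, neg), ref, tolerance = 1e-12)
})
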