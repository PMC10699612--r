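#' Model specification for the presence-background model
#'
#' The habitat model is a Gibbs density over the landscape,
#' `p(x) proportional to exp(beta . f(x))` normalized over the background
#' sample, fitted by l1-penalized maximum likelihood (the standard
#' maximum-entropy / infinitely-weighted-logistic equivalence). `f(x)` is a
#' basis expansion of the raw features: linear and quadratic terms plus
#' forward and reverse hinge terms at background quantile knots, echoing
#' MaxEnt's default feature classes at moderate sample sizes.
#'
#' @param feature_classes Subset of `"linear"`, `"quadratic"`, `"product"`,
#'   `"hinge"`; must include `"linear"`.
#' @param n_hinge_knots Interior quantile knots per feature (each yields a
#'   forward and a reverse hinge term).
#' @param l1_penalty Nonnegative lasso penalty on the basis coefficients.
#' @param output Default prediction scale: `"cloglog"` or `"raw"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(feature_classes = c("linear", "quadratic", "hinge"),
                       n_hinge_knots = 4, l1_penalty = 1e-4,
                       output = c("cloglog", "raw")) {
  feature_classes <- match.arg(feature_classes,
                               c("linear", "quadratic", "product", "hinge"),
                               several.ok = TRUE)
  if (!"linear" %in% feature_classes) stop("the linear feature class is required")
  stopifnot(l1_penalty >= 0, n_hinge_knots >= 1)
  structure(list(feature_classes = feature_classes,
                 n_hinge_knots = as.integer(n_hinge_knots),
                 l1_penalty = l1_penalty, output = match.arg(output)),
            class = "model_spec")
}

# basis definition from background reference rows: per-feature center/scale
# (background moments, the MaxEnt convention) and hinge knots
build_basis <- function(ref, features, spec) {
  info <- lapply(features, function(f) {
    v <- ref[[f]]
    mu <- mean(v); sdv <- stats::sd(v)
    knots <- NULL
    if ("hinge" %in% spec$feature_classes && sdv > 0) {
      probs <- seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1)
      knots <- unique(stats::quantile(v, probs, names = FALSE, type = 7))
    }
    list(name = f, mean = mu, sd = sdv, min = min(v), max = max(v), knots = knots)
  })
  names(info) <- features
  structure(list(features = features, info = info, spec = spec),
            class = "maxent_basis")
}

expand_basis <- function(basis, data) {
  spec <- basis$spec
  cols <- list()
  for (f in basis$features) {
    bi <- basis$info[[f]]
    v <- data[[f]]
    if (is.null(v)) stop("feature '", f, "' missing from data")
    z <- if (bi$sd > 0) (v - bi$mean) / bi$sd else v * 0
    cols[[f]] <- z
    if ("quadratic" %in% spec$feature_classes) cols[[paste0(f, "^2")]] <- z^2
    if (!is.null(bi$knots)) {
      rng <- bi$max - bi$min
      for (i in seq_along(bi$knots)) {
        k <- bi$knots[i]
        cols[[paste0(f, ":h", i)]] <- pmax(0, (v - k)) / rng
        cols[[paste0(f, ":rh", i)]] <- pmax(0, (k - v)) / rng
      }
    }
  }
  if ("product" %in% spec$feature_classes && length(basis$features) > 1) {
    fs <- basis$features
    for (i in seq_along(fs)[-length(fs)]) for (j in (i + 1):length(fs)) {
      zi <- cols[[fs[i]]]; zj <- cols[[fs[j]]]
      cols[[paste0(fs[i], "*", fs[j])]] <- zi * zj
    }
  }
  do.call(cbind, cols)
}

swd_feature_frame <- function(rows, features = NULL) {
  if (is.null(features))
    features <- setdiff(names(rows), c("role", "x", "y", "species"))
  rows <- as.data.frame(rows)[, features, drop = FALSE]
  stopifnot(all(vapply(rows, is.numeric, logical(1))))
  rows
}

#' Fit the maximum-entropy-style presence-background model
#'
#' Maximizes the l1-penalized presence log-likelihood of the Gibbs density
#' normalized over the background sample, via the weighted-logistic
#' equivalence (presence weight 1, background weight large) solved with
#' coordinate descent. Constant features are dropped with a warning rather
#' than silently absorbed; very large coefficients (quasi-separation) also
#' warn.
#'
#' @param presence,background Data frames (or SWD tibbles) of feature
#'   values at presence and background points. At least 10 presence rows;
#'   a background at least 10x the presence count is recommended.
#' @param spec A [model_spec()].
#' @param features Optional character vector restricting the feature columns
#'   used.
#' @return A `maxent_fit` object: coefficients over the expanded basis,
#'   standardization constants, background normalizer `Z`, entropy `H` of
#'   the fitted background distribution (used for cloglog calibration), and
#'   training references.
#' @export
fit_maxent_like <- function(presence, background, spec = model_spec(),
                            features = NULL) {
  pr <- swd_feature_frame(presence, features)
  bg <- swd_feature_frame(background)[, names(pr), drop = FALSE]
  if (nrow(pr) < 10) stop("need at least 10 presence rows")
  all_rows <- rbind(pr, bg)
  sds <- vapply(all_rows, stats::sd, numeric(1))
  dropped <- names(sds)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    pr <- pr[, setdiff(names(pr), dropped), drop = FALSE]
    bg <- bg[, setdiff(names(bg), dropped), drop = FALSE]
  }
  feats <- names(pr)
  if (!length(feats)) {
    warning("no informative features; returning a uniform (intercept-only) model")
    basis <- NULL
    beta <- numeric(0)
  } else {
    basis <- build_basis(bg, feats, spec)
    X <- expand_basis(basis, rbind(pr, bg))
    y <- c(rep(1, nrow(pr)), rep(0, nrow(bg)))
    w <- c(rep(1, nrow(pr)), rep(100, nrow(bg)))
    Xf <- if (ncol(X) < 2) cbind(X, .dummy = 0) else X
    lam <- max(spec$l1_penalty, 1e-8)
    fit <- glmnet::glmnet(Xf, y, family = "binomial", weights = w,
                          lambda = lam * c(64, 16, 4, 1),
                          standardize = FALSE)
    beta <- as.numeric(fit$beta[, ncol(fit$beta)])
    names(beta) <- rownames(fit$beta)
    beta <- beta[colnames(X)]
    if (any(abs(beta) > 50, na.rm = TRUE))
      warning("very large coefficients: possible separation / degenerate design")
  }
  eta_bg <- if (length(beta)) as.numeric(expand_basis(basis, bg) %*% beta)
            else rep(0, nrow(bg))
  m <- max(eta_bg)
  logZ <- m + log(sum(exp(eta_bg - m)))
  raw_bg <- exp(eta_bg - logZ)
  H <- -sum(raw_bg * log(pmax(raw_bg, 1e-300)))
  structure(list(spec = spec, basis = basis, beta = beta,
                 features = feats, dropped = dropped,
                 logZ = logZ, entropy = H,
                 n_presence = nrow(pr), n_background = nrow(bg),
                 train_means = vapply(rbind(pr, bg), mean, numeric(1)),
                 train_ranges = lapply(rbind(pr, bg), range)),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("<maxent_fit: %d feature(s) [%s], %d/%d nonzero basis terms, n = %d presence / %d background>\n",
              length(x$features), paste(x$features, collapse = ", "),
              sum(x$beta != 0), length(x$beta), x$n_presence, x$n_background))
  invisible(x)
}

linear_predictor <- function(object, newdata) {
  if (!length(object$beta)) return(rep(0, nrow(as.data.frame(newdata))))
  as.numeric(expand_basis(object$basis, as.data.frame(newdata)) %*% object$beta)
}

#' Predict from a fitted presence-background model
#'
#' `raw` is the Gibbs density normalized over the training background
#' (raw scores of the training background sum to 1); `cloglog` is the
#' entropy-calibrated complementary log-log transform
#' `1 - exp(-exp(H) * raw)`, a probability-of-presence-like score in (0, 1);
#' `link` is the uncalibrated linear predictor.
#'
#' @param object A `maxent_fit`.
#' @param newdata A data frame of feature values, or a named list of
#'   aligned [raster_layer()]s covering the model's features.
#' @param type `"cloglog"`, `"raw"` or `"link"`.
#' @param ... Unused.
#' @return Numeric vector, or an [raster_layer()] when `newdata` is a
#'   raster stack.
#' @export
predict.maxent_fit <- function(object, newdata,
                               type = c("cloglog", "raw", "link"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && length(newdata) && all(vapply(newdata, is_raster_layer, logical(1)))) {
    stack <- newdata
    if (is.null(names(stack)) || any(!nzchar(names(stack))))
      names(stack) <- vapply(stack, function(l) l$name, character(1))
    g <- stack[[1]]$grid
    df <- as.data.frame(lapply(stack, function(l) as.vector(l$values)))
    names(df) <- names(stack)
    ok <- stats::complete.cases(df[, object$features, drop = FALSE])
    sc <- rep(NA_real_, nrow(df))
    sc[ok] <- predict(object, df[ok, , drop = FALSE], type = type)
    return(raster_layer(matrix(sc, g$n_rows, g$n_cols), g,
                        name = paste0("prediction_", type)))
  }
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f))
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "))
  eta <- linear_predictor(object, newdata)
  switch(type,
    link = eta,
    raw = exp(eta - object$logZ),
    cloglog = 1 - exp(-exp(object$entropy) * exp(eta - object$logZ)))
}

#' Rank (Mann-Whitney) AUC
#'
#' Area under the ROC curve via the rank formulation: the probability that
#' a random positive scores above a random negative, with ties counting
#' one half.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (!np || !nn) stop("both score vectors must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Maximum true skill statistic and its threshold
#'
#' Scans every candidate threshold (midpoints of adjacent unique scores,
#' guarded by -Inf and +Inf) under the rule "presence if score >=
#' threshold" and returns the maximum of `TSS(t) = sensitivity(t) +
#' specificity(t) - 1` together with the lowest maximizing threshold.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both non-empty).
#' @return List with `tss` and `threshold`.
#' @export
max_tss <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score vectors must be non-empty")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  tss <- vapply(cand, function(t)
    mean(pos_scores >= t) + mean(neg_scores < t) - 1, numeric(1))
  best <- max(tss)
  list(tss = best, threshold = cand[which(tss >= best - 1e-12)[1]])
}

#' Sample-size-corrected AIC from a log-likelihood
#'
#' `AICc = 2k - 2 lnL + 2k(k + 1) / (n - k - 1)`; undefined (NA, with a
#' warning) when `n <= k + 1`.
#'
#' @param loglik Log-likelihood.
#' @param k Number of parameters.
#' @param n Sample size.
#' @return AICc value.
#' @export
aicc_from_loglik <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Background-normalized AICc of a presence-background model
#'
#' The likelihood of each presence point is the model's raw output
#' (the Gibbs density renormalized over the supplied background rows), so
#' `lnL = sum log raw_i` over presences; `k` counts nonzero non-intercept
#' basis coefficients after shrinkage.
#'
#' @param model A `maxent_fit`.
#' @param presence,background Data frames of feature values.
#' @return AICc value (NA with a warning when `n <= k + 1`).
#' @export
aicc_bg <- function(model, presence, background) {
  pr <- swd_feature_frame(presence)[, model$features, drop = FALSE]
  bg <- swd_feature_frame(background)[, model$features, drop = FALSE]
  eta_bg <- linear_predictor(model, bg)
  m <- max(eta_bg)
  logZ <- m + log(sum(exp(eta_bg - m)))
  lnL <- sum(linear_predictor(model, pr) - logZ)
  aicc_from_loglik(lnL, k = sum(model$beta != 0), n = nrow(pr))
}

#' Permutation importance of model variables
#'
#' Permutes one variable's values across the supplied presence+background
#' rows, recomputes the training AUC (background-plus-presence negatives),
#' and reports the mean AUC drop over `n_perm` permutations, normalized
#' across the model's variables to sum to 100.
#'
#' @param model A `maxent_fit`.
#' @param swd SWD tibble with a `role` column distinguishing presence rows
#'   (roles starting `presence`) from background rows.
#' @param variables Variables to assess (default: all model features).
#' @param n_perm Permutations per variable.
#' @param seed Integer seed.
#' @return Tibble with `variable`, `auc_drop`, `importance` (percent).
#' @export
permutation_importance <- function(model, swd, variables = NULL, n_perm = 5,
                                   seed = 1) {
  variables <- variables %||% model$features
  bad <- setdiff(variables, model$features)
  if (length(bad)) stop("variable(s) not in model: ", paste(bad, collapse = ", "))
  is_pres <- grepl("^presence", swd$role)
  df <- swd_feature_frame(swd, model$features)
  eta <- linear_predictor(model, df)
  base <- rank_auc(eta[is_pres], eta)
  with_seed(seed, {
    drops <- vapply(variables, function(v) {
      mean(vapply(seq_len(n_perm), function(i) {
        d2 <- df
        d2[[v]] <- sample(d2[[v]])
        e2 <- linear_predictor(model, d2)
        base - rank_auc(e2[is_pres], e2)
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  imp <- if (sum(drops) > 0) 100 * drops / sum(drops)
         else rep(100 / length(drops), length(drops))
  tibble::tibble(variable = variables, auc_drop = unname(drops),
                 importance = unname(imp))
}

#' Marginal response curve
#'
#' Model output along one variable's observed training range with every
#' other variable held at its mean training value.
#'
#' @param model A `maxent_fit`.
#' @param variable Variable name.
#' @param n Curve resolution.
#' @param type Prediction scale (default cloglog).
#' @return Tibble with `value` and `response`.
#' @export
marginal_response <- function(model, variable, n = 100, type = "cloglog") {
  if (!variable %in% model$features) stop("variable not in model: ", variable)
  rng <- model$train_ranges[[variable]]
  grid <- seq(rng[1], rng[2], length.out = n)
  df <- as.data.frame(lapply(model$train_means[model$features],
                             function(m) rep(m, n)))
  names(df) <- model$features
  df[[variable]] <- grid
  tibble::tibble(value = grid, response = predict(model, df, type = type))
}
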