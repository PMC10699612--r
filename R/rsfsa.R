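#' RSFSA-CV configuration
#'
#' Tuning knobs of the three-stage cross-validated random-subset
#' feature-selection algorithm. The full-scale defaults are 250 subsets
#' per size over sizes 1-10 in stage 1; three replicates of 3,000 subsets
#' keeping the top 250 in stage 2; and four random draws per replicate
#' into a 12-model ensemble evaluated with 10-fold CV. Every value is
#' overridable for desk-scale runs.
#'
#' @param sizes Candidate subset sizes screened in stage 1.
#' @param stage1_subsets_per_size Random subsets evaluated per size.
#' @param n_rerand Train/test re-randomizations per subset in stages 1-2.
#' @param stage2_replicates Independent stage-2 replicates.
#' @param stage2_subsets Random subsets per stage-2 replicate.
#' @param stage2_top Top models retained per replicate.
#' @param stage3_per_replicate Models drawn from each replicate's top list.
#' @param stage3_random Draw stage-3 models at random from the top list
#'   (`TRUE`, the default) or take the best-ranked.
#' @param alpha Welch's t-test significance level for top-vs-random
#'   comparisons.
#' @param corr_threshold Absolute Pearson correlation above which two
#'   features may not share a subset (0.5; stricter than the typical 0.7).
#' @param final_cv_folds k for the final k-fold evaluation of the ensemble.
#' @param train_fraction Presence/pseudoabsence train share per
#'   re-randomization.
#' @param model A [model_spec()] used for every fit. Linear+quadratic by
#'   default: subset screening fits thousands of small models, where the
#'   leaner basis is the appropriate complexity control.
#' @param n_perm Permutations per variable for importance ranking.
#' @return An `rsfsa_config` list.
#' @export
rsfsa_config <- function(sizes = 1:10, stage1_subsets_per_size = 250,
                         n_rerand = 3, stage2_replicates = 3,
                         stage2_subsets = 3000, stage2_top = 250,
                         stage3_per_replicate = 4, stage3_random = TRUE,
                         alpha = 0.05, corr_threshold = 0.5,
                         final_cv_folds = 10, train_fraction = 0.75,
                         model = model_spec(feature_classes = c("linear", "quadratic")),
                         n_perm = 3) {
  structure(list(sizes = sizes, stage1_subsets_per_size = stage1_subsets_per_size,
                 n_rerand = n_rerand, stage2_replicates = stage2_replicates,
                 stage2_subsets = stage2_subsets, stage2_top = stage2_top,
                 stage3_per_replicate = stage3_per_replicate,
                 stage3_random = isTRUE(stage3_random), alpha = alpha,
                 corr_threshold = corr_threshold,
                 final_cv_folds = final_cv_folds,
                 train_fraction = train_fraction, model = model,
                 n_perm = n_perm),
            class = "rsfsa_config")
}

#' Pearson correlation matrix of SWD features
#'
#' Computed on the supplied rows (conventionally presence + background) and
#' used both for the subset-composition constraint and for correlation
#' grouping of the ranking.
#'
#' @param swd SWD tibble.
#' @param features Feature columns (default all).
#' @return Correlation matrix.
#' @export
feature_correlation <- function(swd, features = NULL) {
  df <- swd_feature_frame(swd, features %||% swd_features(swd))
  stats::cor(as.matrix(df))
}

#' Sample random decorrelated feature subsets
#'
#' Draws `n` distinct subsets of the given size in which no two members
#' exceed the absolute-correlation threshold, by seeded random greedy
#' construction with bounded retries.
#'
#' @param cor_mat Feature correlation matrix (from [feature_correlation()]).
#' @param size Subset size.
#' @param n Number of subsets requested.
#' @param threshold Absolute correlation ceiling (default 0.5).
#' @param seed Integer seed.
#' @param allow_fewer Return fewer than `n` subsets (with a warning) when
#'   the distinct admissible subsets are exhausted, instead of erroring.
#' @return List of character vectors of feature names.
#' @export
sample_decorrelated_subsets <- function(cor_mat, size, n, threshold = 0.5,
                                        seed = 1, allow_fewer = FALSE) {
  feats <- colnames(cor_mat)
  stopifnot(length(feats) >= size, size >= 1)
  compat <- abs(cor_mat) < threshold
  diag(compat) <- FALSE
  with_seed(seed, {
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    out <- vector("list", n)
    found <- 0L
    tries <- 0L
    max_tries <- 500L * n
    while (found < n && tries < max_tries) {
      tries <- tries + 1L
      sub <- sample(feats, 1)
      while (length(sub) < size) {
        ok <- feats[colSums(!compat[sub, feats, drop = FALSE]) == 0]
        ok <- setdiff(ok, sub)
        if (!length(ok)) break
        sub <- c(sub, if (length(ok) == 1) ok else sample(ok, 1))
      }
      if (length(sub) < size) next
      key <- paste(sort(sub), collapse = "|")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      found <- found + 1L
      out[[found]] <- sort(sub)
    }
    if (found < n) {
      if (!allow_fewer)
        stop("could only form ", found, " distinct admissible subsets of size ",
             size, " (requested ", n, ")")
      warning("returning ", found, " of ", n, " requested subsets of size ", size)
      out <- out[seq_len(found)]
    }
    out
  })
}

split_swd_roles <- function(swd) {
  list(presence = swd[grepl("^presence", swd$role) & swd$role != "presence_withheld", ],
       background = swd[swd$role == "background", ],
       pseudoabsence = swd[swd$role == "pseudoabsence", ])
}

#' Cross-validated evaluation of one feature subset
#'
#' For each re-randomization the presence and pseudoabsence rows are split
#' into train/test shares, the model is fitted on training presences
#' against the full background, and three criteria are computed: test
#' pseudoabsence AUC (accuracy), the train-minus-test AUC difference
#' (overfitting), and background-normalized AICc over all presences
#' (complexity/information). Fit failures are recorded, not absorbed.
#'
#' @param subset Character vector of feature names.
#' @param presence,background,pseudoabsence SWD tibbles.
#' @param config An [rsfsa_config()] (supplies the model spec, train
#'   fraction and re-randomization count).
#' @param seed Integer seed.
#' @return One-row tibble: means and sds of `auc_psa_test`,
#'   `auc_psa_train`, `auc_psa_diff`, `aicc_bg`, plus `n_fail`.
#' @export
cv_evaluate_subset <- function(subset, presence, background, pseudoabsence,
                               config = rsfsa_config(), seed = 1) {
  npr <- nrow(presence); nps <- nrow(pseudoabsence)
  pr_f <- swd_feature_frame(presence, subset)
  bg_f <- swd_feature_frame(background, subset)
  ps_f <- swd_feature_frame(pseudoabsence, subset)
  res <- with_seed(seed, {
    lapply(seq_len(config$n_rerand), function(i) {
      tr_p <- sample.int(npr, round(config$train_fraction * npr))
      tr_a <- sample.int(nps, round(config$train_fraction * nps))
      fit <- tryCatch(
        suppressWarnings(fit_maxent_like(pr_f[tr_p, , drop = FALSE], bg_f,
                                         spec = config$model)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      eta_p <- linear_predictor(fit, pr_f)
      eta_a <- linear_predictor(fit, ps_f)
      auc_tr <- rank_auc(eta_p[tr_p], eta_a[tr_a])
      auc_te <- rank_auc(eta_p[-tr_p], eta_a[-tr_a])
      c(auc_psa_test = auc_te, auc_psa_train = auc_tr,
        auc_psa_diff = auc_tr - auc_te,
        aicc_bg = suppressWarnings(aicc_bg(fit, pr_f, bg_f)))
    })
  })
  ok <- !vapply(res, is.null, logical(1))
  m <- do.call(rbind, res[ok])
  agg <- function(f) if (is.null(m)) rep(NA_real_, 4) else apply(m, 2, f, na.rm = TRUE)
  mu <- agg(mean); sdv <- agg(stats::sd)
  tibble::tibble(features = list(subset), size = length(subset),
                 auc_psa_test = mu[1], auc_psa_train = mu[2],
                 auc_psa_diff = mu[3], aicc_bg = mu[4],
                 sd_auc_psa_test = sdv[1], sd_aicc_bg = sdv[4],
                 n_fail = sum(!ok))
}

evaluate_subsets <- function(subsets, presence, background, pseudoabsence,
                             config, seed) {
  out <- purrr::imap(subsets, function(sub, i)
    cv_evaluate_subset(sub, presence, background, pseudoabsence, config,
                       seed = substream_seed(seed, paste0("eval", i))))
  dplyr::bind_rows(out) |>
    dplyr::mutate(subset_id = dplyr::row_number(), .before = 1)
}

welch_top_vs_random <- function(top, random, alternative) {
  tt <- tryCatch(stats::t.test(top, random, alternative = alternative),
                 error = function(e) NULL)
  if (is.null(tt)) return(c(t = NA_real_, p = NA_real_))
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Stage 1: choose the optimal subset size
#'
#' Evaluates random decorrelated subsets at every candidate size and picks
#' the smallest size whose top-10 models (a) beat 10 randomly drawn
#' evaluated subsets by Welch's t-test at level `alpha`, and (b) lie within
#' one pooled standard deviation of the best size's top-10 mean (the
#' plateau rule), under whichever criterion (test AUC or AICc) separates
#' top from random more sharply. When no size reaches significance the
#' best-mean size is returned with `fallback = TRUE`.
#'
#' @param swd SWD tibble holding presence, background and pseudoabsence
#'   rows (by `role`).
#' @param config An [rsfsa_config()].
#' @param seed Integer seed.
#' @param cor_mat Optional precomputed correlation matrix.
#' @return List: `size`, `criterion` (`"auc_psa"` or `"aicc_bg"`),
#'   `by_size` summary tibble, `fallback`.
#' @export
stage1_optimal_size <- function(swd, config = rsfsa_config(), seed = 1,
                                cor_mat = NULL) {
  roles <- split_swd_roles(swd)
  cor_mat <- cor_mat %||%
    feature_correlation(dplyr::bind_rows(roles$presence, roles$background))
  n_top <- 10L
  per_size <- lapply(config$sizes, function(sz) {
    subs <- sample_decorrelated_subsets(cor_mat, sz, config$stage1_subsets_per_size,
                                        config$corr_threshold,
                                        seed = substream_seed(seed, paste0("s1subs", sz)),
                                        allow_fewer = TRUE)
    ev <- evaluate_subsets(subs, roles$presence, roles$background,
                           roles$pseudoabsence, config,
                           seed = substream_seed(seed, paste0("s1eval", sz)))
    ev$size_group <- sz
    ev
  })
  by_size <- purrr::map2(config$sizes, per_size, function(sz, ev) {
    ev <- ev[!is.na(ev$auc_psa_test) & !is.na(ev$aicc_bg), ]
    k <- min(n_top, nrow(ev))
    top_auc <- dplyr::slice_max(ev, .data$auc_psa_test, n = k, with_ties = FALSE)
    top_aicc <- dplyr::slice_min(ev, .data$aicc_bg, n = k, with_ties = FALSE)
    rnd <- with_seed(substream_seed(seed, paste0("s1rand", sz)),
                     ev[sample.int(nrow(ev), min(k, nrow(ev))), ])
    w_auc <- welch_top_vs_random(top_auc$auc_psa_test, rnd$auc_psa_test, "greater")
    w_aicc <- welch_top_vs_random(top_aicc$aicc_bg, rnd$aicc_bg, "less")
    tibble::tibble(size = sz, n_eval = nrow(ev),
                   top_mean_auc = mean(top_auc$auc_psa_test),
                   top_sd_auc = stats::sd(top_auc$auc_psa_test),
                   top_mean_aicc = mean(top_aicc$aicc_bg),
                   top_sd_aicc = stats::sd(top_aicc$aicc_bg),
                   t_auc = w_auc["t"], p_auc = w_auc["p"],
                   t_aicc = abs(w_aicc["t"]), p_aicc = w_aicc["p"])
  }) |> dplyr::bind_rows()
  criterion <- if (mean(by_size$t_auc, na.rm = TRUE) >=
                   mean(by_size$t_aicc, na.rm = TRUE)) "auc_psa" else "aicc_bg"
  if (criterion == "auc_psa") {
    mu <- by_size$top_mean_auc; sdv <- by_size$top_sd_auc
    best <- which.max(mu); sig <- !is.na(by_size$p_auc) & by_size$p_auc < config$alpha
    pooled <- sqrt((sdv^2 + sdv[best]^2) / 2)
    plateau <- mu >= mu[best] - pooled
  } else {
    mu <- by_size$top_mean_aicc; sdv <- by_size$top_sd_aicc
    best <- which.min(mu); sig <- !is.na(by_size$p_aicc) & by_size$p_aicc < config$alpha
    pooled <- sqrt((sdv^2 + sdv[best]^2) / 2)
    plateau <- mu <= mu[best] + pooled
  }
  eligible <- which(sig & plateau)
  fallback <- !length(eligible)
  size <- if (fallback) by_size$size[best] else min(by_size$size[eligible])
  list(size = size, criterion = criterion, by_size = by_size,
       fallback = fallback)
}

#' Stage 2: replicate screens of the chosen size
#'
#' Runs independent replicates, each sampling a fresh pool of decorrelated
#' subsets of the stage-1 size, evaluating them, and retaining the top
#' models under the stage-1 criterion; each replicate's top list is
#' compared against an equally sized random cohort with Welch's t-test.
#'
#' @inheritParams stage1_optimal_size
#' @param size Subset size chosen by stage 1.
#' @param criterion `"auc_psa"` or `"aicc_bg"`.
#' @return List of replicates; each holds `top` (ranked evaluation tibble),
#'   `welch` (t and p) and `n_eval`.
#' @export
stage2_top_models <- function(swd, size, criterion = "auc_psa",
                              config = rsfsa_config(), seed = 1,
                              cor_mat = NULL) {
  roles <- split_swd_roles(swd)
  cor_mat <- cor_mat %||%
    feature_correlation(dplyr::bind_rows(roles$presence, roles$background))
  lapply(seq_len(config$stage2_replicates), function(r) {
    subs <- sample_decorrelated_subsets(cor_mat, size, config$stage2_subsets,
                                        config$corr_threshold,
                                        seed = substream_seed(seed, paste0("s2subs", r)),
                                        allow_fewer = TRUE)
    ev <- evaluate_subsets(subs, roles$presence, roles$background,
                           roles$pseudoabsence, config,
                           seed = substream_seed(seed, paste0("s2eval", r)))
    ev <- ev[!is.na(ev$auc_psa_test) & !is.na(ev$aicc_bg), ]
    k <- min(config$stage2_top, nrow(ev))
    top <- if (criterion == "auc_psa")
      dplyr::slice_max(ev, .data$auc_psa_test, n = k, with_ties = FALSE)
    else dplyr::slice_min(ev, .data$aicc_bg, n = k, with_ties = FALSE)
    rnd <- with_seed(substream_seed(seed, paste0("s2rand", r)),
                     ev[sample.int(nrow(ev), k), ])
    welch <- if (criterion == "auc_psa")
      welch_top_vs_random(top$auc_psa_test, rnd$auc_psa_test, "greater")
    else welch_top_vs_random(top$aicc_bg, rnd$aicc_bg, "less")
    list(top = top, welch = welch, n_eval = nrow(ev), replicate = r)
  })
}

kfold_metrics <- function(subset, roles, config, seed) {
  k <- config$final_cv_folds
  pr <- swd_feature_frame(roles$presence, subset)
  bg <- swd_feature_frame(roles$background, subset)
  ps <- swd_feature_frame(roles$pseudoabsence, subset)
  with_seed(seed, {
    fp <- sample(rep_len(seq_len(k), nrow(pr)))
    fa <- sample(rep_len(seq_len(k), nrow(ps)))
    folds <- vapply(seq_len(k), function(f) {
      fit <- suppressWarnings(fit_maxent_like(pr[fp != f, , drop = FALSE], bg,
                                              spec = config$model))
      eta_p <- linear_predictor(fit, pr); eta_a <- linear_predictor(fit, ps)
      c(test = rank_auc(eta_p[fp == f], eta_a[fa == f]),
        train = rank_auc(eta_p[fp != f], eta_a[fa != f]))
    }, numeric(2))
    full <- suppressWarnings(fit_maxent_like(pr, bg, spec = config$model))
    eta_p <- linear_predictor(full, pr)
    eta_a <- linear_predictor(full, ps)
    eta_b <- linear_predictor(full, bg)
    cl_p <- predict(full, pr, type = "cloglog")
    cl_a <- predict(full, ps, type = "cloglog")
    cl_b <- predict(full, bg, type = "cloglog")
    mt_psa <- max_tss(cl_p, cl_a)
    mt_bg <- max_tss(cl_p, cl_b)
    list(model = full,
         metrics = tibble::tibble(
           features = list(subset),
           auc_psa = mean(folds["test", ]),
           auc_psa_train = mean(folds["train", ]),
           auc_psa_diff = mean(folds["train", ] - folds["test", ]),
           auc_bgp = rank_auc(eta_p, c(eta_b, eta_p)),
           aicc_bg = suppressWarnings(aicc_bg(full, pr, bg)),
           tss_psa = mt_psa$tss, tss_bg = mt_bg$tss,
           tss_threshold = mt_psa$threshold))
  })
}

#' Stage 3: draw and evaluate the feature-subset ensemble
#'
#' Draws `stage3_per_replicate` subsets from each replicate's top list
#' (randomly by default), refits each on the full data, and evaluates it
#' with k-fold cross-validation, returning the fitted members and the full
#' metric suite (pseudoabsence and background AUCs, AUC difference, AICc,
#' both TSS variants and the max-TSS calibration threshold).
#'
#' @param stage2 Output of [stage2_top_models()].
#' @inheritParams stage1_optimal_size
#' @return List with `models` (fitted `maxent_fit`s, replicates x
#'   per-replicate of them) and `metrics` (one row per member).
#' @export
stage3_select_ensemble <- function(stage2, swd, config = rsfsa_config(),
                                   seed = 1) {
  roles <- split_swd_roles(swd)
  chosen <- list()
  for (rep in stage2) {
    k <- config$stage3_per_replicate
    if (nrow(rep$top) < k)
      stop("replicate ", rep$replicate, " holds fewer than ", k, " top models")
    idx <- if (config$stage3_random)
      with_seed(substream_seed(seed, paste0("s3pick", rep$replicate)),
                sample.int(nrow(rep$top), k))
    else seq_len(k)
    chosen <- c(chosen, rep$top$features[idx])
  }
  fitted <- purrr::imap(chosen, function(sub, i)
    kfold_metrics(sub, roles, config, substream_seed(seed, paste0("s3cv", i))))
  metrics <- dplyr::bind_rows(purrr::map(fitted, "metrics")) |>
    dplyr::mutate(member = dplyr::row_number(), .before = 1)
  list(models = purrr::map(fitted, "model"), metrics = metrics)
}

#' Weighted variable ranking over the stage-2 top models
#'
#' Every retained top model is refitted on the full presence+background
#' data and its variables' permutation importances computed. Per variable:
#' frequency of appearance across all top models and mean permutation
#' importance over its appearances, both min-max normalized, combined as
#' `0.6 * importance + 0.4 * frequency`, ranked descending (ties broken by
#' importance, then name).
#'
#' @param stage2 Output of [stage2_top_models()].
#' @inheritParams stage1_optimal_size
#' @return A `rsfsa_ranking` tibble.
#' @export
rank_variables <- function(stage2, swd, config = rsfsa_config(), seed = 1) {
  roles <- split_swd_roles(swd)
  train <- dplyr::bind_rows(roles$presence, roles$background)
  records <- list()
  i <- 0L
  for (rep in stage2) {
    for (sub in rep$top$features) {
      i <- i + 1L
      fit <- suppressWarnings(fit_maxent_like(
        swd_feature_frame(roles$presence, sub),
        swd_feature_frame(roles$background, sub), spec = config$model))
      imp <- permutation_importance(fit, train, n_perm = config$n_perm,
                                    seed = substream_seed(seed, paste0("perm", i)))
      records[[i]] <- imp
    }
  }
  per_var <- dplyr::bind_rows(records) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(frequency = dplyr::n(),
                     mean_importance = mean(.data$importance),
                     .groups = "drop")
  norm01 <- function(v) if (diff(range(v)) == 0) rep(1, length(v))
            else (v - min(v)) / diff(range(v))
  out <- per_var |>
    dplyr::mutate(imp_norm = norm01(.data$mean_importance),
                  freq_norm = norm01(.data$frequency),
                  score = 0.6 * .data$imp_norm + 0.4 * .data$freq_norm) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$mean_importance), .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("rsfsa_ranking", class(out))
  out
}

#' Correlation groups of ranked variables
#'
#' Walks the ranking from the top: each variable not yet belonging to any
#' group seeds a new group (numbered in seeding order), and every other
#' variable correlated with the seed at `|r| >= threshold` joins that
#' group. Variables may therefore belong to several groups (a variable
#' correlated with two mutually uncorrelated seeds appears in both);
#' memberships are reported as a comma-separated id string.
#'
#' @param ranking A `rsfsa_ranking` tibble (from [rank_variables()]).
#' @param cor_mat Feature correlation matrix.
#' @param threshold Absolute correlation for joint membership (default 0.5).
#' @return The ranking with a `correlation_group` column.
#' @export
assign_correlation_groups <- function(ranking, cor_mat, threshold = 0.5) {
  vars <- ranking$variable[order(ranking$rank)]
  groups <- stats::setNames(vector("list", length(vars)), vars)
  next_id <- 0L
  for (v in vars) {
    if (length(groups[[v]])) next
    next_id <- next_id + 1L
    groups[[v]] <- next_id
    for (w in setdiff(vars, v)) {
      if (v %in% rownames(cor_mat) && w %in% colnames(cor_mat) &&
          abs(cor_mat[v, w]) >= threshold)
        groups[[w]] <- c(groups[[w]], next_id)
    }
  }
  ranking$correlation_group <-
    vapply(ranking$variable, function(v)
      paste(sort(groups[[v]]), collapse = ","), character(1),
      USE.NAMES = FALSE)
  ranking
}

#' Run the full RSFSA-CV selection
#'
#' Orchestrates the three stages and the variable ranking on one SWD table
#' holding presence, background and pseudoabsence rows, all randomness
#' flowing from one master seed through named substreams.
#'
#' @param swd SWD tibble with `role` in `presence`/`presence_model`,
#'   `background`, `pseudoabsence`.
#' @param config An [rsfsa_config()].
#' @param seed Master seed.
#' @return An `rsfsa_result` list: `stage1`, `stage2`, `ensemble`,
#'   `ranking`, `cor_mat`, `config`, `seed`.
#' @export
run_rsfsa <- function(swd, config = rsfsa_config(), seed = 1) {
  roles <- split_swd_roles(swd)
  if (!nrow(roles$presence)) stop("no presence rows in SWD")
  if (!nrow(roles$background)) stop("no background rows in SWD")
  if (!nrow(roles$pseudoabsence)) stop("no pseudoabsence rows in SWD")
  cor_mat <- feature_correlation(dplyr::bind_rows(roles$presence, roles$background))
  stage1 <- stage1_optimal_size(swd, config, seed = substream_seed(seed, "stage1"),
                                cor_mat = cor_mat)
  stage2 <- stage2_top_models(swd, stage1$size, stage1$criterion, config,
                              seed = substream_seed(seed, "stage2"),
                              cor_mat = cor_mat)
  ensemble <- stage3_select_ensemble(stage2, swd, config,
                                     seed = substream_seed(seed, "stage3"))
  ranking <- rank_variables(stage2, swd, config,
                            seed = substream_seed(seed, "ranking")) |>
    assign_correlation_groups(cor_mat, config$corr_threshold)
  structure(list(stage1 = stage1, stage2 = stage2, ensemble = ensemble,
                 ranking = ranking, cor_mat = cor_mat, config = config,
                 seed = seed),
            class = "rsfsa_result")
}

#' @export
print.rsfsa_result <- function(x, ...) {
  cat(sprintf("<rsfsa_result: size %d by %s%s; %d ensemble members; top variables: %s>\n",
              x$stage1$size, x$stage1$criterion,
              if (x$stage1$fallback) " (fallback)" else "",
              length(x$ensemble$models),
              paste(utils::head(x$ranking$variable, 3), collapse = ", ")))
  invisible(x)
}
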