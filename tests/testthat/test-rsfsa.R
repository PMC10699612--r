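# correlated feature data: v1 ~ v2 (r ~ 0.95), v3 signal, v4/v5 noise
gen_corr_swd <- function(seed = 1, n_pres = 80, n_bg = 300, n_psa = 300) {
  set.seed(seed)
  mk <- function(n, shift = 0) {
    base <- rnorm(n)
    tibble::tibble(v1 = base, v2 = base + rnorm(n, sd = 0.3),
                   v3 = rnorm(n, mean = shift), v4 = rnorm(n), v5 = rnorm(n),
                   v6 = rnorm(n), v7 = rnorm(n))
  }
  dplyr::bind_rows(
    dplyr::mutate(mk(n_pres, shift = 1.6), role = "presence_model"),
    dplyr::mutate(mk(n_bg), role = "background"),
    dplyr::mutate(mk(n_psa), role = "pseudoabsence")) |>
    dplyr::mutate(x = 0, y = 0)
}

test_that("decorrelated subsets never pair features above the threshold", {
  swd <- gen_corr_swd(2)
  cm <- feature_correlation(swd, paste0("v", 1:7))
  expect_gt(abs(cm["v1", "v2"]), 0.5)
  subs <- suppressWarnings(
    sample_decorrelated_subsets(cm, 3, 2000, threshold = 0.5, seed = 3,
                                allow_fewer = TRUE))
  expect_gt(length(subs), 20)
  expect_true(all(vapply(subs, function(s)
    !("v1" %in% s && "v2" %in% s), logical(1))))
  cm <- cm[1:5, 1:5]
  # threshold 1 admits any pair eventually
  subs1 <- sample_decorrelated_subsets(cm, 2, choose(5, 2), threshold = 1.01,
                                       seed = 3)
  expect_length(subs1, 10)
  # seeded: identical subset list
  expect_identical(sample_decorrelated_subsets(cm, 2, 8, seed = 5),
                   sample_decorrelated_subsets(cm, 2, 8, seed = 5))
  # distinct subsets, exhaustion reported
  expect_error(sample_decorrelated_subsets(cm, 1, 6, seed = 1), "distinct")
  expect_warning(sample_decorrelated_subsets(cm, 1, 6, seed = 1,
                                             allow_fewer = TRUE), "5 of 6")
})

test_that("subset evaluation is seeded and separates signal from noise", {
  swd <- gen_corr_swd(4)
  roles <- list(p = swd[swd$role == "presence_model", ],
                b = swd[swd$role == "background", ],
                a = swd[swd$role == "pseudoabsence", ])
  cfg <- rsfsa_config(n_rerand = 10)
  ev_sig <- cv_evaluate_subset("v3", roles$p, roles$b, roles$a, cfg, seed = 6)
  ev_noise <- cv_evaluate_subset("v4", roles$p, roles$b, roles$a, cfg, seed = 6)
  expect_lt(abs(ev_noise$auc_psa_test - 0.5), 0.07)
  expect_gt(ev_sig$auc_psa_test, ev_noise$auc_psa_test)
  expect_gt(ev_sig$auc_psa_test, 0.8)
  expect_identical(
    cv_evaluate_subset(c("v3", "v4"), roles$p, roles$b, roles$a, cfg, seed = 7),
    cv_evaluate_subset(c("v3", "v4"), roles$p, roles$b, roles$a, cfg, seed = 7))
  expect_equal(ev_sig$n_fail, 0)
})

test_that("stage 1 finds the smallest sufficient size for a two-driver signal", {
  # presence shifted on two independent features among ten noise features:
  # neither driver alone separates as well as both together
  set.seed(11)
  mk <- function(n, s1 = 0, s2 = 0) {
    d <- as.data.frame(matrix(rnorm(n * 10), n, 10,
                              dimnames = list(NULL, paste0("n", 1:10))))
    d$a <- rnorm(n, s1); d$b <- rnorm(n, s2)
    tibble::as_tibble(d)
  }
  swd <- dplyr::bind_rows(
    dplyr::mutate(mk(120, 1.3, 1.3), role = "presence_model"),
    dplyr::mutate(mk(400), role = "background"),
    dplyr::mutate(mk(400), role = "pseudoabsence"))
  cfg <- rsfsa_config(sizes = 1:3, stage1_subsets_per_size = 50, n_rerand = 3,
                      model = model_spec("linear"))
  s1 <- suppressWarnings(stage1_optimal_size(swd, cfg, seed = 12))
  expect_equal(s1$size, 2)
  expect_false(s1$fallback)
  expect_true(s1$criterion %in% c("auc_psa", "aicc_bg"))
})

test_that("stage 1 falls back gracefully on pure noise", {
  set.seed(13)
  mk <- function(n) tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  swd <- dplyr::bind_rows(
    dplyr::mutate(mk(60), role = "presence_model"),
    dplyr::mutate(mk(250), role = "background"),
    dplyr::mutate(mk(250), role = "pseudoabsence"))
  cfg <- rsfsa_config(sizes = 1:2, stage1_subsets_per_size = 8, n_rerand = 2,
                      model = model_spec("linear"))
  s1 <- suppressWarnings(stage1_optimal_size(swd, cfg, seed = 14))
  expect_true(s1$size %in% 1:2)
  expect_type(s1$fallback, "logical")
})

test_that("stage 2 replicates rank by the chosen criterion and beat random cohorts", {
  swd <- gen_corr_swd(15, n_pres = 100)
  cfg <- rsfsa_config(stage2_replicates = 3, stage2_subsets = 40,
                      stage2_top = 10, n_rerand = 2, model = model_spec("linear"))
  s2 <- suppressWarnings(stage2_top_models(swd, 2, "auc_psa", cfg, seed = 16))
  expect_length(s2, 3)
  for (rep in s2) {
    expect_equal(nrow(rep$top), 10)
    # ranking contract: descending by AUC
    expect_true(all(diff(rep$top$auc_psa_test) <= 1e-12))
    expect_gt(mean(rep$top$auc_psa_test), 0.5)
  }
  # replicate seeds differ: top lists differ
  expect_false(identical(s2[[1]]$top$features, s2[[2]]$top$features))
  # AICc criterion ranks ascending
  s2a <- suppressWarnings(stage2_top_models(swd, 2, "aicc_bg",
                                            rsfsa_config(stage2_replicates = 1,
                                                         stage2_subsets = 15,
                                                         stage2_top = 5,
                                                         n_rerand = 2,
                                                         model = model_spec("linear")),
                                            seed = 17))
  expect_true(all(diff(s2a[[1]]$top$aicc_bg) >= -1e-12))
})

test_that("stage 3 draws replicates x per-replicate members with full metrics", {
  swd <- gen_corr_swd(18, n_pres = 100)
  cfg <- rsfsa_config(stage2_replicates = 3, stage2_subsets = 20,
                      stage2_top = 6, n_rerand = 2, stage3_per_replicate = 4,
                      final_cv_folds = 4, model = model_spec("linear"))
  s2 <- suppressWarnings(stage2_top_models(swd, 2, "auc_psa", cfg, seed = 19))
  ens <- suppressWarnings(stage3_select_ensemble(s2, swd, cfg, seed = 20))
  expect_length(ens$models, 12)
  expect_equal(nrow(ens$metrics), 12)
  expect_true(all(c("auc_psa", "auc_bgp", "auc_psa_diff", "aicc_bg",
                    "tss_psa", "tss_bg", "tss_threshold") %in%
                    names(ens$metrics)))
  expect_true(all(ens$metrics$auc_psa >= 0 & ens$metrics$auc_psa <= 1))
  # per_replicate 1 yields 3 members
  cfg1 <- cfg; cfg1$stage3_per_replicate <- 1
  ens1 <- suppressWarnings(stage3_select_ensemble(s2, swd, cfg1, seed = 21))
  expect_length(ens1$models, 3)
  # seeded draw
  ens2 <- suppressWarnings(stage3_select_ensemble(s2, swd, cfg, seed = 20))
  expect_identical(ens$metrics$features, ens2$metrics$features)
  cfg_many <- cfg; cfg_many$stage3_per_replicate <- 7
  expect_error(suppressWarnings(stage3_select_ensemble(s2, swd, cfg_many,
                                                       seed = 1)), "fewer")
})

test_that("variable ranking weights importance over frequency 60/40", {
  swd <- gen_corr_swd(22, n_pres = 100)
  cfg <- rsfsa_config(stage2_replicates = 2, stage2_subsets = 25,
                      stage2_top = 8, n_rerand = 2, n_perm = 2,
                      model = model_spec("linear"))
  s2 <- suppressWarnings(stage2_top_models(swd, 2, "auc_psa", cfg, seed = 23))
  rk <- suppressWarnings(rank_variables(s2, swd, cfg, seed = 24))
  expect_s3_class(rk, "rsfsa_ranking")
  # the signal variable tops the ranking
  expect_equal(rk$variable[1], "v3")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # scores follow the 60/40 weighting of the normalized components
  expect_equal(rk$score, 0.6 * rk$imp_norm + 0.4 * rk$freq_norm)
  expect_true(all(diff(rk$score) <= 1e-12))
})

test_that("correlation grouping follows the ranked multi-membership walk", {
  ranking <- tibble::tibble(variable = c("A", "B", "C"), rank = 1:3)
  cm <- diag(3); dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cm["A", "B"] <- cm["B", "A"] <- 0.8   # A-B correlated
  cm["B", "C"] <- cm["C", "B"] <- 0.7   # B-C correlated
  cm["A", "C"] <- cm["C", "A"] <- 0.1   # A-C not
  out <- assign_correlation_groups(ranking, cm, 0.5)
  # B joins A's group; C seeds a new group that also contains B
  expect_equal(out$correlation_group[out$variable == "A"], "1")
  expect_equal(out$correlation_group[out$variable == "B"], "1,2")
  expect_equal(out$correlation_group[out$variable == "C"], "2")
  # uncorrelated variables each seed their own group
  cm0 <- diag(3); dimnames(cm0) <- dimnames(cm)
  out0 <- assign_correlation_groups(ranking, cm0, 0.5)
  expect_equal(out0$correlation_group, c("1", "2", "3"))
  # three mutually correlated variables form one group seeded by the top rank
  cm1 <- matrix(0.9, 3, 3); diag(cm1) <- 1; dimnames(cm1) <- dimnames(cm)
  out1 <- assign_correlation_groups(ranking, cm1, 0.5)
  expect_equal(out1$correlation_group, c("1", "1", "1"))
})

test_that("run_rsfsa is deterministic given the master seed", {
  swd <- gen_corr_swd(25, n_pres = 80, n_bg = 200, n_psa = 200)
  cfg <- rsfsa_config(sizes = 1:2, stage1_subsets_per_size = 8,
                      stage2_replicates = 2, stage2_subsets = 12,
                      stage2_top = 4, stage3_per_replicate = 2,
                      n_rerand = 2, final_cv_folds = 3, n_perm = 2,
                      model = model_spec("linear"))
  r1 <- suppressWarnings(run_rsfsa(swd, cfg, seed = 26))
  r2 <- suppressWarnings(run_rsfsa(swd, cfg, seed = 26))
  expect_identical(r1$ranking$variable, r2$ranking$variable)
  expect_identical(r1$ranking$score, r2$ranking$score)
  expect_identical(r1$ensemble$metrics$auc_psa, r2$ensemble$metrics$auc_psa)
  expect_length(r1$ensemble$models, 4)
})
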