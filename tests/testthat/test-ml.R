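test_that("feature selection returns tissue-specific columns and drops missing flags", {
  co <- small_cohort(n = 60, seed = 12, missingness = 0.1)
  fm <- select_features(co, "connective", "CHF")
  expect_identical(colnames(fm$X), c("conn_N", "conn_mu", "conn_sigma"))
  expect_identical(nrow(fm$X), sum(!is.na(co$chf)))
  fm_all <- select_features(co, "all", "CHD")
  expect_identical(colnames(fm_all$X), ntra_parameter_names())
  expect_error(select_features(co, "bone", "CHD"), "unknown tissue")
  empty <- co[0, ]
  fm0 <- select_features(empty, "fat", "CHD")
  expect_identical(nrow(fm0$X), 0L)
})

test_that("confusion-matrix metrics match hand arithmetic", {
  y <- c(rep(TRUE, 20), rep(FALSE, 20))
  s <- c(rep(1, 19), 0, 1, 1, rep(0, 18))  # TP=19 FN=1 FP=2 TN=18
  m <- compute_metrics(y, s)
  expect_equal(m$sensitivity, 95.0)
  expect_equal(m$specificity, 90.0)
  expect_equal(m$precision, 100 * 19 / 21, tolerance = 1e-10)
  expect_equal(m$accuracy, 92.5)
  expect_identical(m$sensitivity, m$recall)
  expect_equal(compute_metrics(c(TRUE, FALSE), c(0.9, 0.1))$aucroc, 1.0)
  expect_error(auc_roc(c(TRUE, TRUE), c(0.1, 0.2)), "single class")
})

test_that("rank-statistic AUC agrees with the brute-force all-pairs oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    y <- runif(n) < 0.4
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))    # coarse scores force ties
    expect_equal(auc_roc(y, s), brute_force_auc(y, s), tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(auc_roc(y, qlogis((s + 1) / 3)), auc_roc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("SMOTE produces parity, segment geometry, and seeded determinism", {
  # two minority points: the synthetic point is (u, u) on the segment
  X <- rbind(matrix(runif(40), 20), c(0, 0), c(1, 1))
  colnames(X) <- c("a", "b")
  y <- c(rep(FALSE, 20), TRUE, TRUE)
  out <- smote_balance(X, y, k_neighbors = 1, seed = 4)
  expect_identical(sum(out$y), sum(!out$y))
  synth <- out$X[out$synthetic, , drop = FALSE]
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-12))
  expect_true(all(synth >= 0 & synth <= 1))
  # originals unchanged, determinism
  expect_identical(out$X[1:22, ], X)
  out2 <- smote_balance(X, y, k_neighbors = 1, seed = 4)
  expect_identical(out$X, out2$X)
  # convex hull coordinatewise for a larger minority
  set.seed(6)
  X2 <- matrix(rnorm(600), 200)
  colnames(X2) <- c("a", "b", "c")
  y2 <- c(rep(TRUE, 40), rep(FALSE, 160))
  o2 <- smote_balance(X2, y2, seed = 7)
  M <- X2[1:40, ]
  s2 <- o2$X[o2$synthetic, ]
  for (j in 1:3) {
    expect_gte(min(s2[, j]), min(M[, j]))
    expect_lte(max(s2[, j]), max(M[, j]))
  }
  expect_error(smote_balance(X2[c(1, 41:161), ], c(TRUE, rep(FALSE, 121))),
               "single member")
  expect_warning(smote_balance(X2[c(1:3, 41:100), ], c(rep(TRUE, 3), rep(FALSE, 60))),
                 "reduced")
})

test_that("SMOTE balances the published 59 vs 2394 imbalance to parity", {
  set.seed(13)
  X <- matrix(rnorm(2453 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- c(rep(TRUE, 59), rep(FALSE, 2394))
  out <- smote_balance(X, y)
  expect_identical(sum(out$y), 2394L)
  expect_identical(sum(!out$y), 2394L)
})

test_that("stratified folds partition the data and CV accounts for them", {
  cl <- separable_clusters(n_per = 60, sep = 10, seed = 2)
  rep <- run_cv(cl$X, cl$y, "RF", k = 12, n_trees = 50, seed = 3)
  expect_identical(rep$n_folds, 12L)
  expect_identical(sum(rep$fold_sizes), 120L)
  expect_true(all(rep$fold_sizes == 10))
  expect_identical(nrow(rep$pooled), 120L)   # every subject tested once
  expect_gte(rep$accuracy_mean, 99)
  expect_gte(rep$aucroc, 0.999)
  expect_error(run_cv(cl$X[1:5, ], cl$y[1:5], "RF", k = 12), "at least")
})

test_that("all three ensembles separate well-separated clusters", {
  cl <- separable_clusters(n_per = 60, sep = 10, seed = 4)
  for (alg in c("RF", "ADA-B", "GB")) {
    rep <- run_cv(cl$X, cl$y, alg, k = 8, n_trees = 60, seed = 5)
    expect_gte(rep$accuracy_mean, 99)
  }
})

test_that("tissue importance groups and rescales to 100", {
  imp <- setNames(c(0.20, 0.10, 0.06, 0.05, 0.11, 0.10, 0.10,
                    0.08, 0.08, 0.06, 0.06), ntra_parameter_names())
  ti <- tissue_importance(imp)
  expect_equal(ti$fat_pct, 41)
  expect_equal(ti$connective_pct, 31)
  expect_equal(ti$muscle_pct, 28)
  expect_equal(ti$fat_pct + ti$connective_pct + ti$muscle_pct, 100,
               tolerance = 1e-6)
  # equal importance across 11 features: 4/11, 3/11, 4/11
  eq <- setNames(rep(1 / 11, 11), ntra_parameter_names())
  te <- tissue_importance(eq)
  expect_equal(te$fat_pct, 400 / 11, tolerance = 1e-10)
  expect_equal(te$connective_pct, 300 / 11, tolerance = 1e-10)
  # all mass on one muscle feature
  one <- setNames(c(rep(0, 7), 1, 0, 0, 0), ntra_parameter_names())
  expect_equal(tissue_importance(one)$muscle_pct, 100)
  expect_error(tissue_importance(c(x = 0.5, fat_N = 0.5)), "unmapped")
  # a trained ensemble exposes importances that sum to one
  cl <- separable_clusters(n_per = 40, d = 4, seed = 6)
  m <- train_ensemble(cl$X, cl$y, "GB", n_trees = 30, seed = 7)
  expect_equal(sum(feature_importances(m)), 1, tolerance = 1e-9)
})

test_that("age strata assign boundary ages per the published headers", {
  expect_identical(assign_age_bin(c(66, 75, 76, 83, 84, 98)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  co <- small_cohort(n = 90, seed = 19)
  bins <- default_age_bins()
  ids <- assign_age_bin(co$age, bins)
  expect_false(anyNA(ids))           # partition covers every subject once
  expect_identical(length(ids), nrow(co))
})

test_that("incidence labelling follows the two-timepoint rule", {
  t1 <- small_cohort(n = 40, seed = 23)
  t1$chf <- c(rep(TRUE, 5), rep(FALSE, 35))
  t2 <- simulate_longitudinal(t1, incidence_rate = 0, seed = 2)
  t2$chf[6:10] <- TRUE               # five incident cases
  lab <- incidence_labels(t1, t2)
  expect_true(all(lab$excluded[1:5]))        # positive at baseline
  expect_true(all(lab$label[6:10] == 1))
  expect_true(all(lab$label[11:40] == 0))
  expect_true(all(is.na(lab$label[lab$excluded])))
  # a subject missing at follow-up is excluded with a warning
  expect_warning(lab2 <- incidence_labels(t1, t2[-6, ]), "missing at follow-up")
  expect_true(lab2$excluded[6])
})

test_that("permuted labels give chance-level AUC", {
  cl <- separable_clusters(n_per = 50, sep = 10, seed = 31)
  set.seed(99)
  aucs <- replicate(12, {
    yp <- sample(cl$y)
    run_cv(cl$X, yp, "GB", k = 8, n_trees = 40)$aucroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("the full typology report has the promised structure", {
  co <- small_cohort(n = 90, seed = 41)
  t2 <- simulate_longitudinal(co, incidence_rate = 0.3, seed = 42)
  rep <- full_typology(co, cohort_t2 = t2, conditions = c("CHD", "CHF"),
                       algorithms = c("RF", "GB"), k = 4, n_trees = 30,
                       age_bins = list(c(66, 98)), seed = 7)
  expect_identical(length(rep$total), 4L)              # 2 cond x 2 alg
  expect_identical(length(rep$by_tissue), 12L)         # x 3 tissues
  expect_identical(length(rep$tissue_importance), 4L)
  expect_identical(names(rep$longitudinal), c("RF", "GB"))
  for (ti in rep$tissue_importance)
    expect_equal(ti$fat_pct + ti$connective_pct + ti$muscle_pct, 100,
                 tolerance = 1e-6)
  # without a follow-up cohort the longitudinal section is absent
  rep2 <- full_typology(co, conditions = "CHD", algorithms = "RF", k = 4,
                        n_trees = 20, age_bins = list(c(66, 98)), seed = 7)
  expect_null(rep2$longitudinal)
})
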