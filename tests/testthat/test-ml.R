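toy_panel <- function(seed = 1, effect = 1) {
  simulate_cytokine_panel(n_vehicle = 8, n_treated = 6,
                          group_effect_day28 = effect, seed = seed)
}

test_that("feature engineering produces raw, difference and slope features", {
  pan <- data.frame(
    animal_id = rep(c("a1", "a2"), each = 3),
    group = rep(c("vehicle", "treated"), each = 3),
    day = rep(c(7, 14, 28), 2),
    variable = "IL-6",
    value = c(5, 5, 5, 1, 2, 3))
  fs <- feature_set("series", days = c(7, 14, 28), augment = TRUE)
  feats <- build_features(pan, fs)
  expect_equal(colnames(feats$X),
               c("IL-6_d7", "IL-6_d14", "IL-6_d28",
                 "IL-6_diff_d14_d7", "IL-6_diff_d28_d14", "IL-6_slope"))
  expect_equal(feats$y, c(0L, 1L))
  # constant series: zero differences, zero slope
  expect_equal(unname(feats$X["a1", 4:6]), c(0, 0, 0))
  # series (1,2,3) at days (7,14,28): diffs (1,1), slope Sxy/Sxx = 21/228.667
  expect_equal(unname(feats$X["a2", 4:5]), c(1, 1))
  expect_equal(unname(feats$X["a2", 6]), 21 / (686 / 3), tolerance = 1e-12)
  expect_error(build_features(pan[-2, ], fs), "animal a1.*day 14")
  expect_error(feature_set("one-day", days = 28, augment = TRUE), "augment")
})

test_that("a single-day cytokine set yields 12 raw features without augmentation", {
  pan <- toy_panel()
  feats <- build_features(pan, feature_set("day28", days = 28))
  expect_equal(ncol(feats$X), 12L)
  expect_false(any(grepl("slope|diff", colnames(feats$X))))
  expect_equal(sum(feats$y), 6L)
})

test_that("feature selection strategies keep the expected columns", {
  set.seed(3)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(0L, 1L), each = 20)
  X[, 4] <- X[, 4] + y * 3  # the only informative feature
  # percentile arithmetic: 20% of 10 features = 2
  sel <- select_features(X, y, "f_score_percentile", list(percentile = 20))
  expect_length(sel$keep, 2L)
  expect_true(4L %in% sel$keep)
  # percentile so small it would keep zero features: keep the single best
  sel1 <- select_features(X, y, "f_score_percentile", list(percentile = 1))
  expect_equal(sel1$keep, 4L)
  # identity strategy
  expect_equal(apply_selector(select_features(X, y, "none"), X), X)
  # embedded forest concentrates importance on the informative feature
  self <- select_features(X, y, "embedded_forest")
  expect_true(4L %in% self$keep)
  # pca projects to fewer columns but keeps the requested variance
  selp <- select_features(X, y, "pca", list(variance = 0.8))
  expect_lt(ncol(apply_selector(selp, X)), 10L)
})

test_that("pooled AUC matches pROC on random scores", {
  set.seed(4)
  for (i in 1:10) {
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)  # rounding forces score ties
    expect_equal(pooled_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("a perfectly separating feature gives pooled AUC 1 every repeat", {
  set.seed(6)
  n <- 26
  y <- rep(c(0L, 1L), c(15, 11))
  # class-constant separating feature: the held-out animal's value always
  # coincides with the training-set split threshold, so leave-one-out
  # cannot push it across the boundary
  X <- cbind(sep = y * 10, noise = matrix(rnorm(n * 5), n, 5))
  res <- nested_cv_evaluate(X, y, cheap_cv(seed = 2, n_repeats = 2))
  expect_equal(res$per_repeat_auc, c(1, 1))
  expect_true(res$gate_passed)
})

test_that("nested CV is deterministic given seed, config and data", {
  pan <- toy_panel(seed = 8, effect = 2)
  feats <- build_features(pan, feature_set("day28", days = 28))
  cfg <- cv_config(strategy = "f_score_percentile",
                   grid = expand.grid(max_depth = 2L, eta = 0.1,
                                      nrounds = c(20L, 40L),
                                      percentile = c(25, 100)),
                   inner_folds = 5, n_repeats = 2, seed = 99)
  r1 <- nested_cv_evaluate(feats$X, feats$y, cfg)
  r2 <- nested_cv_evaluate(feats$X, feats$y, cfg)
  expect_identical(r1$per_repeat_auc, r2$per_repeat_auc)
  expect_identical(r1$winners, r2$winners)
})

test_that("the held-out animal cannot influence its outer-fold model", {
  pan <- toy_panel(seed = 12, effect = 2)
  feats <- build_features(pan, feature_set("day28", days = 28))
  X <- feats$X; y <- feats$y
  cfg <- cheap_cv(seed = 31)
  i <- 3L
  set.seed(cfg$seed)
  fit1 <- tbitriage:::fit_outer_fold(X[-i, , drop = FALSE], y[-i], cfg)
  Xc <- X
  Xc[i, ] <- 1e6  # corrupt the held-out animal only
  set.seed(cfg$seed)
  fit2 <- tbitriage:::fit_outer_fold(Xc[-i, , drop = FALSE], y[-i], cfg)
  expect_identical(fit1$standardizer, fit2$standardizer)
  expect_identical(fit1$winner, fit2$winner)
  probe <- X[sample(nrow(X), 5), , drop = FALSE]
  expect_identical(tbitriage:::predict_outer_fold(fit1, probe),
                   tbitriage:::predict_outer_fold(fit2, probe))
})

test_that("labels with a missing class or missing features are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(nested_cv_evaluate(X, rep(1L, 10), cheap_cv(1)), "single-class")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(nested_cv_evaluate(Xna, rep(c(0L, 1L), 5), cheap_cv(1)),
               "missing feature")
  expect_error(cv_config(inner_folds = 1), "inner_folds")
  expect_error(cv_config(n_repeats = 0), "n_repeats")
})

test_that("permutation p is high for a chance-level AUC and needs >= 1 permutation", {
  pan <- toy_panel(seed = 14, effect = 1)
  feats <- build_features(pan, feature_set("day28", days = 28))
  cfg <- cheap_cv(seed = 41)
  obs <- nested_cv_evaluate(feats$X, feats$y, cfg)$mean_auc
  pp <- permutation_pvalue(feats$X, feats$y, cfg, obs, n_permutations = 19)
  expect_gte(pp$p, 1 / 20)
  expect_lte(pp$p, 1)
  expect_length(pp$permuted_auc, 19L)
  expect_error(permutation_pvalue(feats$X, feats$y, cfg, obs, 0),
               "n_permutations")
})

test_that("a strongly separated synthetic panel passes the AUC gate", {
  pan <- simulate_cytokine_panel(n_vehicle = 15, n_treated = 11,
                                 group_effect_day28 = 3, seed = 17)
  feats <- build_features(pan, feature_set("day28", days = 28))
  res <- nested_cv_evaluate(feats$X, feats$y, cheap_cv(seed = 5))
  expect_gt(res$mean_auc, 0.75)
  expect_true(res$gate_passed)
})
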