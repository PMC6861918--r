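#' Define a longitudinal feature set
#'
#' Names the variables and sampling days entering the classifier, and
#' whether the longitudinal augmentation (successive differences and
#' per-series least-squares slope) is applied. Single-day sets cannot be
#' augmented.
#'
#' @param name label for reports.
#' @param days numeric sampling days to include (e.g. `c(7, 14, 28)`).
#' @param variables variable names (cytokines/measures) to include;
#'   `NULL` = all present in the panel.
#' @param augment add successive differences and slope features?
#' @return a `feature_set` object.
#' @export
feature_set <- function(name, days, variables = NULL, augment = FALSE) {
  days <- sort(unique(days))
  if (length(days) < 1L) stop("feature set needs at least one day")
  if (augment && length(days) < 2L) {
    stop("augmentation requires a series of >= 2 days")
  }
  structure(list(name = name, days = days, variables = variables,
                 augment = augment),
            class = "feature_set")
}

# least-squares slope of value on day (units per day)
series_slope <- function(days, values) {
  dx <- days - mean(days)
  sum(dx * (values - mean(values))) / sum(dx^2)
}

#' Build a feature matrix from a longitudinal panel
#'
#' Pivots a long panel (one row per animal x day x variable) into an
#' animals-by-features matrix. Base features are the raw measurements at the
#' requested days (`<variable>_d<day>`); with `augment = TRUE` each series
#' additionally contributes the differences between subsequent measurements
#' (`<variable>_diff_d14_d7`, ...) and the least-squares slope of value on
#' actual day (`<variable>_slope`, units per day).
#'
#' @param panel data.frame with columns `animal_id`, `group`, `day`,
#'   `variable` (or `cytokine`), `value` (or `concentration`).
#' @param spec a [feature_set()].
#' @return list: `X` (numeric matrix), `y` (integer labels, treated = 1),
#'   `animals`, `groups`.
#' @export
build_features <- function(panel, spec) {
  stopifnot(inherits(spec, "feature_set"), is.data.frame(panel))
  if ("cytokine" %in% names(panel) && !"variable" %in% names(panel)) {
    names(panel)[names(panel) == "cytokine"] <- "variable"
  }
  if ("concentration" %in% names(panel) && !"value" %in% names(panel)) {
    names(panel)[names(panel) == "concentration"] <- "value"
  }
  stopifnot(all(c("animal_id", "group", "day", "variable", "value")
                %in% names(panel)))
  if (any(panel$value < 0, na.rm = TRUE)) stop("panel values must be >= 0")
  vars <- spec$variables
  if (is.null(vars)) vars <- sort(unique(panel$variable))
  panel <- panel[panel$variable %in% vars & panel$day %in% spec$days, ,
                 drop = FALSE]
  panel$animal_id <- as.character(panel$animal_id)
  animals <- unique(panel$animal_id)
  groups <- vapply(animals, function(a) {
    unique(panel$group[panel$animal_id == a])[1L]
  }, character(1))
  ndays <- length(spec$days)
  series <- array(NA_real_, dim = c(length(animals), length(vars), ndays),
                  dimnames = list(animals, vars, paste0("d", spec$days)))
  for (i in seq_len(nrow(panel))) {
    series[panel$animal_id[i], panel$variable[i],
           paste0("d", panel$day[i])] <- panel$value[i]
  }
  if (anyNA(series)) {
    miss <- which(is.na(series), arr.ind = TRUE)[1L, ]
    stop("missing measurement: animal ", animals[miss[1L]],
         ", variable ", vars[miss[2L]], ", day ", spec$days[miss[3L]])
  }
  cols <- list()
  for (v in vars) {
    for (j in seq_len(ndays)) {
      cols[[paste0(v, "_d", spec$days[j])]] <- series[, v, j]
    }
  }
  if (spec$augment) {
    for (v in vars) {
      for (j in 2:ndays) {
        nm <- paste0(v, "_diff_d", spec$days[j], "_d", spec$days[j - 1L])
        cols[[nm]] <- series[, v, j] - series[, v, j - 1L]
      }
      cols[[paste0(v, "_slope")]] <- apply(series[, v, , drop = FALSE], 1L,
                                           function(vals) {
                                             series_slope(spec$days, vals)
                                           })
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- animals
  list(X = X,
       y = as.integer(groups != "vehicle"),
       animals = animals, groups = groups)
}

#' Pooled ROC AUC
#'
#' Area under the ROC curve from scores and binary labels, via the rank
#' (Mann-Whitney) formula with midrank tie handling.
#'
#' @param scores numeric classifier scores (higher = more class-1).
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
pooled_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# one-way (two-group) F statistic per column
f_scores <- function(X, y) {
  y1 <- y == 1L
  n1 <- sum(y1); n0 <- sum(!y1); n <- n1 + n0
  m1 <- colMeans(X[y1, , drop = FALSE])
  m0 <- colMeans(X[!y1, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums(sweep(X[y1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(X[!y1, , drop = FALSE], 2L, m0)^2)
  ifelse(ssw <= 0, Inf, ssb / (ssw / (n - 2)))
}

#' Fit a feature-selection step on training data
#'
#' Strategies: `f_score_percentile` keeps the top percentile of features by
#' the one-way F statistic (at least one feature); `embedded_forest` fits an
#' extremely-randomized tree ensemble and keeps features with above-average
#' impurity importance; `pca` projects onto the leading principal components
#' retaining a configured variance fraction; `none` is the identity. The fit
#' uses training rows only; apply the returned selector to held-out rows
#' with [apply_selector()].
#'
#' @param X training feature matrix (already standardized).
#' @param y training labels (0/1).
#' @param strategy one of "f_score_percentile", "embedded_forest", "pca",
#'   "none".
#' @param params list: `percentile` (f_score_percentile), `variance` (pca).
#' @return a `feature_selector`.
#' @export
select_features <- function(X, y, strategy = "none", params = list()) {
  sel <- switch(
    strategy,
    none = list(type = "columns", keep = seq_len(ncol(X))),
    f_score_percentile = {
      pct <- params$percentile
      if (is.null(pct)) stop("f_score_percentile needs params$percentile")
      f <- f_scores(X, y)
      n_keep <- max(1L, floor(pct / 100 * ncol(X) + 1e-9))
      list(type = "columns",
           keep = sort(order(-f, seq_along(f))[seq_len(n_keep)]))
    },
    embedded_forest = {
      dat <- data.frame(.y = factor(y), X, check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = 100L, splitrule = "extratrees",
        importance = "impurity", num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      keep <- which(imp > mean(imp))
      if (length(keep) == 0L) keep <- which.max(imp)
      list(type = "columns", keep = sort(unname(keep)))
    },
    pca = {
      variance <- if (is.null(params$variance)) 0.95 else params$variance
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      k <- max(1L, which(cumvar >= variance)[1L])
      list(type = "pca", center = pc$center,
           rotation = pc$rotation[, seq_len(k), drop = FALSE])
    },
    stop("unknown feature-selection strategy: ", strategy)
  )
  structure(sel, class = "feature_selector")
}

#' Apply a fitted feature selector to new rows
#' @param selector from [select_features()].
#' @param X feature matrix (same columns as the training matrix).
#' @return transformed matrix.
#' @export
apply_selector <- function(selector, X) {
  stopifnot(inherits(selector, "feature_selector"))
  if (selector$type == "columns") return(X[, selector$keep, drop = FALSE])
  sweep(X, 2L, selector$center) %*% selector$rotation
}

#' Default hyperparameter grid for nested cross-validation
#'
#' Gradient-boosted-tree depth \{2, 3\}, learning rate \{0.05, 0.1\} and
#' number of trees \{50, 200\}, crossed with the feature-selection
#' hyperparameter where the strategy has one (F-score percentile
#' \{10, 25, 50, 100\}; PCA variance fraction \{0.8, 0.95\}).
#'
#' @param strategy feature-selection strategy (see [select_features()]).
#' @return data.frame grid, one row per hyperparameter combination.
#' @export
default_grid <- function(strategy = "f_score_percentile") {
  base <- expand.grid(max_depth = c(2L, 3L), eta = c(0.05, 0.1),
                      nrounds = c(50L, 200L))
  switch(strategy,
         f_score_percentile = merge(base,
                                    data.frame(percentile = c(10, 25, 50, 100))),
         pca = merge(base, data.frame(variance = c(0.8, 0.95))),
         base)
}

#' Nested cross-validation configuration
#'
#' @param strategy feature-selection strategy used inside the inner loop.
#' @param grid hyperparameter grid (default [default_grid()] for the
#'   strategy).
#' @param inner_folds stratified inner folds (default 10).
#' @param n_repeats repetitions with fresh fold randomization (default 10).
#' @param auc_gate mean-AUC threshold for advancement (default 0.75).
#' @param seed master seed; every random draw of the evaluation derives
#'   from it.
#' @return a `cv_config` list.
#' @export
cv_config <- function(strategy = "f_score_percentile", grid = NULL,
                      inner_folds = 10L, n_repeats = 10L,
                      auc_gate = 0.75, seed = 1L) {
  if (is.null(grid)) grid <- default_grid(strategy)
  if (inner_folds < 2L) stop("inner_folds must be >= 2")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(strategy = strategy, grid = grid,
                 inner_folds = as.integer(inner_folds),
                 n_repeats = as.integer(n_repeats),
                 auc_gate = auc_gate, seed = as.integer(seed)),
            class = "cv_config")
}

# stratified fold ids; re-drawn until every training set keeps both classes
draw_folds <- function(y, k) {
  k <- min(k, length(y) - 1L)
  for (attempt in 1:100) {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- y[folds != f]
      length(unique(tr)) == 2L && length(tr) > 0L
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not draw stratified folds without a single-class training set")
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(st, X) {
  sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")
}

xgb_fit <- function(X, y, max_depth, eta, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_score <- function(model, X, nrounds = NULL) {
  dx <- xgboost::xgb.DMatrix(X, nthread = 1)
  if (is.null(nrounds)) stats::predict(model, dx)
  else stats::predict(model, dx, iterationrange = c(1L, nrounds))
}

# grid columns that parameterize the feature-selection step
selection_cols <- function(strategy) {
  switch(strategy, f_score_percentile = "percentile", pca = "variance",
         character(0))
}

# Fit one outer fold: standardize on training rows, grid-search via
# stratified inner CV (pooled inner AUC), refit winner on the full training
# set. Sees training rows only; leakage-freedom is structural.
fit_outer_fold <- function(Xtr, ytr, config) {
  st <- standardizer(Xtr)
  Xs <- apply_standardizer(st, Xtr)
  grid <- config$grid
  sel_cols <- selection_cols(config$strategy)
  if (nrow(grid) == 1L) {
    # degenerate grid: nothing to search, no inner loop needed
    wrow <- grid[1L, , drop = FALSE]
    sel <- select_features(Xs, ytr, config$strategy,
                           as.list(wrow[, sel_cols, drop = FALSE]))
    model <- xgb_fit(apply_selector(sel, Xs), ytr,
                     wrow$max_depth, wrow$eta, wrow$nrounds)
    return(list(standardizer = st, selector = sel, model = model,
                winner = wrow, inner_auc = NA_real_))
  }
  other_cols <- setdiff(names(grid), "nrounds")
  combos <- unique(grid[, other_cols, drop = FALSE])
  folds <- draw_folds(ytr, config$inner_folds)
  k <- max(folds)
  grid_auc <- numeric(nrow(grid))
  grid_preds <- matrix(NA_real_, nrow = nrow(grid), ncol = length(ytr))
  for (ci in seq_len(nrow(combos))) {
    combo <- combos[ci, , drop = FALSE]
    rows <- which(apply(grid[, other_cols, drop = FALSE], 1L, function(r) {
      all(r == unlist(combo))
    }))
    nrs <- grid$nrounds[rows]
    params <- as.list(combo[, sel_cols, drop = FALSE])
    for (f in seq_len(k)) {
      tr <- folds != f
      sel <- select_features(Xs[tr, , drop = FALSE], ytr[tr],
                             config$strategy, params)
      Xin <- apply_selector(sel, Xs[tr, , drop = FALSE])
      Xval <- apply_selector(sel, Xs[!tr, , drop = FALSE])
      model <- xgb_fit(Xin, ytr[tr], combo$max_depth, combo$eta, max(nrs))
      for (j in seq_along(rows)) {
        grid_preds[rows[j], !tr] <- xgb_score(model, Xval, nrs[j])
      }
    }
  }
  for (gi in seq_len(nrow(grid))) {
    grid_auc[gi] <- pooled_auc(grid_preds[gi, ], ytr)
  }
  winner <- which.max(grid_auc)  # first max: deterministic tie-break
  wrow <- grid[winner, , drop = FALSE]
  sel <- select_features(Xs, ytr, config$strategy,
                         as.list(wrow[, sel_cols, drop = FALSE]))
  model <- xgb_fit(apply_selector(sel, Xs), ytr,
                   wrow$max_depth, wrow$eta, wrow$nrounds)
  list(standardizer = st, selector = sel, model = model,
       winner = wrow, inner_auc = grid_auc[winner])
}

predict_outer_fold <- function(fit, Xnew) {
  Xs <- apply_standardizer(fit$standardizer, Xnew)
  xgb_score(fit$model, apply_selector(fit$selector, Xs),
            fit$winner$nrounds)
}

#' Nested cross-validated evaluation of a cytokine classifier
#'
#' Leave-one-out on the outer level: for each held-out animal, features are
#' standardized with the outer-training mean/SD only, hyperparameters
#' (including the feature-selection parameter) are chosen by stratified
#' inner k-fold grid search maximizing the AUC of the pooled inner
#' predictions, the winning configuration is refit on the full outer
#' training set, and the held-out animal is scored with its class-1
#' probability. The pooled held-out scores give one AUC per repeat; repeats
#' differ in inner fold randomization. The gate passes when the mean AUC
#' over repeats exceeds `auc_gate`.
#'
#' @param X feature matrix (animals x features), e.g. from
#'   [build_features()].
#' @param y binary labels (1 = treated).
#' @param config a [cv_config()].
#' @return list: `per_repeat_auc`, `mean_auc`, `gate_passed`, `auc_gate`,
#'   `scores` (held-out scores of the last repeat), `winners` (selected
#'   hyperparameters per repeat x outer fold).
#' @export
nested_cv_evaluate <- function(X, y, config) {
  stopifnot(inherits(config, "cv_config"), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class labels; nothing to classify")
  if (min(table(y)) < 2L) stop("need >= 2 animals per class")
  if (anyNA(X)) stop("missing feature values")
  set.seed(config$seed)
  n <- length(y)
  per_repeat_auc <- numeric(config$n_repeats)
  winners <- NULL
  scores <- NULL
  for (rep_i in seq_len(config$n_repeats)) {
    scores <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_outer_fold(X[-i, , drop = FALSE], y[-i], config)
      scores[i] <- predict_outer_fold(fit, X[i, , drop = FALSE])
      winners <- rbind(winners,
                       cbind(data.frame(repeat_i = rep_i, fold = i),
                             fit$winner))
    }
    per_repeat_auc[rep_i] <- pooled_auc(scores, y)
  }
  mean_auc <- mean(per_repeat_auc)
  rownames(winners) <- NULL
  list(per_repeat_auc = per_repeat_auc, mean_auc = mean_auc,
       gate_passed = mean_auc > config$auc_gate, auc_gate = config$auc_gate,
       scores = scores, winners = winners)
}

#' Permutation p-value for a cross-validated AUC
#'
#' Repeats the full nested-CV evaluation on label-permuted copies of the
#' data and reports the finite-sample-corrected p-value
#' `(1 + #\{permuted AUC >= observed\}) / (1 + n_permutations)`.
#' Permutations are drawn from a stream derived from `config$seed`, so the
#' result is reproducible.
#'
#' @param X,y as in [nested_cv_evaluate()].
#' @param config the same configuration used for the observed AUC.
#' @param observed_auc the observed mean AUC.
#' @param n_permutations number of permutations (>= 1).
#' @return list: `p`, `permuted_auc`.
#' @export
permutation_pvalue <- function(X, y, config, observed_auc,
                               n_permutations = 99L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  set.seed(config$seed + 500009L)
  perms <- lapply(seq_len(n_permutations), function(i) sample(y))
  permuted_auc <- vapply(perms, function(yp) {
    nested_cv_evaluate(X, yp, config)$mean_auc
  }, numeric(1))
  list(p = (1 + sum(permuted_auc >= observed_auc)) / (1 + n_permutations),
       permuted_auc = permuted_auc)
}
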