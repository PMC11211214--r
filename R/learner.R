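# The supervised core: unit-interval scaling, shadow-feature (Boruta-style)
# selection scored by tree-SHAP importances, random-search hyper-parameter
# tuning maximizing inner-fold mean average precision, per-outer-fold
# gradient-boosted training with early stopping, prediction, and Shapley
# attribution. All fits are single-threaded and seeded for determinism;
# scaler, selection, and tuning only ever see outer-training rows.

#' Fit a unit-interval scaler
#'
#' Per-column min-max statistics computed from the fitting rows only; the
#' transform is `(x - min) / (max - min)`. Constant columns map to 0.
#' Transformed values of unseen rows may fall outside `[0, 1]` — there is no
#' clipping, so out-of-range test values remain visible to the model.
#'
#' @param x Numeric matrix (fitting rows only).
#' @return Object of class `ep_scaler` with `min` and `range` vectors.
#' @export
fit_unit_scaler <- function(x) {
  stopifnot(nrow(x) > 0)
  mins <- apply(x, 2, min)
  rng <- apply(x, 2, max) - mins
  structure(list(min = mins, range = rng), class = "ep_scaler")
}

#' Apply a unit-interval scaler
#'
#' @param scaler An `ep_scaler` from [fit_unit_scaler()].
#' @param x Numeric matrix with the scaler's columns.
#' @return Scaled matrix; columns constant in the fitting rows become 0.
#' @export
apply_unit_scaler <- function(scaler, x) {
  stopifnot(identical(colnames(x), names(scaler$min)))
  rng <- scaler$range
  out <- sweep(x, 2, scaler$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], `/`)
  out[, !nz] <- 0
  out
}

#' Scale features to the unit interval
#'
#' Convenience wrapper: fits the scaler on `fit_rows` and transforms the full
#' matrix.
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices used to fit the statistics.
#' @return List with `scaler` and `x` (transformed full matrix).
#' @export
scale_unit_interval <- function(x, fit_rows = seq_len(nrow(x))) {
  scaler <- fit_unit_scaler(x[fit_rows, , drop = FALSE])
  list(scaler = scaler, x = apply_unit_scaler(scaler, x))
}

# ---- xgboost plumbing -------------------------------------------------------

default_hyperparams <- function(y = NULL) {
  spw <- if (is.null(y) || sum(y == 1) == 0) 1 else sum(y == 0) / sum(y == 1)
  list(max_depth = 5L, learning_rate = 0.1, min_child_weight = 1,
       subsample = 0.9, colsample_bytree = 0.9, reg_alpha = 0,
       reg_lambda = 1, scale_pos_weight = spw, max_rounds = 500L)
}

hyperparam_bounds <- function(y) {
  spw_max <- max(1, sum(y == 0) / max(1, sum(y == 1)))
  list(max_depth = c(2L, 10L),
       learning_rate = c(0.005, 0.3),      # log-uniform
       min_child_weight = c(1, 20),        # log-uniform
       subsample = c(0.5, 1),
       colsample_bytree = c(0.5, 1),
       reg_alpha = c(1e-4, 1),             # log-uniform
       reg_lambda = c(1e-2, 10),           # log-uniform
       scale_pos_weight = c(1, spw_max),
       max_rounds = 2000L)
}

sample_hyperparams <- function(bounds) {
  lunif <- function(b) exp(stats::runif(1, log(b[1]), log(b[2])))
  list(max_depth = sample(seq(bounds$max_depth[1], bounds$max_depth[2]), 1),
       learning_rate = lunif(bounds$learning_rate),
       min_child_weight = lunif(bounds$min_child_weight),
       subsample = stats::runif(1, bounds$subsample[1], bounds$subsample[2]),
       colsample_bytree = stats::runif(1, bounds$colsample_bytree[1],
                                       bounds$colsample_bytree[2]),
       reg_alpha = lunif(bounds$reg_alpha),
       reg_lambda = lunif(bounds$reg_lambda),
       scale_pos_weight = stats::runif(1, bounds$scale_pos_weight[1],
                                       bounds$scale_pos_weight[2]),
       max_rounds = bounds$max_rounds)
}

xgb_params <- function(hp, seed, eval_metric = "aucpr") {
  xgboost::xgb.params(objective = "binary:logistic", eval_metric = eval_metric,
                      tree_method = "hist", nthread = 1, seed = seed,
                      max_depth = hp$max_depth,
                      learning_rate = hp$learning_rate,
                      min_child_weight = hp$min_child_weight,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      reg_alpha = hp$reg_alpha, reg_lambda = hp$reg_lambda,
                      scale_pos_weight = hp$scale_pos_weight)
}

xgb_fit <- function(x, y, hp, seed, nrounds, val = NULL,
                    early_stop_rounds = NULL) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  evals <- list()
  metric <- "aucpr"
  if (!is.null(val)) {
    evals <- list(val = xgboost::xgb.DMatrix(val$x, label = val$y,
                                             nthread = 1))
    # aucpr is undefined on a single-class validation split
    if (length(unique(val$y)) < 2L) metric <- "logloss"
  }
  xgboost::xgb.train(params = xgb_params(hp, seed, metric), data = dtrain,
                     nrounds = nrounds, evals = evals,
                     early_stopping_rounds = early_stop_rounds,
                     verbose = 0)
}

booster_best_iteration <- function(bst) {
  bi <- xgboost::xgb.attr(bst, "best_iteration")
  if (is.null(bi)) NA_integer_ else as.integer(bi)
}

# ---- shadow-feature selection -----------------------------------------------

#' Boruta-style shadow-feature selection with SHAP importances
#'
#' Each round appends a shadow copy of every feature (its values permuted
#' independently), trains a preliminary boosted ensemble on the augmented
#' matrix, and computes mean-|SHAP| importances; a real feature scores a hit
#' when its importance beats the best shadow's. After `n_rounds`, features
#' with hit counts above the upper `binomial(n_rounds, 0.5)` quantile at
#' level `alpha_sel` are confirmed, those below the lower quantile rejected,
#' and the remainder tentative (kept by default — conservative under extreme
#' class imbalance).
#'
#' @param x Scaled numeric feature matrix (training rows only).
#' @param y Binary labels.
#' @param seed Integer seed.
#' @param n_rounds Number of shadow rounds (at least 5).
#' @param alpha_sel Two-sided binomial level for the hit test.
#' @param keep_tentative Keep tentative features in the selected set.
#' @param prelim_hp Hyper-parameters of the preliminary ensembles.
#' @param prelim_rounds Boosting rounds of the preliminary ensembles.
#' @param max_rows Row cap for each round's preliminary fit. Larger training
#'   splits are subsampled per round — every positive is kept and negatives
#'   are drawn at random — since selection needs importances that are only
#'   roughly right, and under ~2% prevalence the positives carry the signal.
#' @return List with `selected`, `confirmed`, `tentative`, `rejected`
#'   (character vectors) and `hits` (named integer vector).
#' @export
boruta_select <- function(x, y, seed = 1L, n_rounds = 10L, alpha_sel = 0.05,
                          keep_tentative = TRUE, prelim_hp = NULL,
                          prelim_rounds = 40L, max_rows = 8000L) {
  if (n_rounds < 5L) stop("n_rounds must be at least 5")
  if (is.null(prelim_hp)) {
    prelim_hp <- default_hyperparams(y)
    prelim_hp$max_depth <- 4L
  }
  p <- ncol(x)
  feat <- colnames(x)
  hits <- stats::setNames(integer(p), feat)
  pos <- which(y == 1)
  neg <- which(y == 0)
  for (r in seq_len(n_rounds)) {
    set.seed(seed * 1000L + r)
    rows <- if (nrow(x) > max_rows) {
      sort(c(pos, sample(neg, max(0L, max_rows - length(pos)))))
    } else seq_len(nrow(x))
    xr <- x[rows, , drop = FALSE]
    shadow <- apply(xr, 2, sample)
    colnames(shadow) <- paste0(".shadow.", feat)
    xa <- cbind(xr, shadow)
    bst <- xgb_fit(xa, y[rows], prelim_hp, seed = seed * 1000L + r,
                   nrounds = prelim_rounds)
    # importances need only an unbiased row sample; keep every positive
    pos_r <- which(y[rows] == 1)
    neg_r <- which(y[rows] == 0)
    srows <- if (length(rows) > 3000L) {
      sort(c(pos_r, sample(neg_r, max(0L, 3000L - length(pos_r)))))
    } else seq_along(rows)
    contrib <- predict(bst, xa[srows, , drop = FALSE], predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, seq_len(2L * p), drop = FALSE]))
    real_imp <- imp[seq_len(p)]
    shadow_max <- max(imp[p + seq_len(p)])
    hits <- hits + as.integer(real_imp > shadow_max)
  }
  upper <- stats::qbinom(1 - alpha_sel, n_rounds, 0.5)
  lower <- stats::qbinom(alpha_sel, n_rounds, 0.5)
  confirmed <- feat[hits > upper]
  rejected <- feat[hits < lower]
  tentative <- setdiff(feat, c(confirmed, rejected))
  selected <- if (keep_tentative) c(confirmed, tentative) else confirmed
  if (length(selected) == 0L) {
    warning("shadow selection rejected every feature; keeping all features")
    selected <- feat
  }
  list(selected = feat[feat %in% selected], confirmed = confirmed,
       tentative = tentative, rejected = rejected, hits = hits)
}

# ---- hyper-parameter tuning -------------------------------------------------

#' Tune hyper-parameters on the inner folds
#'
#' Random search within declared bounds (depth 2-10; learning rate
#' 0.005-0.3 and regularization log-uniform; subsamples 0.5-1; positive-class
#' weight up to the negative/positive ratio). Each candidate is trained on
#' every inner training split with early stopping on the inner validation
#' split and scored by the mean average precision across inner validations;
#' the argmax candidate is returned. The first candidate evaluated is always
#' the default parameter set.
#'
#' @param x Scaled feature matrix (outer training rows).
#' @param y Binary labels.
#' @param inner Inner fold id per row (1..inner_k).
#' @param budget Number of candidates (>= 1).
#' @param seed Integer seed.
#' @param early_stop_rounds Early-stopping patience.
#' @return List with `params` (best candidate), `map` (its inner MAP), and
#'   `trace` (`data.table` of candidate index and MAP).
#' @export
tune_hyperparams <- function(x, y, inner, budget = 6L, seed = 1L,
                             early_stop_rounds = 25L) {
  if (budget < 1L) stop("budget must be >= 1")
  stopifnot(length(inner) == nrow(x))
  bounds <- hyperparam_bounds(y)
  folds <- sort(unique(inner))
  set.seed(seed)
  candidates <- vector("list", budget)
  candidates[[1]] <- default_hyperparams(y)
  if (budget > 1L)
    for (i in 2:budget) candidates[[i]] <- sample_hyperparams(bounds)
  maps <- numeric(budget)
  for (i in seq_len(budget)) {
    hp <- candidates[[i]]
    aps <- vapply(folds, function(f) {
      tr <- inner != f
      if (sum(y[!tr]) == 0L) return(NA_real_)  # AP undefined without positives
      bst <- xgb_fit(x[tr, , drop = FALSE], y[tr], hp,
                     seed = seed + i,
                     nrounds = min(hp$max_rounds, 500L),
                     val = list(x = x[!tr, , drop = FALSE], y = y[!tr]),
                     early_stop_rounds = early_stop_rounds)
      average_precision(predict(bst, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    maps[i] <- mean(aps, na.rm = TRUE)
  }
  best <- which.max(maps)
  list(params = candidates[[best]], map = maps[best],
       trace = data.table::data.table(candidate = seq_len(budget),
                                      map = maps))
}

# ---- training / prediction / attribution ------------------------------------

#' Train one outer-fold model
#'
#' Boosts on the training rows (selected features only) with early stopping
#' when the validation average precision fails to improve for
#' `early_stop_rounds` rounds. The validation split must be disjoint from
#' the training rows and lie inside the outer training split.
#'
#' @param x Scaled feature matrix (selected features only).
#' @param y Binary labels.
#' @param params Hyper-parameter list (e.g. from [tune_hyperparams()]).
#' @param val_rows Indices of validation rows within `x`.
#' @param early_stop_rounds Early-stopping patience.
#' @param fold Outer fold id recorded in the bundle.
#' @param seed Integer seed.
#' @param scaler The `ep_scaler` fitted on the outer training split.
#' @return Object of class `ep_model_bundle`.
#' @export
train_model <- function(x, y, params = default_hyperparams(y),
                        val_rows, early_stop_rounds = 25L, fold = NA_integer_,
                        seed = 1L, scaler = NULL) {
  if (length(unique(y)) < 2L) stop("single-class labels; cannot train")
  stopifnot(length(val_rows) > 0, length(val_rows) < nrow(x))
  tr <- setdiff(seq_len(nrow(x)), val_rows)
  bst <- xgb_fit(x[tr, , drop = FALSE], y[tr], params, seed = seed,
                 nrounds = params$max_rounds,
                 val = list(x = x[val_rows, , drop = FALSE], y = y[val_rows]),
                 early_stop_rounds = early_stop_rounds)
  structure(list(booster = bst, scaler = scaler,
                 features = colnames(x), params = params, fold = fold,
                 seed = seed,
                 best_iteration = booster_best_iteration(bst),
                 early_stop_rounds = early_stop_rounds),
            class = "ep_model_bundle")
}

#' @export
print.ep_model_bundle <- function(x, ...) {
  cat(sprintf("ep_model_bundle: fold %s, %d features, stopped at round %s\n",
              x$fold, length(x$features), x$best_iteration))
  invisible(x)
}

#' Predict positive-class scores
#'
#' Scores in (0, 1) from the fitted ensemble; only the bundle's selected
#' features are consumed, so extra columns in `x` are ignored. If the bundle
#' carries a scaler and `x` is raw, pass `scale = TRUE` to apply it.
#'
#' @param bundle An `ep_model_bundle`.
#' @param x Numeric matrix containing at least the bundle's features.
#' @param scale Apply the bundle's scaler to `x` first.
#' @return Numeric vector of scores, row order preserved.
#' @export
predict_scores <- function(bundle, x, scale = FALSE) {
  if (nrow(x) == 0L) return(numeric(0))
  missing_feat <- setdiff(bundle$features, colnames(x))
  if (length(missing_feat))
    stop("missing feature column(s): ", paste(missing_feat, collapse = ", "))
  if (scale) {
    x <- x[, names(bundle$scaler$min), drop = FALSE]
    x <- apply_unit_scaler(bundle$scaler, x)
  }
  predict(bundle$booster, x[, bundle$features, drop = FALSE])
}

#' Tree-SHAP attributions
#'
#' Exact tree-path Shapley attributions per row and feature on the margin
#' (log-odds) scale; per row the attributions plus the base value equal the
#' model's margin prediction (local accuracy).
#'
#' @param bundle An `ep_model_bundle`.
#' @param x Numeric matrix containing the bundle's features (already
#'   scaled, or pass `scale = TRUE`).
#' @param scale Apply the bundle's scaler first.
#' @return Object of class `ep_shap`: list with `values` (rows x features),
#'   `base` (per-row base value), `fold`.
#' @export
shap_attributions <- function(bundle, x, scale = FALSE) {
  if (scale) {
    x <- x[, names(bundle$scaler$min), drop = FALSE]
    x <- apply_unit_scaler(bundle$scaler, x)
  }
  xm <- x[, bundle$features, drop = FALSE]
  contrib <- predict(bundle$booster, xm, predcontrib = TRUE)
  nb <- ncol(contrib)
  structure(list(values = contrib[, -nb, drop = FALSE],
                 base = contrib[, nb], fold = bundle$fold),
            class = "ep_shap")
}

#' Concatenate SHAP matrices across folds
#'
#' Rows are stacked in order. When folds selected different feature subsets
#' the columns are aligned on the union, with zeros for features absent from
#' a fold's model (an unselected feature contributes nothing to that fold's
#' predictions). Disjoint feature sets are an error.
#'
#' @param shaps List of `ep_shap` objects.
#' @return One `ep_shap` with rows concatenated in order.
#' @export
concat_shap <- function(shaps) {
  cols <- lapply(shaps, function(s) colnames(s$values))
  if (length(shaps) > 1L && length(Reduce(intersect, cols)) == 0L)
    stop("SHAP matrices have disjoint feature sets")
  all_cols <- Reduce(union, cols)
  aligned <- lapply(shaps, function(s) {
    out <- matrix(0, nrow(s$values), length(all_cols),
                  dimnames = list(NULL, all_cols))
    out[, colnames(s$values)] <- s$values
    out
  })
  structure(list(values = do.call(rbind, aligned),
                 base = unlist(lapply(shaps, `[[`, "base")),
                 fold = NA_integer_),
            class = "ep_shap")
}

#' Rank features by mean absolute SHAP value
#'
#' Features sorted by the mean of |attribution| over all rows of the
#' (concatenated) SHAP matrices, descending; ties broken by feature name.
#'
#' @param shaps An `ep_shap` or list of them (concatenated first).
#' @return `data.table` with columns `feature` and `mean_abs_shap`.
#' @export
rank_features_by_mean_abs_shap <- function(shaps) {
  if (inherits(shaps, "ep_shap")) shaps <- list(shaps)
  s <- concat_shap(shaps)
  m <- colMeans(abs(s$values))
  ord <- order(-m, names(m))
  data.table::data.table(feature = names(m)[ord],
                         mean_abs_shap = unname(m)[ord])
}

# ---- end-to-end orchestration -----------------------------------------------

#' Run the full supervised pipeline on labeled pairs
#'
#' For each outer fold of the genomically blocked plan: fits the
#' unit-interval scaler on the outer training split, runs shadow-feature
#' selection, tunes hyper-parameters by inner-fold mean average precision,
#' trains with early stopping (inner fold 1 is the early-stop validation
#' split), then scores and attributes the held-out outer fold. Models are
#' never merged or refit on combined folds; per-fold SHAP matrices are
#' combined by concatenation.
#'
#' @param features Assembled feature table ([assemble_features()]).
#' @param labels Binary label per row.
#' @param groups Blocking group id per row ([ep_groups()]).
#' @param cfg A [pipeline_config()].
#' @return List of class `ep_pipeline_fit`: `bundles` (one per outer fold),
#'   `scores` (out-of-fold score per row), `fold_ap` (per-fold test AP),
#'   `shap` (concatenated `ep_shap` over the outer test folds, rows in
#'   `shap_rows` order), `ranking` (mean-|SHAP| feature ranking), `plan`.
#' @export
run_ep_pipeline <- function(features, labels, groups, cfg = pipeline_config()) {
  x_all <- feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(x_all) == length(y), length(groups) == length(y))
  plan <- nested_group_kfold(groups, y, cfg$outer_folds, cfg$inner_folds,
                             cfg$seed)
  scores <- rep(NA_real_, length(y))
  bundles <- vector("list", cfg$outer_folds)
  shaps <- vector("list", cfg$outer_folds)
  shap_rows <- integer(0)
  fold_ap <- numeric(cfg$outer_folds)
  for (f in seq_len(cfg$outer_folds)) {
    tr <- which(plan$outer != f)
    te <- which(plan$outer == f)
    scaler <- fit_unit_scaler(x_all[tr, , drop = FALSE])
    xs <- apply_unit_scaler(scaler, x_all)
    sel <- boruta_select(xs[tr, , drop = FALSE], y[tr],
                         seed = cfg$seed + f, n_rounds = cfg$boruta_rounds)
    feats <- sel$selected
    inner <- plan[[paste0("inner", f)]][tr]
    tuned <- tune_hyperparams(xs[tr, feats, drop = FALSE], y[tr], inner,
                              budget = cfg$tune_budget, seed = cfg$seed + f,
                              early_stop_rounds = cfg$early_stop_rounds)
    val_rows <- which(inner == min(inner))
    bundle <- train_model(xs[tr, feats, drop = FALSE], y[tr],
                          params = tuned$params, val_rows = val_rows,
                          early_stop_rounds = cfg$early_stop_rounds,
                          fold = f, seed = cfg$seed + f, scaler = scaler)
    bundle$selection <- sel
    bundle$tuning <- tuned$trace
    bundles[[f]] <- bundle
    scores[te] <- predict_scores(bundle, xs[te, , drop = FALSE])
    fold_ap[f] <- if (sum(y[te]) > 0) average_precision(scores[te], y[te])
    else NA_real_
    shaps[[f]] <- shap_attributions(bundle, xs[te, , drop = FALSE])
    shap_rows <- c(shap_rows, te)
  }
  shap <- concat_shap(shaps)
  structure(list(bundles = bundles, scores = scores, fold_ap = fold_ap,
                 shap = shap, shap_rows = shap_rows,
                 ranking = rank_features_by_mean_abs_shap(shap),
                 plan = plan, cfg = cfg),
            class = "ep_pipeline_fit")
}

#' @export
print.ep_pipeline_fit <- function(x, ...) {
  cat(sprintf("ep_pipeline_fit: %d folds, out-of-fold AP per fold: %s\n",
              length(x$bundles),
              paste(sprintf("%.3f", x$fold_ap), collapse = ", ")))
  invisible(x)
}

#' Score an unseen set with every fold model
#'
#' Applies each outer-fold bundle (its own scaler and feature set) to a raw
#' feature table and returns per-fold scores plus their mean (the
#' fold-combined score).
#'
#' @param fit An `ep_pipeline_fit`.
#' @param features Assembled feature table of unseen pairs.
#' @return List with `per_fold` (matrix rows x folds) and `mean` scores.
#' @export
predict_holdout <- function(fit, features) {
  x <- feature_matrix(features)
  per_fold <- vapply(fit$bundles, function(b) {
    predict_scores(b, x, scale = TRUE)
  }, numeric(nrow(x)))
  list(per_fold = per_fold, mean = rowMeans(per_fold))
}
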