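# supervised core: scaling, shadow selection, tuning, training, prediction,
# Shapley attribution, and the no-leakage guarantee

toy_xy <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- cbind(signal = c(rep(1, n / 4), rep(0, 3 * n / 4)) ,
             noise = runif(n))
  y <- as.integer(x[, "signal"] == 1)
  list(x = x, y = y)
}

test_that("unit-interval scaling uses training statistics without clipping", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- scale_unit_interval(x)
  expect_equal(unname(sc$x[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(sc$x[, "b"]), c(0, 0, 0))   # constant column
  xt <- cbind(a = 8, b = 7)
  expect_equal(unname(apply_unit_scaler(sc$scaler, xt)[, "a"]), 1.5)
})

test_that("shadow selection confirms planted features, rejects pure noise", {
  set.seed(2)
  n <- 4000
  x <- matrix(runif(n * 23), n, 23,
              dimnames = list(NULL, c(paste0("causal", 1:3),
                                      paste0("noise", 1:20))))
  logit <- -4.5 + 3 * x[, 1] + 2.5 * x[, 2] - 3 * x[, 3]
  y <- rbinom(n, 1, plogis(logit))
  sel <- boruta_select(x, y, seed = 1, n_rounds = 20, prelim_rounds = 40)
  expect_true(all(paste0("causal", 1:3) %in% sel$confirmed))
  expect_gt(length(sel$rejected), 10L)
  expect_error(boruta_select(x, y, n_rounds = 3), "at least 5")
})

test_that("pure-noise features are rejected across seeds (binomial null)", {
  rejected <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 800
    x <- matrix(runif(n * 6), n, 6,
                dimnames = list(NULL, c("causal", paste0("noise", 1:5))))
    y <- rbinom(n, 1, plogis(-2 + 3 * x[, 1]))
    sel <- boruta_select(x, y, seed = s, n_rounds = 10, prelim_rounds = 30)
    if ("noise1" %in% sel$rejected) rejected <- rejected + 1L
  }
  expect_gte(rejected, 8L)
})

test_that("tuning returns in-bounds params and never loses to the default", {
  set.seed(5)
  n <- 1200
  x <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(-3 + 2.5 * x[, 1] + 2 * x[, 2]))
  inner <- rep_len(1:3, n)
  tuned <- tune_hyperparams(x, y, inner, budget = 4, seed = 2)
  b <- eplearn:::hyperparam_bounds(y)
  p <- tuned$params
  expect_gte(p$max_depth, b$max_depth[1]); expect_lte(p$max_depth, b$max_depth[2])
  expect_gte(p$learning_rate, b$learning_rate[1])
  expect_lte(p$learning_rate, b$learning_rate[2])
  expect_gte(p$scale_pos_weight, 1)
  # argmax property: the winner is at least as good as the default candidate
  expect_gte(tuned$map, tuned$trace$map[1])
  # degenerate budget is deterministic
  t1 <- tune_hyperparams(x, y, inner, budget = 1, seed = 9)
  t2 <- tune_hyperparams(x, y, inner, budget = 1, seed = 9)
  expect_identical(t1$params, t2$params)
  expect_equal(t1$map, t2$map)
  expect_error(tune_hyperparams(x, y, inner, budget = 0), "budget")
})

test_that("training separates a separable toy and stops within budget", {
  d <- toy_xy()
  val <- which(seq_along(d$y) %% 4 == 0)
  b <- train_model(d$x, d$y, val_rows = val, fold = 1L, seed = 3L)
  s <- predict_scores(b, d$x)
  expect_equal(average_precision(s, d$y), 1.0)
  expect_lte(b$best_iteration, b$params$max_rounds)
  # determinism
  b2 <- train_model(d$x, d$y, val_rows = val, fold = 1L, seed = 3L)
  expect_identical(predict_scores(b2, d$x), s)
  expect_error(train_model(d$x, rep(1L, nrow(d$x)), val_rows = val),
               "single-class")
})

test_that("prediction respects the selected-feature contract", {
  d <- toy_xy()
  b <- train_model(d$x, d$y, val_rows = seq(4, 400, by = 4), seed = 3L)
  extra <- cbind(d$x, irrelevant = rnorm(nrow(d$x)))
  expect_equal(predict_scores(b, extra), predict_scores(b, d$x))
  expect_equal(predict_scores(b, d$x[0, , drop = FALSE]), numeric(0))
  expect_error(predict_scores(b, d$x[, "noise", drop = FALSE]),
               "signal")   # error names the missing feature
  expect_true(all(predict_scores(b, d$x) > 0 & predict_scores(b, d$x) < 1))
})

test_that("tree SHAP satisfies local accuracy and isolates the split feature", {
  d <- toy_xy()
  b <- train_model(d$x, d$y, val_rows = seq(4, 400, by = 4), seed = 3L)
  sh <- shap_attributions(b, d$x)
  margin <- qlogis(predict_scores(b, d$x))
  expect_lt(max(abs(rowSums(sh$values) + sh$base - margin)), 1e-4)
  # the signal feature dominates the attribution on this toy
  imp <- colMeans(abs(sh$values))
  expect_lt(unname(imp["noise"]), unname(imp["signal"]))

  # a single depth-1 tree gives the split feature the entire margin
  # difference and everything else exactly zero
  p1 <- eplearn:::default_hyperparams(d$y)
  p1$max_depth <- 1L
  p1$max_rounds <- 1L
  p1$subsample <- 1
  p1$colsample_bytree <- 1
  b1 <- train_model(d$x, d$y, params = p1, val_rows = seq(4, 400, by = 4),
                    seed = 3L)
  sh1 <- shap_attributions(b1, d$x)
  expect_equal(unname(sh1$values[, "noise"]), rep(0, nrow(d$x)))
  m1 <- qlogis(predict_scores(b1, d$x))
  expect_equal(sh1$values[, "signal"] + sh1$base, m1, tolerance = 1e-6)

  # concatenation across folds conserves rows
  cc <- concat_shap(list(sh, sh))
  expect_equal(nrow(cc$values), 2L * nrow(sh$values))
})

test_that("mean-|SHAP| ranking matches hand computation and is stable", {
  s1 <- structure(list(values = matrix(c(1, -1, 0, 0.5), 2, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                       base = c(0, 0), fold = 1L), class = "ep_shap")
  r <- rank_features_by_mean_abs_shap(s1)
  expect_equal(r$feature, c("a", "b"))
  expect_equal(r$mean_abs_shap, c(1.0, 0.25))
  # all-zero attributions -> stable name order
  s0 <- structure(list(values = matrix(0, 2, 2,
                                       dimnames = list(NULL, c("z", "y"))),
                       base = c(0, 0), fold = 1L), class = "ep_shap")
  expect_equal(rank_features_by_mean_abs_shap(s0)$feature, c("y", "z"))
  # ranking invariant to row permutation
  s2 <- s1; s2$values <- s1$values[2:1, ]
  expect_equal(rank_features_by_mean_abs_shap(s2), r)
  sd <- structure(list(values = matrix(0, 2, 1,
                                       dimnames = list(NULL, "q")),
                       base = c(0, 0), fold = 1L), class = "ep_shap")
  expect_error(rank_features_by_mean_abs_shap(list(s1, sd)), "disjoint")
})

test_that("test-fold rows never influence the fitted pipeline", {
  sim <- simulate_ep_dataset(sim_config(seed = 31L, n_chrom = 8L,
                                        n_enhancers = 480L, n_tss = 160L))
  fz <- featurize_ep_dataset(sim, nmf_k = 3L)
  keep <- !is.na(sim$ep$adj_p)
  feats <- fz$features[keep]
  y <- label_positives(sim$ep)$label
  g <- ep_groups(sim$ep[keep], assign_groups(sim$elements, 5e6))
  cfg <- pipeline_config(outer_folds = 2L, inner_folds = 2L,
                         boruta_rounds = 5L, tune_budget = 2L, seed = 8L)
  fit_clean <- run_ep_pipeline(feats, y, g, cfg)
  # poison every feature of the rows in outer fold 1 (test rows of model 1)
  poisoned <- data.table::copy(feats)
  te1 <- which(fit_clean$plan$outer == 1L)
  for (cc in setdiff(names(poisoned), c("enhancer_id", "tss_id")))
    data.table::set(poisoned, te1, cc, 1e9)
  fit_poison <- suppressWarnings(run_ep_pipeline(poisoned, y, g, cfg))
  probe <- feature_matrix(feats)[sample(nrow(feats), 50), , drop = FALSE]
  ps <- apply_unit_scaler(fit_clean$bundles[[1]]$scaler, probe)
  expect_identical(fit_clean$bundles[[1]]$features,
                   fit_poison$bundles[[1]]$features)
  expect_identical(predict_scores(fit_clean$bundles[[1]], ps),
                   predict_scores(fit_poison$bundles[[1]], ps))
})
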