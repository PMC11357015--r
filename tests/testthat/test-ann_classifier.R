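ann_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- simulation_scenario(seed = 7)
      gm <- generate_matrix(sc)
      m <- normalize_matrix(gm$matrix)
      scr <- response_screen(m)
      feat <- unclass(m)[, top_features(scr, 20)$model_acc]
      cache <<- list(features = feat, labels = matrix_labels(m))
    }
    cache
  }
})

# a hand-built one-stage model whose logit depends only on feature j
manual_model <- function(feature_names, j, v = 10) {
  p <- length(feature_names)
  a <- matrix(0, p, 3); a[j, 1] <- 1
  structure(list(
    stages = list(list(a = a, c = rep(0, 3), v = c(v, 0, 0), b0 = 0)),
    f0 = 0, learning_rate = 1,
    feature_means = setNames(rep(0, p), feature_names),
    feature_sds = setNames(rep(1, p), feature_names),
    feature_names = feature_names, classes = c("HL", "LL"),
    config = ann_config(n_models = 1L)), class = "ann_boost")
}

test_that("split_holdout is stratified, rounded up per class, and deterministic", {
  ids <- c(sprintf("HL%02d", 1:25), sprintf("LL%02d", 1:15))
  labs <- rep(c("HL", "LL"), c(25, 15))
  sp <- split_holdout(ids, labs, 0.2, seed = 3)
  expect_length(sp$holdout_ids, 8L)
  expect_equal(sum(grepl("^HL", sp$holdout_ids)), 5L)
  expect_equal(sum(grepl("^LL", sp$holdout_ids)), 3L)
  expect_length(intersect(sp$train_ids, sp$holdout_ids), 0L)
  expect_identical(sp, split_holdout(ids, labs, 0.2, seed = 3))
  expect_false(identical(sp$holdout_ids,
                         split_holdout(ids, labs, 0.2, seed = 4)$holdout_ids))
  expect_error(split_holdout(ids, labs, 0), "fraction")
  expect_error(split_holdout(c("a", "b"), c("HL", "LL"), 0.2), ">= 2")
})

test_that("training on separable planted features yields zero holdout misclassification", {
  fx <- ann_fixture()
  fit <- ann_fit(fx$features, fx$labels, ann_config(seed = 17))
  expect_equal(fit$report$valid_misclass, 0)
  expect_equal(fit$report$train_misclass, 0)
  expect_gt(fit$report$valid_r2, 0.99)
  pred <- predict(fit, fx$features, type = "class")
  expect_equal(unname(pred), unname(fx$labels))
})

test_that("identical configuration and seed reproduce the fit bit-for-bit", {
  fx <- ann_fixture()
  f1 <- ann_fit(fx$features, fx$labels, ann_config(seed = 23))
  f2 <- ann_fit(fx$features, fx$labels, ann_config(seed = 23))
  expect_identical(f1$report, f2$report)
  expect_identical(f1$stages, f2$stages)
  v1 <- variable_importance(f1, fx$features, n_mc = 300, seed = 5)
  v2 <- variable_importance(f2, fx$features, n_mc = 300, seed = 5)
  expect_identical(v1, v2)
})

test_that("holdout rows never influence the fitted weights", {
  fx <- ann_fixture()
  cfg <- ann_config(seed = 29)
  f1 <- ann_fit(fx$features, fx$labels, cfg)
  scrambled <- fx$features
  scrambled[f1$report$holdout_ids, ] <- 999
  f2 <- ann_fit(scrambled, fx$labels, cfg)
  expect_identical(f1$stages, f2$stages)
  expect_identical(f1$feature_means, f2$feature_means)
})

test_that("degenerate and noise-only inputs behave as expected", {
  set.seed(31)
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(paste0("g", 1:40), paste0("PF", 1:3)))
  all_hl <- setNames(rep("HL", 40), rownames(x))
  fit <- ann_fit(x, all_hl, ann_config(seed = 1))
  expect_equal(unique(unname(predict(fit, x, type = "class"))), "HL")
  expect_equal(fit$report$train_misclass, 0)

  # pure noise: holdout accuracy near the majority-class rate
  set.seed(32)
  xn <- matrix(rnorm(200 * 5), 200, 5,
               dimnames = list(paste0("g", 1:200), paste0("PF", 1:5)))
  labs <- setNames(rep(c("HL", "LL"), each = 100), rownames(xn))
  fitn <- ann_fit(xn, labs, ann_config(seed = 2))
  expect_lt(abs(fitn$report$valid_misclass - 0.5), 0.25)
})

test_that("predicted probabilities are a proper two-class distribution", {
  fx <- ann_fixture()
  fit <- ann_fit(fx$features, fx$labels, ann_config(seed = 37))
  p <- predict(fit, fx$features, type = "prob")
  expect_equal(colnames(p), c("HL", "LL"))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
  expect_error(predict(fit, fx$features[, 1:3]), "mismatch")

  zero <- manual_model(colnames(fx$features), 1, v = 0)
  pz <- predict(zero, fx$features, type = "prob")
  expect_equal(unname(pz[, "HL"]), rep(0.5, nrow(pz)))
})

test_that("Sobol importance identifies which features the model uses", {
  set.seed(41)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(paste0("g", 1:60), paste0("PF", 1:4)))
  mono <- manual_model(colnames(x), 2)
  vi <- variable_importance(mono, x, n_mc = 3000, seed = 6)
  expect_equal(vi$total_effect[2], 1, tolerance = 0.05)
  expect_true(all(vi$total_effect[-2] < 0.01))
  expect_true(all(vi$main_effect[-2] < 0.01))
  expect_lte(sum(vi$main_effect), 1.05)
  expect_true(all(vi$total_effect >= vi$main_effect - 0.05))
  expect_error(variable_importance(mono, x, n_mc = 50), "n_mc")

  # two exchangeable features built from the same marginal get equal importance
  x2 <- x; x2[, 3] <- x2[, 2]
  two <- manual_model(colnames(x), 2)
  two$stages[[1]]$a[3, 2] <- 1; two$stages[[1]]$v[2] <- 10
  vi2 <- variable_importance(two, x2, n_mc = 4000, seed = 7)
  expect_equal(vi2$total_effect[2], vi2$total_effect[3], tolerance = 0.1)
})

test_that("marginal profiles span the observed range and track monotone models", {
  set.seed(43)
  x <- matrix(rnorm(50 * 3), 50, 3,
              dimnames = list(paste0("g", 1:50), paste0("PF", 1:3)))
  mono <- manual_model(colnames(x), 1)
  pr <- marginal_profile(mono, x, 1, grid_size = 15)
  expect_equal(pr$value[1], min(x[, 1]))
  expect_equal(pr$value[nrow(pr)], max(x[, 1]))
  expect_true(all(diff(pr$prob_hl) >= -1e-12))

  flat <- marginal_profile(mono, x, 3)
  expect_equal(diff(range(flat$prob_hl)), 0)

  xc <- x; xc[, 2] <- 4
  expect_warning(pc <- marginal_profile(mono, xc, 2), "constant")
  expect_equal(nrow(pc), 1L)
})
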