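# Constructed models with known explanations: linear models (closed-form
# Shapley values and ALE slopes), indicator classifiers (known anchor
# precision), and exchangeable/dummy features (Shapley axioms).

test_that("exact Shapley values satisfy the axioms on constructed models", {
  set.seed(2)
  bg <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  inst <- c(1.2, -0.7, 0.4, 2.1)
  # dummy: feature 3 unused
  f_dummy <- function(X) X[, 1] - 2 * X[, 2] + 0.5 * X[, 4]
  phi <- exact_shapley(f_dummy, inst, bg)
  expect_equal(unname(phi[3]), 0)
  # efficiency
  expect_equal(sum(phi) + attr(phi, "base_value"),
               unname(f_dummy(rbind(inst))), tolerance = 1e-9)
  # symmetry: exchangeable features with identical values get equal shares
  bg_sym <- bg; bg_sym[, 2] <- bg_sym[, 1]
  f_sym <- function(X) X[, 1] + X[, 2]
  inst_sym <- c(1.5, 1.5, 0, 0)
  phi_sym <- exact_shapley(f_sym, inst_sym, bg_sym)
  expect_equal(unname(phi_sym[1]), unname(phi_sym[2]), tolerance = 1e-9)
})

test_that("exact Shapley matches the linear-model closed form", {
  set.seed(3)
  beta <- c(2, -1, 0.5, 0, 3)
  f <- function(X) drop(as.matrix(X) %*% beta)
  bg <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  inst <- rnorm(5)
  phi <- exact_shapley(f, inst, bg)
  expect_equal(as.vector(phi), unname(beta * (inst - colMeans(bg))),
               tolerance = 1e-9)
})

test_that("kernel SHAP converges to the exact oracle", {
  set.seed(4)
  bg <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("f", 1:6)))
  inst <- rnorm(6)
  # nonlinear model so the check is not vacuous
  f <- function(X) X[, 1]^2 + tanh(X[, 2]) * X[, 3] - X[, 5]
  exact <- exact_shapley(f, inst, bg)
  rng <- diff(range(f(bg)))
  approx <- kernel_shap(f, inst, bg, n_coalitions = 400, seed = 1)
  expect_lt(max(abs(approx - exact)), 0.05 * rng)
  # additivity is enforced by the constraint
  expect_equal(sum(approx), unname(f(rbind(inst)) - attr(approx, "base_value")),
               tolerance = 1e-6)
  # constant model: all attributions zero
  fc <- function(X) rep(2.5, nrow(as.matrix(X)))
  phi0 <- kernel_shap(fc, inst, bg, n_coalitions = 100, seed = 2)
  expect_equal(as.vector(phi0), rep(0, 6), tolerance = 1e-9)
})

test_that("kernel SHAP error shrinks with more coalitions", {
  set.seed(9)
  bg <- matrix(rnorm(25 * 7), 25, 7, dimnames = list(NULL, paste0("f", 1:7)))
  inst <- rnorm(7)
  f <- function(X) sin(X[, 1]) + X[, 2] * X[, 3] + exp(X[, 4] / 3) - X[, 6]
  exact <- exact_shapley(f, inst, bg)
  err <- function(nc) stats::median(vapply(1:7, function(s)
    max(abs(kernel_shap(f, inst, bg, n_coalitions = nc, seed = s) - exact)),
    0))
  expect_lt(err(600), err(30))
})

test_that("ALE recovers linear effects under correlated inputs", {
  set.seed(5)
  L <- chol(matrix(c(1, 0.8, 0.8, 1), 2))
  X <- matrix(rnorm(4000), 2000, 2) %*% L
  colnames(X) <- c("x1", "x2")
  f <- function(M) 3 * M[, "x1"] - 2 * M[, "x2"]
  cur <- ale_curve(f, X, "x1", n_bins = 10)
  slope <- stats::coef(stats::lm(cur$effect ~ cur$edges[-1]))[2]
  expect_equal(unname(slope), 3, tolerance = 0.05)
  # centring: data-weighted mean effect is zero
  expect_lt(abs(sum(cur$counts * cur$effect) / sum(cur$counts)), 1e-9)
  # constant model: flat zero curve
  cur0 <- ale_curve(function(M) rep(1, nrow(M)), X, "x2", n_bins = 5)
  expect_equal(cur0$effect, rep(0, length(cur0$effect)))
})

test_that("anchor search isolates the deciding feature of an indicator model", {
  set.seed(6)
  Xtr <- matrix(runif(600 * 3), 600, 3, dimnames = list(NULL, c("a", "b", "c")))
  fc <- function(X) as.integer(as.matrix(X)[, "a"] > 0.5) + 1L
  inst <- c(a = 0.9, b = 0.2, c = 0.5)
  rule <- find_anchor(fc, inst, Xtr, max_features = 3, seed = 1)
  expect_true("a" %in% rule$predicates$feature)
  expect_gte(rule$precision, 0.95)
  # ground truth: anchoring "a" at 0.9 makes every perturbation class 2
  expect_equal(rule$predicted_class, 2L)

  # analytic precision of the empty rule = marginal predicted frequency
  r0 <- find_anchor(fc, inst, Xtr, max_features = 0, seed = 2)
  expect_equal(nrow(r0$predicates), 0L)
  p_marginal <- mean(Xtr[, "a"] > 0.5)
  se <- sqrt(p_marginal * (1 - p_marginal) / 1000)
  expect_lt(abs(r0$precision - p_marginal), 3 * se)
  expect_equal(r0$coverage, 1)

  # constant model: nothing to anchor
  rconst <- find_anchor(function(X) rep(1L, nrow(as.matrix(X))), inst, Xtr,
                        max_features = 3, seed = 3)
  expect_equal(nrow(rconst$predicates), 0L)
  expect_equal(rconst$precision, 1)
  expect_equal(rconst$coverage, 1)
})

test_that("anchor precision estimates track analytic ground truth", {
  # two-feature indicator: class 2 iff a > 0.6 and b > 0.3
  set.seed(7)
  Xtr <- matrix(runif(800 * 2), 800, 2, dimnames = list(NULL, c("a", "b")))
  fc <- function(X) { M <- as.matrix(X); as.integer(M[, "a"] > 0.6 & M[, "b"] > 0.3) + 1L }
  inst <- c(a = 0.95, b = 0.9)
  # anchoring only "a": precision = P(b > 0.3) under the marginal
  rule1 <- find_anchor(fc, inst, Xtr, max_features = 1, seed = 4)
  expect_equal(nrow(rule1$predicates), 1L)
  p_true <- if (rule1$predicates$feature == "a") mean(Xtr[, "b"] > 0.3)
            else mean(Xtr[, "a"] > 0.6)
  se <- sqrt(p_true * (1 - p_true) / 1000)
  expect_lt(abs(rule1$precision - p_true), 3 * se)
  # with both features anchorable the rule reaches the target
  rule2 <- find_anchor(fc, inst, Xtr, max_features = 2, seed = 5)
  expect_gte(rule2$precision, 0.95)
})

test_that("rendered rules carry raw-scale thresholds", {
  set.seed(8)
  hr <- runif(300, 50, 120)
  Xtr <- cbind("heart-rate" = hr, "anxious" = sample(1:7, 300, TRUE))
  fc <- function(X) as.integer(as.matrix(X)[, "heart-rate"] > 90) + 3L
  inst <- c("heart-rate" = 110, "anxious" = 3)
  rule <- find_anchor(fc, inst, Xtr, max_features = 2, seed = 9)
  txt <- format_anchor(rule)
  expect_match(txt, "IF \\[.*\\] THEN Depressed = 4")
  expect_match(txt, "Precision: ")
  expect_match(txt, "Coverage: ")
  # the threshold sits in the raw heart-rate range, not on a z-scale
  thr <- rule$predicates$threshold[rule$predicates$feature == "heart-rate"]
  expect_true(length(thr) >= 1 && all(thr > 40 & thr < 130))
})

test_that("mood-jump detection matches its definition exactly", {
  expect_equal(nrow(detect_mood_anomalies(rep(3L, 10),
                                          as.POSIXct("2024-01-01") +
                                            (1:10) * 3600)), 0L)
  ts <- as.POSIXct("2024-01-01 08:00", tz = "UTC") + c(0, 4, 8) * 3600
  ev <- detect_mood_anomalies(c(3L, 3L, 5L), ts, min_jump = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$change, 2L)
  expect_equal(ev$elapsed_hours, 4)
  # outside the window: excluded
  ts2 <- as.POSIXct("2024-01-01", tz = "UTC") + c(0, 48) * 3600
  expect_equal(nrow(detect_mood_anomalies(c(3L, 5L), ts2, max_hours = 24)), 0L)
  # direction preserved
  ev2 <- detect_mood_anomalies(c(6L, 2L), ts2[1:2] , min_jump = 2,
                               max_hours = 72)
  expect_equal(ev2$change, -4L)
})

test_that("anomaly explanation pairs rules or skips misclassified endpoints", {
  # train a tiny classifier whose class flips on one feature's threshold
  set.seed(10)
  n <- 90
  X <- cbind("anxious" = sample(1:7, n, TRUE),
             "heart-rate" = runif(n, 60, 100))
  y <- ifelse(X[, "anxious"] >= 4, 5L, 2L)
  arch <- arch_spec(2, 30, "tanh", 8, "classification")
  sc <- standard_normalize(X)
  model <- mlp_train(build_mlp(arch, 2, seed = 1), sc$X, y, epochs = 150,
                     seed = 2)
  tbl <- tiny_table(X, y = y,
                    timestamps = as.POSIXct("2024-01-01", tz = "UTC") +
                      (1:n) * 6 * 3600)
  fc <- moodcast:::class_predictor(model, sc$params)
  acc <- mean(fc(X) == y)
  expect_gte(acc, 0.99)   # the fixture must separate for rules to be meaningful

  ev <- detect_mood_anomalies(tbl$y, tbl$timestamps, min_jump = 2,
                              max_hours = 24)
  expect_gt(nrow(ev), 0)
  res <- explain_anomaly(model, sc$params, tbl, ev[1, ], max_features = 2,
                         n_perturbations = 500, seed = 3)
  expect_false(res$skipped)
  # the flip feature appears among the differing predicates
  expect_true("anxious" %in% c(res$before$predicates$feature,
                               res$after$predicates$feature))
  expect_match(res$rendered, "before:")
  expect_match(res$rendered, "Precision")

  # a forged event with a wrong label is skipped with a reason
  tbl_bad <- tbl
  tbl_bad$y[ev$before[1]] <- ifelse(tbl$y[ev$before[1]] == 5L, 2L, 5L)
  res_bad <- explain_anomaly(model, sc$params, tbl_bad, ev[1, ],
                             n_perturbations = 200, seed = 4)
  expect_true(res_bad$skipped)
  expect_match(res_bad$reason, "misclassified")
})

test_that("the planted feature tops the fold-averaged SHAP ranking", {
  tbl <- planted_table(effect = 2, noise = 0.25, seed = 42)
  pp <- preprocess(tbl, "manual")$table
  arch <- arch_spec(2, 30, "relu", 8, "regression")
  cv <- train_with_cv(pp, arch, epochs = 25, seed = 6, keep_models = TRUE)
  rk <- rank_features_by_shap(cv, pp, k = 5, n_coalitions = 120,
                              background_max = 40, seed = 3)
  expect_equal(rk$feature[1], "anxious")
  expect_equal(nrow(rk), 5L)
  # restriction removed neurocognitive features
  kinds <- moodcast:::schema_feature_kinds(pp$schema)
  expect_false(any(kinds[rk$feature] == "neurocognitive"))
  # k larger than the filtered feature count returns everything available
  rk_all <- rank_features_by_shap(cv, pp, k = 100, n_coalitions = 120,
                                  background_max = 40, seed = 3)
  expect_equal(nrow(rk_all), 16L)
})

test_that("fold-averaged ALE of the planted feature trends upward", {
  tbl <- planted_table(effect = 2, noise = 0.25, seed = 42)
  pp <- preprocess(tbl, "manual")$table
  arch <- arch_spec(2, 30, "relu", 8, "regression")
  cv <- train_with_cv(pp, arch, epochs = 25, seed = 6, keep_models = TRUE)
  cur <- ale_curve_cv(cv, pp, "anxious", n_bins = 6)
  # higher anxiety -> higher predicted mood score
  expect_gt(cur$effect[length(cur$effect)], cur$effect[1])
})
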