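test_that("time_sort orders rows stably by timestamp", {
  ts <- as.POSIXct("2024-01-01", tz = "UTC") + c(3, 1, 2, 1) * 3600
  X <- cbind("heart-rate" = c(10, 20, 30, 40))
  tbl <- tiny_table(X, y = c(1L, 2L, 3L, 4L), timestamps = ts)
  out <- time_sort(tbl)
  # the two ties (rows 2 and 4) keep their original relative order
  expect_equal(out$X[, 1], c(20, 40, 30, 10))
  expect_equal(out$y, c(2L, 4L, 3L, 1L))
  expect_identical(time_sort(out), out)
})

test_that("constant-feature detection ignores missing cells and respects kinds", {
  X <- cbind("heart-rate" = c(3, 3, 3), "anxious" = c(3, 3, 4),
             "ppg-std" = c(3, NA, 3), "GLbias-dACC" = c(1, 1, 1))
  tbl <- tiny_table(X)
  expect_setequal(detect_constant_features(tbl), c("heart-rate", "ppg-std"))
  expect_true("GLbias-dACC" %in%
                detect_constant_features(tbl, restrict_to_wearable = FALSE))
})

test_that("deletion keeps complete rows or excludes constant-sensor participants", {
  X <- cbind("heart-rate" = c(60, NA, 70, 75, 80),
             "anxious" = c(1, 2, 3, NA, 5))
  tbl <- tiny_table(X, y = rep(2L, 5))
  res <- deletion_preprocess(tbl)
  expect_equal(nrow(res$table$X), 3L)
  expect_equal(res$report$dropped_rows, 2L)
  expect_false(any(res$table$mask))

  const <- tiny_table(cbind("heart-rate" = rep(72, 5),
                            "anxious" = 1:5), y = rep(2L, 5))
  res2 <- deletion_preprocess(const)
  expect_null(res2$table)
  expect_true(res2$report$excluded)
  expect_match(res2$report$reason, "heart-rate")
})

test_that("single-column fill methods complete columns without touching observations", {
  expect_equal(fill_column(c(1, NA, 3), "mean"), c(1, 2, 3))
  expect_equal(fill_column(c(1, NA, NA, 4), "forward_fill"), c(1, 1, 1, 4))
  expect_equal(fill_column(c(1, NA, 3), "linear_interpolation"), c(1, 2, 3))
  expect_equal(fill_column(c(NA, NA, 5, 7), "forward_fill"), c(5, 5, 5, 7))
  expect_equal(fill_column(c(5, 7, NA, NA), "backward_fill"), c(5, 7, 7, 7))
  expect_equal(fill_column(c(1, NA, 2, NA, 9), "median"), c(1, 2, 2, 2, 9))
  # property: observed cells never modified, across methods and seeds
  set.seed(1)
  for (m in c("mean", "median", "forward_fill", "backward_fill",
              "linear_interpolation")) {
    v <- rnorm(40)
    v[sample(40, 12)] <- NA
    out <- fill_column(v, m)
    expect_false(anyNA(out))
    expect_identical(out[!is.na(v)], v[!is.na(v)])
  }
  expect_error(fill_column(c(NA, NA), "mean"), class = "moodcast_data_error")
})

test_that("iterative imputation recovers noiseless linear structure", {
  set.seed(7)
  x <- c(rnorm(20), 5)
  y <- 2 * x
  y[21] <- NA
  X <- cbind("heart-rate" = x, "ppg-std" = y)
  out <- iterative_impute(tiny_table(X, y = rep(2L, 21)))
  expect_lt(abs(out$X[21, "ppg-std"] - 10), 1e-6)
  # no missing -> unchanged
  full <- tiny_table(cbind("heart-rate" = 1:5), y = rep(2L, 5))
  expect_identical(iterative_impute(full), full)
})

test_that("iterative imputation falls back to means without regressors", {
  X <- cbind("heart-rate" = c(1, 2, NA, 3))
  out <- iterative_impute(X)                 # bare matrix, single column
  expect_equal(unname(out[3, 1]), 2)
})

test_that("knn imputation copies duplicates at k=1 and means at k >= n-1", {
  X <- cbind("heart-rate" = c(60, 60, 80), "anxious" = c(2, NA, 5))
  tbl <- tiny_table(X)
  out <- knn_impute(tbl, k = 1)
  expect_equal(unname(out$X[2, "anxious"]), 2)     # zero-distance duplicate
  out_all <- knn_impute(tbl, k = 10)
  expect_equal(unname(out_all$X[2, "anxious"]), mean(c(2, 5)))
  expect_identical(knn_impute(tiny_table(cbind("anxious" = 1:4))),
                   tiny_table(cbind("anxious" = 1:4)))
})

test_that("manual imputation is type-aware", {
  X <- cbind("past-day-fats" = c(2, 2, NA, 5),     # discrete -> mode
             "heart-rate" = c(60, 65, 70, NA),     # continuous -> iterative
             "GLbias-dACC" = c(0.5, NA, NA, 0.2))  # neurocognitive -> zero
  tbl <- tiny_table(X)
  res <- manual_impute(tbl)
  expect_equal(unname(res$table$X[3, "past-day-fats"]), 2)
  expect_equal(unname(res$table$X[c(2, 3), "GLbias-dACC"]), c(0, 0))
  expect_false(anyNA(res$table$X))
  # untouched when complete
  full <- tiny_table(cbind("anxious" = c(1, 2, 3)))
  expect_equal(manual_impute(full)$table$X, full$X)
})

test_that("KS statistic matches hand values, symmetry and a brute-force scan", {
  expect_equal(ks_two_sample(1:5, 1:5), 0)
  expect_equal(ks_two_sample(1:3, 7:9), 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 10)), 0.25)
  brute <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
  }
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:7, 30, replace = TRUE)          # tied, discrete
    b <- rnorm(17)
    expect_equal(ks_two_sample(a, b), brute(a, b))
    expect_equal(ks_two_sample(a, b), ks_two_sample(b, a))
    expect_true(ks_two_sample(a, b) >= 0 && ks_two_sample(a, b) <= 1)
  }
  # independent oracle on tie-free samples
  set.seed(12)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  expect_equal(ks_two_sample(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
})

test_that("automatic imputation picks the minimum-KS method", {
  # smooth ramp with interior gaps: interpolation preserves the marginal,
  # mean-fill piles mass at the mean
  n <- 60
  ramp <- seq(0, 10, length.out = n)
  v <- ramp
  set.seed(3)
  v[sample(10:50, 12)] <- NA
  obs <- v[!is.na(v)]
  ks_mean <- ks_two_sample(fill_column(v, "mean"), obs)
  ks_lin <- ks_two_sample(fill_column(v, "linear_interpolation"), obs)
  expect_lt(ks_lin, ks_mean)

  X <- cbind("heart-rate" = v, "anxious" = rep(1:6, 10))
  res <- auto_impute(tiny_table(X))
  expect_false(anyNA(res$table$X))
  scores <- res$report$ks_scores[["heart-rate"]]
  pick <- res$report$chosen_method_per_feature[["heart-rate"]]
  expect_equal(unname(scores[pick]), min(scores))
  expect_true(all(names(scores) %in% imputation_methods()))
})

test_that("automatic imputation selection is consistent on noisy columns", {
  set.seed(21)
  for (i in 1:5) {
    v <- rnorm(80)
    v[sample(80, 16)] <- NA
    X <- cbind("heart-rate" = v, "ppg-std" = rnorm(80))
    res <- auto_impute(tiny_table(X))
    for (fn in names(res$report$ks_scores)) {
      sc <- res$report$ks_scores[[fn]]
      pick <- res$report$chosen_method_per_feature[[fn]]
      expect_equal(unname(sc[pick]), min(sc))
    }
    # observed cells never modified
    expect_identical(res$table$X[!is.na(v), "heart-rate"],
                     v[!is.na(v)])
  }
})

test_that("standard normalisation centres, scales, guards and round-trips", {
  out <- standard_normalize(cbind(a = c(0, 2)))
  expect_equal(unname(out$X[, 1]), c(-1, 1))          # population sd
  X <- matrix(rnorm(60), 20, 3)
  fit <- standard_normalize(X)
  expect_equal(unname(colMeans(fit$X)), rep(0, 3), tolerance = 1e-12)
  refit <- standard_normalize(fit$X, fit$params)      # idempotent on params?
  expect_equal(standard_normalize(X, fit$params)$X, fit$X, tolerance = 1e-12)
  cst <- standard_normalize(cbind(a = rep(5, 4)))
  expect_equal(unname(cst$X[, 1]), rep(0, 4))
  expect_equal(unname(cst$params$sigma), 1)
})
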