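# Stratified cross-validation, the metric suite, and the fold-training loop.

#' Stratified k-fold split
#'
#' Partitions `1..n` into `k` disjoint, exhaustive test folds whose per-class
#' counts differ by at most one across folds, so every fold carries the same
#' label proportions as the data permit. Assignment is seeded: within each
#' class the indices are shuffled and dealt round-robin, the dealing offset
#' rotating between classes to balance overall fold sizes.
#'
#' @param labels ordinal/discrete label vector (any type with equality).
#' @param k fold count (>= 2, `<= length(labels)`).
#' @param seed integer seed.
#' @return list of `k` elements, each `list(train = idx, test = idx)`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k < 2L || n < k) stop_config("need k >= 2 and at least k samples")
  assignment <- integer(n)
  with_seed(derive_seed(seed, "kfold"), {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      ix <- which(labels == cl)
      ix <- ix[sample.int(length(ix))]
      assignment[ix] <- ((seq_along(ix) - 1L + offset) %% k) + 1L
      offset <- (offset + length(ix)) %% k
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(assignment != f), test = which(assignment == f)))
}

#' Prediction metrics
#'
#' Computes the metric suite on a prediction batch. For classification the
#' point prediction is the arg-max class on the 1--7 scale; macro-F1 and
#' balanced accuracy (mean per-class recall) are added, both averaged over
#' the classes present in the true labels (per-class scores that are
#' undefined because the class was never predicted count as zero). MAPE is
#' computed on the 1--7 label scale, which never contains zero, so the
#' division is always defined.
#'
#' @param batch list with `y_true`, and either `y_pred` (regression) or
#'   `probs` (classification, `n x 7` matrix).
#' @param problem_type `"classification"` or `"regression"`.
#' @return named list: `mae`, `mape` (percent), `mse`, plus `f1` and
#'   `balanced_accuracy` for classification.
#' @examples
#' compute_metrics(list(y_true = 1, y_pred = 2), "regression")$mape  # 100
#' compute_metrics(list(y_true = 5, y_pred = 6), "regression")$mape  # 20
#' @export
compute_metrics <- function(batch,
                            problem_type = c("classification", "regression")) {
  problem_type <- match.arg(problem_type)
  y <- batch$y_true
  if (length(y) == 0L) stop_data("empty prediction batch")
  if (problem_type == "classification") {
    probs <- matrix(batch$probs, nrow = length(y))
    yhat <- max.col(probs, ties.method = "first")
  } else {
    yhat <- batch$y_pred
  }
  out <- list(
    mae = mean(abs(y - yhat)),
    mape = mean(abs(y - yhat) / y) * 100,
    mse = mean((y - yhat)^2)
  )
  if (problem_type == "classification") {
    classes <- sort(unique(y))
    recall <- vapply(classes, function(cl)
      sum(y == cl & yhat == cl) / sum(y == cl), 0)
    f1 <- vapply(classes, function(cl) {
      tp <- sum(y == cl & yhat == cl)
      fp <- sum(y != cl & yhat == cl)
      fn <- sum(y == cl & yhat != cl)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, 0)
    out$balanced_accuracy <- mean(recall)
    out$f1 <- mean(f1)
  }
  out
}

#' Train one architecture under stratified 5-fold cross-validation
#'
#' For each fold: the feature scaler is fitted on the training split and
#' applied to the test split (set `paper_faithful_scaling = TRUE` to instead
#' normalise the whole table once before splitting), the network is trained
#' with Adam and early stopping, and train/test metrics are computed. The
#' report carries per-fold metrics and their mean and standard deviation.
#' Everything is seeded, so identical inputs give identical reports.
#'
#' A degenerate training fold (a single class under classification) cannot
#' be fitted meaningfully; its metrics are set to the worst case (maximum
#' label distance, zero F1/balanced accuracy) and flagged.
#'
#' @param table a complete (imputed) `participant_table`.
#' @param arch an [arch_spec()].
#' @param loss_kind regression loss, `"mse"` (default) or `"mae"`;
#'   classification always uses the cross-entropy.
#' @param epochs maximum training epochs (default 100).
#' @param k fold count (default 5).
#' @param patience early-stopping patience (default 10).
#' @param seed integer seed.
#' @param paper_faithful_scaling normalise before splitting (default FALSE,
#'   avoiding train/test leakage).
#' @param keep_models retain per-fold models, fold indices and scalers for
#'   downstream explanation (default FALSE).
#' @return object of class `cv_report`: `folds` (per-fold metric lists),
#'   `mean`/`sd` (train and test), `arch`, and optionally `fold_models`.
#' @export
train_with_cv <- function(table, arch, loss_kind = NULL, epochs = 100L,
                          k = 5L, patience = 10L, seed = 1L,
                          paper_faithful_scaling = FALSE,
                          keep_models = FALSE) {
  X <- table$X
  if (anyNA(X)) stop_data("table must be imputed/complete before training")
  y <- table$y
  if (length(y) < k) stop_data("need at least k samples")
  cls <- arch$problem_type == "classification"
  if (is.null(loss_kind)) loss_kind <- if (cls) "cross_entropy" else "mse"

  pre <- if (paper_faithful_scaling) standard_normalize(X) else NULL
  folds <- stratified_kfold(y, k = k, seed = derive_seed(seed, "folds"))

  fold_entries <- vector("list", k)
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (paper_faithful_scaling) {
      Xtr <- pre$X[tr, , drop = FALSE]; Xte <- pre$X[te, , drop = FALSE]
      scaler <- pre$params
    } else {
      sc <- standard_normalize(X[tr, , drop = FALSE])
      scaler <- sc$params
      Xtr <- sc$X
      Xte <- standard_normalize(X[te, , drop = FALSE], scaler)$X
    }
    degenerate <- cls && length(unique(y[tr])) < 2L
    if (degenerate) {
      worst <- list(mae = 6, mape = 600, mse = 36,
                    balanced_accuracy = 0, f1 = 0)
      fold_entries[[f]] <- list(train = worst, test = worst,
                                degenerate = TRUE)
      next
    }
    model <- build_mlp(arch, ncol(X), seed = derive_seed(seed, "init", f))
    model <- mlp_train(model, Xtr, y[tr], loss_kind = loss_kind,
                       epochs = epochs, patience = patience,
                       seed = derive_seed(seed, "fit", f))
    mk_batch <- function(Xs, ys) {
      if (cls) list(y_true = ys, probs = mlp_predict(model, Xs))
      else list(y_true = ys, y_pred = mlp_predict(model, Xs))
    }
    fold_entries[[f]] <- list(
      train = compute_metrics(mk_batch(Xtr, y[tr]), arch$problem_type),
      test = compute_metrics(mk_batch(Xte, y[te]), arch$problem_type),
      degenerate = FALSE)
    if (keep_models)
      fold_models[[f]] <- list(model = model, scaler = scaler,
                               train = tr, test = te)
  }

  metric_names <- names(fold_entries[[1L]]$test)
  agg <- function(side, fun) {
    vapply(metric_names, function(m)
      fun(vapply(fold_entries, function(e) e[[side]][[m]], 0)), 0)
  }
  rep <- structure(list(
    folds = fold_entries,
    mean = list(train = agg("train", mean), test = agg("test", mean)),
    sd = list(train = agg("train", stats::sd), test = agg("test", stats::sd)),
    arch = arch, loss_kind = loss_kind, k = k, seed = seed
  ), class = "cv_report")
  if (keep_models) rep$fold_models <- fold_models
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$arch$problem_type, ", ", x$k, "-fold\n", sep = "")
  cat("  mean test: ",
      paste(names(x$mean$test),
            sprintf("%.3f", unlist(x$mean$test)), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
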