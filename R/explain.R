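utils::globalVariables(c("mean_abs_shap", "feature", "x", "ale"))

# Post hoc model explanation: exact and kernel Shapley attributions,
# accumulated local effects (ALE) curves, anchor IF-THEN rules with
# precision/coverage, and the before/after rule comparison around anomalous
# mood jumps. All operations consume un-normalised feature values; model
# wrappers normalise internally so thresholds and curves live on the raw
# data scale.

#' Wrap a trained fold model as a raw-data predictor
#'
#' Returns `f(X_raw) -> numeric` that applies the fold's stored scaler and
#' the model. For regression the raw output is returned; for classification
#' the probability of `class` (a single scalar target is required for
#' attribution methods, and the predicted-class probability is the
#' convention used here).
#'
#' @param model an `mlp_model`.
#' @param scaler `normalization_params` fitted on the fold's training data.
#' @param class target class in 1..7 (classification only).
#' @return a function mapping a raw feature matrix to a numeric vector.
#' @export
model_predictor <- function(model, scaler, class = NULL) {
  cls <- model$arch$problem_type == "classification"
  if (cls && is.null(class))
    stop_config("a target class is required for classification predictors")
  function(X) {
    X <- as.matrix(X)
    Xn <- standard_normalize(X, scaler)$X
    out <- mlp_predict(model, Xn)
    if (cls) out[, class] else out
  }
}

# classification class-label predictor (argmax on 1-7)
class_predictor <- function(model, scaler) {
  function(X) {
    Xn <- standard_normalize(as.matrix(X), scaler)$X
    max.col(mlp_predict(model, Xn), ties.method = "first")
  }
}

# single-row matrix preserving feature names
row_matrix <- function(instance, ref = NULL) {
  nm <- names(instance) %||% if (!is.null(ref)) colnames(ref) else NULL
  matrix(instance, 1L, dimnames = list(NULL, nm))
}

shapley_weight <- function(s, p) {
  exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
}

#' Exact Shapley values by subset enumeration
#'
#' The reference oracle: classic Shapley values with characteristic function
#' `v(S)` = mean over the background rows of the model output on hybrids
#' taking features in `S` from the instance and the rest from the background
#' row. Exponential in the feature count, hence capped at 14 features.
#' Satisfies efficiency: `sum(phi) + base = f(instance)`.
#'
#' @param f predictor `f(X) -> numeric` (see [model_predictor()]).
#' @param instance numeric vector (raw scale).
#' @param background matrix of background rows (raw scale).
#' @return named numeric vector of per-feature values, with attribute
#'   `base_value` (mean model output over the background).
#' @export
exact_shapley <- function(f, instance, background) {
  p <- length(instance)
  if (p > 14L) stop_config("exact enumeration capped at 14 features")
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop_config("background must be non-empty")
  n_mask <- bitwShiftL(1L, p)
  # v(S) for every subset, vectorised over one big hybrid matrix
  nb <- nrow(background)
  v <- numeric(n_mask)
  big <- background[rep(seq_len(nb), n_mask), , drop = FALSE]
  for (m in seq_len(n_mask) - 1L) {
    rows <- (m * nb + 1L):((m + 1L) * nb)
    on <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) > 0L)
    if (length(on)) big[rows, on] <- matrix(instance[on], nb, length(on),
                                            byrow = TRUE)
  }
  out <- f(big)
  v <- vapply(seq_len(n_mask) - 1L, function(m)
    mean(out[(m * nb + 1L):((m + 1L) * nb)]), 0)

  phi <- numeric(p)
  sizes <- vapply(seq_len(n_mask) - 1L, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) > 0L), 0L)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_mask) - 1L, bit) == 0L) - 1L
    w <- shapley_weight(sizes[without + 1L], p)
    phi[j] <- sum(w * (v[without + bit + 1L] - v[without + 1L]))
  }
  names(phi) <- colnames(background)
  attr(phi, "base_value") <- v[1L]
  phi
}

#' Kernel SHAP approximation
#'
#' Weighted-least-squares approximation to the Shapley values over sampled
#' feature coalitions with the Shapley kernel weights, constrained so the
#' attributions sum exactly to `f(instance) - base_value` (the efficiency
#' property). Coalition sizes are drawn proportional to the kernel and
#' sampled in complementary pairs. A singular system falls back to a
#' ridge-regularised solve.
#'
#' @param f predictor as in [exact_shapley()].
#' @param instance numeric vector (raw scale).
#' @param background background matrix (raw scale).
#' @param n_coalitions number of sampled coalitions (>= p + 2).
#' @param seed integer seed.
#' @return named numeric vector with attribute `base_value`.
#' @export
kernel_shap <- function(f, instance, background, n_coalitions = 200L,
                        seed = 1L) {
  p <- length(instance)
  if (n_coalitions < p + 2L) stop_config("n_coalitions must be >= p + 2")
  background <- as.matrix(background)
  nb <- nrow(background)
  fx <- as.numeric(f(row_matrix(instance, background)))[1L]
  base <- mean(f(background))

  with_seed(derive_seed(seed, "kshap"), {
    sizes <- seq_len(p - 1L)
    size_w <- (p - 1) / (sizes * (p - sizes))
    half <- ceiling(n_coalitions / 2)
    s_draw <- sample(sizes, half, replace = TRUE, prob = size_w)
    Z <- matrix(0L, 2L * half, p)
    for (i in seq_len(half)) {
      on <- sample.int(p, s_draw[i])
      Z[2L * i - 1L, on] <- 1L
      Z[2L * i, -on] <- 1L           # complementary pair
    }
  })
  zs <- rowSums(Z)
  keep <- zs > 0L & zs < p
  Z <- Z[keep, , drop = FALSE]; zs <- zs[keep]
  w <- (p - 1) / (choose(p, zs) * zs * (p - zs))

  # E f on each coalition (hybrids against every background row)
  nz <- nrow(Z)
  big <- background[rep(seq_len(nb), nz), , drop = FALSE]
  for (i in seq_len(nz)) {
    on <- which(Z[i, ] == 1L)
    rows <- ((i - 1L) * nb + 1L):(i * nb)
    big[rows, on] <- matrix(instance[on], nb, length(on), byrow = TRUE)
  }
  vf <- f(big)
  v <- vapply(seq_len(nz), function(i)
    mean(vf[((i - 1L) * nb + 1L):(i * nb)]), 0)

  # WLS with the efficiency constraint sum(phi) = fx - base, eliminated via
  # the last feature: phi_p = (fx - base) - sum(phi_-p)
  y <- v - base - Z[, p] * (fx - base)
  Zr <- Z[, -p, drop = FALSE] - Z[, p]
  A <- crossprod(Zr, Zr * w)
  bvec <- crossprod(Zr, y * w)
  phi_r <- tryCatch(solve(A, bvec), error = function(e) {
    signalCondition(structure(class = c("moodcast_fallback", "condition"),
                              list(message = "kernel_shap: singular system; ridge fallback",
                                   call = NULL)))
    solve(A + diag(1e-8, ncol(A)), bvec)
  })
  phi <- c(drop(phi_r), (fx - base) - sum(phi_r))
  names(phi) <- colnames(background)
  attr(phi, "base_value") <- base
  phi
}

#' Fold-averaged mean-|SHAP| feature ranking
#'
#' For each cross-validation fold, kernel SHAP attributions are computed on
#' the fold's test instances against a (subsampled) background of the fold's
#' training rows; the mean absolute attribution per feature is taken over
#' instances, averaged across folds, optionally restricted to wearable/EMA
#' features (the actionable ones for lifestyle intervention), and the top-k
#' returned. For classification the scalar explained is the probability of
#' each instance's predicted class; for regression the raw output.
#'
#' @param cv a `cv_report` from [train_with_cv()] with `keep_models = TRUE`.
#' @param table the raw (un-normalised, complete) `participant_table`.
#' @param restrict `"wearable_ema"` (default) or `"none"`.
#' @param k number of features to return (default 5).
#' @param n_coalitions,background_max,seed kernel-SHAP settings.
#' @return data frame of `feature`, `mean_abs_shap`, sorted descending,
#'   top-`k` rows; attribute `all_features` holds the full ranking.
#' @export
rank_features_by_shap <- function(cv, table, restrict = c("wearable_ema",
                                                          "none"),
                                  k = 5L, n_coalitions = 200L,
                                  background_max = 100L, seed = 1L) {
  restrict <- match.arg(restrict)
  if (is.null(cv$fold_models))
    stop_config("train_with_cv must be run with keep_models = TRUE")
  X <- table$X
  p <- ncol(X)
  cls <- cv$arch$problem_type == "classification"

  fold_means <- list()
  for (f_i in seq_along(cv$fold_models)) {
    fm <- cv$fold_models[[f_i]]
    if (is.null(fm)) next
    bg <- X[fm$train, , drop = FALSE]
    if (nrow(bg) > background_max) {
      pick <- with_seed(derive_seed(seed, "bg", f_i),
                        sample.int(nrow(bg), background_max))
      bg <- bg[pick, , drop = FALSE]
    }
    test_X <- X[fm$test, , drop = FALSE]
    cls_pred <- if (cls) class_predictor(fm$model, fm$scaler)(test_X)
    abs_sum <- numeric(p)
    for (i in seq_len(nrow(test_X))) {
      f <- if (cls)
        model_predictor(fm$model, fm$scaler, class = cls_pred[i])
      else model_predictor(fm$model, fm$scaler)
      phi <- kernel_shap(f, test_X[i, ], bg, n_coalitions = n_coalitions,
                         seed = derive_seed(seed, f_i, i))
      abs_sum <- abs_sum + abs(phi)
    }
    fold_means[[length(fold_means) + 1L]] <- abs_sum / nrow(test_X)
  }
  overall <- Reduce(`+`, fold_means) / length(fold_means)
  names(overall) <- colnames(X)

  if (restrict == "wearable_ema") {
    kinds <- schema_feature_kinds(table$schema)
    overall <- overall[kinds[names(overall)] %in% wearable_ema_kinds]
  }
  ord <- order(-overall)
  full <- data.frame(feature = names(overall)[ord],
                     mean_abs_shap = unname(overall[ord]),
                     stringsAsFactors = FALSE)
  out <- utils::head(full, k)
  attr(out, "all_features") <- full
  out
}

#' First-order accumulated local effects curve
#'
#' Bins the feature at empirical quantiles; within each bin the local effect
#' is the average over in-bin rows of `f(row with feature set to the upper
#' edge) - f(row with feature at the lower edge)`; effects are accumulated
#' (cumulative sum) and centred by subtracting the data-weighted mean, so the
#' curve reads as the feature's main effect relative to the average
#' prediction. Duplicate quantile edges (few distinct values) are collapsed.
#'
#' @param f predictor `f(X_raw) -> numeric`.
#' @param data raw feature matrix the curve is evaluated on.
#' @param feature feature name (a column of `data`).
#' @param n_bins quantile bin count (default 10).
#' @param edges optional explicit bin edges (overrides `n_bins`), used to put
#'   several folds on a common grid.
#' @return object of class `ale_curve`: `feature`, `edges`, `effect`
#'   (centred accumulated effect at each upper edge), `counts`.
#' @export
ale_curve <- function(f, data, feature, n_bins = 10L, edges = NULL) {
  data <- as.matrix(data)
  x <- data[, feature]
  if (is.null(edges)) {
    if (n_bins < 2L) stop_config("n_bins must be >= 2")
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                     n_bins + 1L),
                                    names = FALSE, type = 7))
  }
  K <- length(edges) - 1L
  if (K < 1L) {
    # single distinct value: flat zero curve
    return(structure(list(feature = feature, edges = edges,
                          effect = 0, counts = length(x)),
                     class = "ale_curve"))
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  eff <- numeric(K); counts <- integer(K)
  for (b in seq_len(K)) {
    rows <- which(bin == b)
    counts[b] <- length(rows)
    if (length(rows) == 0L) { eff[b] <- 0; next }
    hi <- data[rows, , drop = FALSE]; hi[, feature] <- edges[b + 1L]
    lo <- data[rows, , drop = FALSE]; lo[, feature] <- edges[b]
    eff[b] <- mean(f(hi) - f(lo))
  }
  acc <- cumsum(eff)
  centre <- sum(counts * acc) / sum(counts)
  structure(list(feature = feature, edges = edges, effect = acc - centre,
                 counts = counts), class = "ale_curve")
}

#' Fold-averaged ALE curve
#'
#' Computes one ALE curve per cross-validation fold on the fold's test rows,
#' using a common bin grid built from the pooled data quantiles, and averages
#' the curves.
#'
#' @param cv a `cv_report` with `keep_models = TRUE`.
#' @param table raw, complete `participant_table`.
#' @param feature feature name.
#' @param n_bins quantile bins on the pooled data (default 10).
#' @return an `ale_curve` (fold-averaged), with `fold_curves` attached.
#' @export
ale_curve_cv <- function(cv, table, feature, n_bins = 10L) {
  if (is.null(cv$fold_models))
    stop_config("train_with_cv must be run with keep_models = TRUE")
  X <- table$X
  edges <- unique(stats::quantile(X[, feature],
                                  probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  cls <- cv$arch$problem_type == "classification"
  curves <- list()
  for (f_i in seq_along(cv$fold_models)) {
    fm <- cv$fold_models[[f_i]]
    if (is.null(fm)) next
    test_X <- X[fm$test, , drop = FALSE]
    f <- if (cls) {
      # majority predicted class on the fold as the scalar target
      pred <- class_predictor(fm$model, fm$scaler)(test_X)
      tgt <- as.integer(names(sort(table(pred), decreasing = TRUE))[1L])
      model_predictor(fm$model, fm$scaler, class = tgt)
    } else model_predictor(fm$model, fm$scaler)
    curves[[length(curves) + 1L]] <- ale_curve(f, test_X, feature,
                                               edges = edges)
  }
  eff <- Reduce(`+`, lapply(curves, `[[`, "effect")) / length(curves)
  cnt <- Reduce(`+`, lapply(curves, `[[`, "counts"))
  structure(list(feature = feature, edges = edges, effect = eff,
                 counts = cnt, fold_curves = curves,
                 fold_averaged = TRUE), class = "ale_curve")
}

new_anchor_rule <- function(predicates, predicted_class, precision, coverage,
                            max_features, target_met) {
  structure(list(predicates = predicates, predicted_class = predicted_class,
                 precision = precision, coverage = coverage,
                 max_features = max_features, target_met = target_met),
            class = "anchor_rule")
}

#' Render an anchor rule in IF-THEN form
#'
#' @param rule an `anchor_rule`.
#' @return single string, e.g.
#'   `IF [(anxious > 4.04) AND (distracted <= 2.94)] THEN Depressed = 4
#'   (Precision: 0.80, Coverage: 0.08)`.
#' @export
format_anchor <- function(rule) {
  preds <- if (nrow(rule$predicates) == 0L) "TRUE" else
    paste(sprintf("(%s %s %.2f)", rule$predicates$feature,
                  rule$predicates$relation, rule$predicates$threshold),
          collapse = " AND ")
  sprintf("IF [%s] THEN Depressed = %d (Precision: %.2f, Coverage: %.2f)",
          preds, rule$predicted_class, rule$precision, rule$coverage)
}

#' @export
print.anchor_rule <- function(x, ...) {
  cat(format_anchor(x), "\n")
  invisible(x)
}

#' Find an anchor rule for a classified instance
#'
#' Searches for an IF-THEN rule that locally fixes ("anchors") a classifier's
#' prediction. Features are discretised into quartile bins of the training
#' data; the candidate predicates are the instance's own bin bounds expressed
#' as `<=`/`>` thresholds. A greedy bottom-up search adds the predicate that
#' most increases the estimated precision until `precision_target` is reached,
#' `max_features` predicates are used, or no candidate improves. Precision is
#' the fraction of perturbed samples (unanchored features resampled from the
#' training marginals, anchored features fixed at the instance's values) that
#' keep the instance's predicted class; coverage is the fraction of freely
#' perturbed samples satisfying the rule. The rule is returned with its
#' estimates even when the target is missed (`target_met = FALSE`).
#'
#' @param f_class classifier label function `f(X_raw) -> class` (see
#'   [class_predictor()]).
#' @param instance numeric vector (raw scale).
#' @param train_data raw training matrix defining bins and marginals.
#' @param max_features maximum number of predicates (default 5).
#' @param precision_target target precision (default 0.95).
#' @param n_perturbations Monte-Carlo samples per estimate (default 1000).
#' @param seed integer seed.
#' @return an `anchor_rule`.
#' @export
find_anchor <- function(f_class, instance, train_data, max_features = 5L,
                        precision_target = 0.95, n_perturbations = 1000L,
                        seed = 1L) {
  train_data <- as.matrix(train_data)
  p <- ncol(train_data)
  target <- f_class(row_matrix(instance, train_data))

  # candidate predicates: the instance's quartile-bin bounds per feature
  cand <- list()
  for (j in seq_len(p)) {
    qs <- unique(stats::quantile(train_data[, j], c(0.25, 0.5, 0.75),
                                 names = FALSE, type = 7))
    lo <- suppressWarnings(max(qs[qs < instance[j]]))
    hi <- suppressWarnings(min(qs[qs >= instance[j]]))
    fn <- colnames(train_data)[j]
    if (is.finite(lo))
      cand[[length(cand) + 1L]] <- list(feature = fn, j = j,
                                        relation = ">", threshold = lo)
    if (is.finite(hi))
      cand[[length(cand) + 1L]] <- list(feature = fn, j = j,
                                        relation = "<=", threshold = hi)
  }

  perturb <- function(n, anchored_j, seed) {
    with_seed(seed, {
      P <- vapply(seq_len(p), function(j)
        sample(train_data[, j], n, replace = TRUE), numeric(n))
      colnames(P) <- colnames(train_data)
      if (length(anchored_j))
        P[, anchored_j] <- matrix(instance[anchored_j], n,
                                  length(anchored_j), byrow = TRUE)
      P
    })
  }
  precision_of <- function(anchored_j, seed) {
    P <- perturb(n_perturbations, anchored_j, seed)
    mean(f_class(P) == target)
  }

  selected <- list()
  anchored <- integer(0)
  prec <- precision_of(anchored, derive_seed(seed, "round", 0L))
  round_i <- 0L
  while (prec < precision_target && length(selected) < max_features &&
         length(cand)) {
    round_i <- round_i + 1L
    round_seed <- derive_seed(seed, "round", round_i)
    est <- vapply(cand, function(cd)
      precision_of(unique(c(anchored, cd$j)), round_seed), 0)
    best <- which.max(est)
    if (est[best] <= prec + 1e-12) break   # no candidate improves
    selected[[length(selected) + 1L]] <- cand[[best]]
    anchored <- unique(c(anchored, cand[[best]]$j))
    cand <- cand[-best]
    prec <- est[best]
  }

  # final unbiased estimates on fresh perturbations
  prec <- precision_of(anchored, derive_seed(seed, "final_p"))
  Pfree <- perturb(n_perturbations, integer(0), derive_seed(seed, "final_c"))
  sat <- rep(TRUE, n_perturbations)
  for (cd in selected) {
    sat <- sat & if (cd$relation == "<=") Pfree[, cd$j] <= cd$threshold
    else Pfree[, cd$j] > cd$threshold
  }
  preds <- if (length(selected))
    data.frame(feature = vapply(selected, `[[`, "", "feature"),
               relation = vapply(selected, `[[`, "", "relation"),
               threshold = vapply(selected, `[[`, 0, "threshold"),
               stringsAsFactors = FALSE)
  else data.frame(feature = character(), relation = character(),
                  threshold = numeric(), stringsAsFactors = FALSE)
  new_anchor_rule(preds, as.integer(target), prec, mean(sat),
                  max_features, prec >= precision_target)
}

#' Detect anomalous mood jumps
#'
#' Flags consecutive EMA pairs where the mood score changes by at least
#' `min_jump` scale points within `max_hours`. The defaults (a 2-point jump
#' inside 24 h) capture sudden mood deterioration or recovery while ignoring
#' slow drift.
#'
#' @param y ordinal mood series (time-sorted).
#' @param timestamps matching `POSIXct` vector.
#' @param min_jump minimum absolute score change (default 2).
#' @param max_hours maximum elapsed time in hours (default 24).
#' @return data frame with `before`, `after` (indices), `change` (signed) and
#'   `elapsed_hours`; zero rows when nothing qualifies.
#' @export
detect_mood_anomalies <- function(y, timestamps, min_jump = 2L,
                                  max_hours = 24) {
  n <- length(y)
  if (n < 2L)
    return(data.frame(before = integer(), after = integer(),
                      change = integer(), elapsed_hours = numeric()))
  dy <- diff(y)
  dt <- as.numeric(difftime(timestamps[-1L], timestamps[-n], units = "hours"))
  hit <- which(abs(dy) >= min_jump & dt <= max_hours)
  data.frame(before = hit, after = hit + 1L, change = dy[hit],
             elapsed_hours = dt[hit])
}

#' Explain an anomalous mood jump with paired anchor rules
#'
#' Computes anchor rules for the instances just before and just after an
#' anomalous jump and reports the rule difference, rendered in IF-THEN form.
#' Rules are only meaningful when the model is right about both endpoints, so
#' an event where either endpoint is misclassified is skipped with a reason.
#'
#' @param model a classification `mlp_model`.
#' @param scaler its `normalization_params`.
#' @param table raw, complete `participant_table` (time-sorted).
#' @param event one row of [detect_mood_anomalies()] output.
#' @param max_features,precision_target,n_perturbations,seed passed to
#'   [find_anchor()].
#' @return list with `skipped` flag (and `reason`), or `before`/`after`
#'   `anchor_rule`s, `changed_features` (features whose predicates differ)
#'   and `rendered` text block.
#' @export
explain_anomaly <- function(model, scaler, table, event, max_features = 5L,
                            precision_target = 0.95,
                            n_perturbations = 1000L, seed = 1L) {
  if (model$arch$problem_type != "classification")
    stop_config("anchor explanations require a classification model")
  fc <- class_predictor(model, scaler)
  i0 <- event$before; i1 <- event$after
  pred <- fc(table$X[c(i0, i1), , drop = FALSE])
  if (pred[1L] != table$y[i0] || pred[2L] != table$y[i1]) {
    return(list(skipped = TRUE,
                reason = sprintf(
                  "endpoint misclassified (predicted %d/%d, actual %d/%d)",
                  pred[1L], pred[2L], table$y[i0], table$y[i1])))
  }
  before <- find_anchor(fc, table$X[i0, ], table$X, max_features,
                        precision_target, n_perturbations,
                        seed = derive_seed(seed, "before"))
  after <- find_anchor(fc, table$X[i1, ], table$X, max_features,
                       precision_target, n_perturbations,
                       seed = derive_seed(seed, "after"))
  changed <- union(setdiff(before$predicates$feature,
                           after$predicates$feature),
                   setdiff(after$predicates$feature,
                           before$predicates$feature))
  list(skipped = FALSE, before = before, after = after,
       changed_features = changed,
       rendered = paste0(
         "Anomaly: mood ", table$y[i0], " -> ", table$y[i1], " in ",
         sprintf("%.0f", event$elapsed_hours), " h\n",
         "  before: ", format_anchor(before), "\n",
         "  after:  ", format_anchor(after), "\n"))
}

#' SHAP top-feature bar plot
#'
#' @param ranking output of [rank_features_by_shap()].
#' @return a ggplot object.
#' @export
plot_shap_summary <- function(ranking) {
  ranking$feature <- factor(ranking$feature,
                            levels = rev(ranking$feature))
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = mean_abs_shap, y = feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |SHAP value|", y = NULL,
                  title = "Top features by mean absolute SHAP value") +
    ggplot2::theme_minimal()
}

#' ALE curve plot
#'
#' @param curve an `ale_curve`.
#' @return a ggplot object.
#' @export
plot_ale <- function(curve) {
  df <- data.frame(x = curve$edges[-1L], ale = curve$effect)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = ale)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = curve$feature, y = "ALE (effect on prediction)") +
    ggplot2::theme_minimal()
}
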